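# RSS objective, analytic p0 profile and grid fitting

test_that("rss and the analytic p0 minimizer match independent optimization", {
  expect_equal(rss_value(c(0.1, 0.2), c(1, 1), 0.15), 0.005)
  expect_equal(rss_value(c(0.1, 0.2), c(1, 1), 0), 0.05)
  g <- c(0.9, 0.95, 1)
  expect_equal(rss_value(0.03 * g, g, 0.03), 0)
  # exact linear fit and single-SNP cases
  expect_equal(p0_analytic(0.03 * g, g), 0.03)
  expect_equal(p0_analytic(0.02, 0.8), 0.025)
  # random instance vs 1-D numerical minimization (golden-section oracle)
  set.seed(42)
  for (i in 1:5) {
    g <- runif(100, 0.5, 1)
    pn <- pmin(pmax(0.03 * g + rnorm(100, 0, 0.01), 0), 1)
    opt <- optimize(function(p) sum((pn - p * g)^2), c(0, 1), tol = 1e-12)
    expect_equal(p0_analytic(pn, g), opt$minimum, tolerance = 1e-8)
  }
  # clamping to [0, 1]
  expect_equal(p0_analytic(rep(2, 3), rep(1, 3)), 1)
  expect_error(p0_analytic(numeric(0), numeric(0)), "non-empty")
})

test_that("per-SNP g values behave as the mixture model requires", {
  map <- toy_map(length_mb = 20)
  ex <- toy_exons(10.1)
  calls <- toy_calls(10, 0.03, map = map)
  # single SNP, single exon at 0.1 cM: g = mu*l*f + (1 - mu*l)
  g <- expected_g(calls, ex, map, s = 4e-4, mu = 1e-4, t = 2000)
  f1 <- f_autosome(0.001, 4e-4, 2000)
  expect_equal(g, 0.1 * f1 + 0.9, tolerance = 1e-9)
  # mu = 0: all ones
  expect_equal(expected_g(calls, ex, map, s = 4e-4, mu = 0), 1)
  # X mode routes through the X reduction factor
  gx <- expected_g(calls, ex, map, s = 4e-4, mu = 1e-4, mode = "X")
  expect_equal(gx, 0.1 * f_xchr(0.001, 4e-4, 2000) + 0.9, tolerance = 1e-9)
  # larger windows include more linked targets: g(10 cM) <= g(1 cM)
  gen <- small_genome(seed = 5)
  calls2 <- synthetic_calls(gen, noise = "none")
  g1 <- expected_g(calls2, gen$exons, gen$map, s = 4e-4, mu = 8e-5,
                   window_cM = 1)
  g10 <- expected_g(calls2, gen$exons, gen$map, s = 4e-4, mu = 8e-5,
                    window_cM = 10)
  expect_true(all(g10 <= g1 + 1e-12))
  expect_true(all(g1 > 0 & g1 <= 1))
})

test_that("the C++ grid pass agrees with the R mixture evaluation", {
  gen <- small_genome(seed = 6)
  calls <- synthetic_calls(gen, noise = "drift", seed = 7)
  pairs <- introgsel:::site_windows(calls, gen$exons, gen$map, 1)
  s_grid <- c(1e-4, 4e-4); mu_grid <- c(1e-5, 8e-5)
  for (mode in c("autosome", "X")) {
    for (t in c(2000, Inf)) {
      cs <- introgsel:::grid_sums(pairs, calls$pn, rep(0L, nrow(calls)), 1L,
                                  s_grid, mu_grid, t, mode)
      k <- 0
      for (s in s_grid) for (mu in mu_grid) {
        k <- k + 1
        g <- introgsel:::g_from_pairs(pairs, s, mu, t, mode)
        expect_equal(cs$num[1, k], sum(calls$pn * g), tolerance = 1e-10)
        expect_equal(cs$den[1, k], sum(g^2), tolerance = 1e-10)
      }
    }
  }
})

test_that("noiseless data generated at a grid point are recovered exactly", {
  gen <- small_genome(seed = 8)
  s_true <- 4e-4; mu_true <- 8e-5; p0_true <- 0.034
  calls <- synthetic_calls(gen, p0 = p0_true, s = s_true, mu = mu_true,
                           noise = "none")
  s_grid <- grid_with(s_true, 1e-5, 4e-3)
  mu_grid <- grid_with(mu_true, 1e-6, 1e-3)
  fit <- fit_introgression(calls, gen$exons, gen$map,
                           s_grid = s_grid, mu_grid = mu_grid)
  expect_identical(fit$best$s, s_true)
  expect_identical(fit$best$mu, mu_true)
  expect_equal(fit$best$p0, p0_true, tolerance = 1e-6)
  expect_lt(fit$best$rss, 1e-12)
  # scaled surface is <= 0 everywhere and 0 at the optimum
  scaled <- fit$best$rss - fit$surface$rss
  expect_true(all(scaled <= 1e-12))
  expect_equal(max(scaled), 0)
})

test_that("constant observed frequencies are explained by mu = 0", {
  gen <- small_genome(seed = 9)
  calls <- call_table(gen$snps$chrom, gen$snps$pos,
                      rep(0.025, nrow(gen$snps)), map = gen$map)
  fit <- fit_introgression(calls, gen$exons, gen$map,
                           s_grid = c(1e-5, 1e-4, 1e-3),
                           mu_grid = c(0, 1e-4, 1e-3))
  expect_identical(fit$best$mu, 0)
  expect_identical(fit$best$s, 1e-5)  # tie broken toward smaller s
  expect_equal(fit$best$p0, 0.025)
  expect_equal(fit$best$rss, 0)
})

test_that("the fit is invariant to SNP order", {
  gen <- small_genome(seed = 10)
  calls <- synthetic_calls(gen, noise = "drift", seed = 11)
  fit1 <- fit_introgression(calls, gen$exons, gen$map)
  perm <- calls[sample(nrow(calls)), ]
  class(perm) <- class(calls)
  fit2 <- fit_introgression(perm, gen$exons, gen$map)
  expect_equal(fit1$best, fit2$best)
  expect_equal(fit1$surface, fit2$surface)
})

test_that("the profile surface shows the (s, mu) ridge along constant mu*s", {
  # moving away from the optimum along constant mu*s (raise s, lower mu)
  # costs much less RSS than moving across it (raise both)
  gen <- small_genome(seed = 12, n_chrom = 4)
  calls <- synthetic_calls(gen, noise = "none")
  fit <- fit_introgression(calls, gen$exons, gen$map)
  surf <- fit$surface
  ns <- length(fit$grid$s); nm <- length(fit$grid$mu)
  is <- which.min(abs(fit$grid$s - fit$best$s))
  im <- which.min(abs(fit$grid$mu - fit$best$mu))
  ds <- if (is + 4 <= ns && im - 4 >= 1 && im + 4 <= nm) 4 else -4
  cell <- function(i, k) surf$rss[(i - 1) * nm + k]
  along <- cell(is + ds, im - ds)
  across <- cell(is + ds, im + ds)
  expect_lt(along - fit$best$rss, 0.25 * (across - fit$best$rss))
})

test_that("fitted-model methods are mutually consistent", {
  gen <- small_genome(seed = 14)
  calls <- synthetic_calls(gen, noise = "drift", seed = 15)
  fit <- fit_introgression(calls, gen$exons, gen$map)
  co <- coef(fit)
  expect_named(co, c("p0", "s", "mu", "mus"))
  expect_equal(unname(co["mus"]), unname(co["s"] * co["mu"]))
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), calls$pn - fitted(fit))
  expect_equal(rss_value(calls$pn, fit$g_hat, fit$best$p0), fit$best$rss,
               tolerance = 1e-8)
  # predict under explicit parameters: mu = 0 gives a constant column
  pr <- predict(fit, model_params(p0 = 0.03, s = 1e-4, t = 2000, mu = 0))
  expect_true(all(pr == 0.03))
  expect_output(print(fit), "Introgression selection fit")
  expect_output(print(summary(fit)), "Scaled RSS")
  # simulate() returns call tables on the same sites
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$pos, calls$pos)
  expect_true(all(sims[[1]]$pn >= 0 & sims[[1]]$pn <= 1))
})

test_that("parameters are recovered across noisy synthetic genomes", {
  # full study conditions: 22 chromosomes, ~50k SNPs, drift noise,
  # truths spread around the genome-wide autosomal estimates
  n_runs <- 20
  est <- truth <- matrix(NA_real_, n_runs, 3,
                         dimnames = list(NULL, c("p0", "s", "mu")))
  for (i in seq_len(n_runs)) {
    set.seed(9000 + i)
    tr <- c(p0 = 0.0338, s = 4.12e-4 * exp(runif(1, -0.6, 0.6)),
            mu = 8.1e-5 * exp(runif(1, -0.6, 0.6)))
    gen <- synthetic_genome(seed = 9100 + i)
    calls <- synthetic_calls(gen, p0 = tr["p0"], s = tr["s"], mu = tr["mu"],
                             noise = "drift", seed = 9200 + i)
    fit <- fit_introgression(calls, gen$exons, gen$map)
    truth[i, ] <- tr
    est[i, ] <- coef(fit)[1:3]
  }
  expect_lte(median(abs(est[, "s"] - truth[, "s"]) / truth[, "s"]), 0.5)
  expect_lte(median(abs(est[, "p0"] - truth[, "p0"]) / truth[, "p0"]), 0.1)
  # the compound parameter mu*s is better constrained than mu or s alone:
  # its estimates track the truth across runs
  expect_gt(cor(truth[, "s"] * truth[, "mu"], est[, "s"] * est[, "mu"],
                method = "spearman"), 0)
})

test_that("weighted RSS surface is computed on request and shares the optimum on clean data", {
  gen <- small_genome(seed = 16, n_chrom = 1, chrom_cM = 30)
  calls <- synthetic_calls(gen, p0 = 0.034, s = 4e-4, mu = 8e-5,
                           noise = "none")
  fit <- fit_introgression(calls, gen$exons, gen$map,
                           s_grid = grid_with(4e-4, 1e-4, 1e-3, 5),
                           mu_grid = grid_with(8e-5, 1e-5, 3e-4, 5),
                           weighted = TRUE)
  expect_false(is.null(fit$weighted))
  expect_true(all(fit$weighted$surface$rss >= 0))
  expect_identical(fit$weighted$best$s, 4e-4)
  expect_identical(fit$weighted$best$mu, 8e-5)
  expect_lt(fit$weighted$best$rss, 1e-10)
})

test_that("exon density diagnostic matches the model structure", {
  # zero noise: observed equals predicted in every bin
  gen <- small_genome(seed = 18, n_chrom = 4)
  calls <- synthetic_calls(gen, noise = "none")
  s_grid <- grid_with(4.12e-4, 1e-5, 4e-3)
  mu_grid <- grid_with(8.1e-5, 1e-6, 1e-3)
  fit <- fit_introgression(calls, gen$exons, gen$map, s_grid = s_grid,
                           mu_grid = mu_grid)
  dg <- exon_density_diagnostic(fit, gen$exons, gen$map)
  expect_equal(dg$bins$observed, dg$bins$predicted, tolerance = 1e-8)
  expect_equal(dg$pearson, 1, tolerance = 1e-6)
  # predicted bin means non-increasing with exon-density rank
  expect_true(all(diff(dg$bins$predicted) <= 1e-12))
  # fewer segments than bins reduces the bin count with a warning
  gen2 <- small_genome(seed = 19, n_chrom = 1, chrom_cM = 5)
  calls2 <- synthetic_calls(gen2, noise = "none")
  fit2 <- fit_introgression(calls2, gen2$exons, gen2$map, s_grid = s_grid,
                            mu_grid = mu_grid)
  expect_warning(dg2 <- exon_density_diagnostic(fit2, gen2$exons, gen2$map,
                                                n_bins = 10),
                 "fewer segments")
  expect_lte(nrow(dg2$bins), 5)
})

test_that("a toy segment layout produces hand-computed bin means", {
  map <- toy_map(length_mb = 4)
  # four 1-cM segments; exons only in segments 3 and 4
  ex <- toy_exons(c(2.5, 3.2, 3.6), len = 2000)
  calls <- toy_calls(c(0.5, 1.5, 2.5, 3.5), c(0.040, 0.036, 0.030, 0.020),
                     map = map)
  fit <- fit_introgression(calls, ex, map, s_grid = c(4e-4),
                           mu_grid = c(8e-5), block_cM = 1)
  dg <- exon_density_diagnostic(fit, ex, map, segment_cM = 1, n_bins = 2)
  expect_equal(nrow(dg$bins), 2)
  # low-density bin: segments 1 and 2 (no exons)
  expect_equal(dg$bins$observed[1], mean(c(0.040, 0.036)))
  expect_equal(dg$bins$observed[2], mean(c(0.030, 0.020)))
  expect_equal(dg$bins$mean_exonic_bp, c(0, 3000))
})
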