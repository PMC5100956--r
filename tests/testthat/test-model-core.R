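# closed-form reduction factors, recursion oracles and the
# nearest-selected-exon mixture

test_that("reduction factors reproduce their analytic special cases", {
  # r = 0 collapses to the unlinked decay (1-s)^t
  expect_equal(f_autosome(0, 4e-4, 2000), (1 - 4e-4)^2000, tolerance = 1e-12)
  expect_equal(f_xchr(0, 4e-4, 2000), (1 - 4e-4)^2000, tolerance = 1e-12)
  # no selection, no loss
  expect_identical(f_autosome(0.3, 0, 5000), 1)
  expect_identical(f_xchr(0.2, 0, 1000), 1)
  # equilibrium closed forms
  expect_equal(f_autosome_equilibrium(0.001, 4e-4), 0.001 / 0.0013996,
               tolerance = 1e-12)
  expect_equal(f_autosome_equilibrium(0.5, 0), 1)
  expect_equal(f_autosome_equilibrium(0.01, 1e-5), 0.99901, tolerance = 1e-4)
  # domain errors
  expect_error(f_autosome(0.6, 1e-4, 10), "r must be")
  expect_error(f_autosome(0.1, 1, 10), "s must be")
  expect_error(f_autosome(0.1, -0.1, 10), "s must be")
  expect_error(f_autosome_equilibrium(0, 0), "degenerate")
  expect_error(f_xchr(0, 0, Inf), "degenerate")
})

test_that("closed forms agree with the iterated haplotype recursion", {
  # frozen oracle values (recursion at p0 = 1)
  expect_equal(haplotype_recursion(0.001, 4e-4, 2000), 0.7318316037,
               tolerance = 1e-9)
  expect_equal(f_autosome(0.001, 4e-4, 2000), 0.7318316037, tolerance = 1e-9)
  expect_equal(f_xchr(0.001, 4e-4, 2000), 0.6695266256, tolerance = 1e-9)
  # fully neutral recursion returns p0 unchanged
  expect_equal(haplotype_recursion(0, 0, 100, p0 = 0.04), 0.04)
  # recursion is linear in p0
  expect_equal(haplotype_recursion(0.002, 2e-4, 500, p0 = 0.034),
               0.034 * haplotype_recursion(0.002, 2e-4, 500), tolerance = 1e-14)
  # spot agreement across the (r, s) plane, both modes
  for (r in c(1e-5, 1e-4, 1e-3, 1e-2)) {
    for (s in c(1e-5, 1e-4, 4e-4)) {
      expect_lt(abs(f_autosome(r, s, 2000) -
                      haplotype_recursion(r, s, 2000)), 1e-8)
      expect_lt(abs(f_xchr(r, s, 2000) -
                      haplotype_recursion(r, s, 2000, mode = "X")), 1e-8)
    }
  }
  # frequency is non-increasing in t under selection
  traj <- vapply(c(0, 10, 100, 1000), function(tt)
    haplotype_recursion(0.5, 0.9, tt), numeric(1))
  expect_true(all(diff(traj) <= 0))
})

test_that("the explicit two-sex X recursion matches Eq-3 dynamics to first order", {
  # the 2/3 time-weighting is the first-order reduction of the two-sex
  # system; agreement is close but not exact
  for (r in c(1e-4, 1e-3, 5e-3)) {
    d <- abs(f_xchr(r, 4e-4, 2000) -
               haplotype_recursion(r, 4e-4, 2000, mode = "X", two_sex = TRUE))
    expect_lt(d, 2e-4)
  }
  # and it is genuinely a different trajectory
  expect_gt(abs(f_xchr(5e-3, 4e-4, 2000) -
                  haplotype_recursion(5e-3, 4e-4, 2000, mode = "X",
                                      two_sex = TRUE)), 1e-8)
})

test_that("finite-t factors converge to the equilibrium gene flow factor", {
  for (r in c(1e-4, 1e-3, 1e-2)) {
    for (s in c(1e-5, 4e-4)) {
      expect_equal(f_autosome(r, s, 1e7), f_autosome_equilibrium(r, s),
                   tolerance = 1e-6)
      expect_equal(f_xchr(r, s, 1e7), f_xchr_equilibrium(r, s),
                   tolerance = 1e-6)
      expect_equal(f_autosome(r, s, Inf), f_autosome_equilibrium(r, s))
    }
  }
})

test_that("reduction factors are monotone and bounded on a dense grid", {
  rs <- exp(seq(log(1e-5), log(1e-2), length.out = 26))
  ss <- exp(seq(log(1e-5), log(4e-4), length.out = 26))
  ts <- c(100, 1000, 2000, 10000, 1e5)
  for (f in list(f_autosome, f_xchr)) {
    vals <- array(dim = c(26, 26, 5))
    for (i in 1:26) for (k in 1:5) vals[i, , k] <- f(rs[i], ss, ts[k])
    expect_true(all(vals >= 0 & vals <= 1))
    # non-increasing in s
    expect_true(all(apply(vals, c(1, 3), diff) <= 1e-14))
    # non-increasing in t
    expect_true(all(apply(vals, c(1, 2), diff) <= 1e-14))
    # non-decreasing in r
    expect_true(all(apply(vals, c(2, 3), diff) >= -1e-14))
  }
})

test_that("nearest-exon weights form a proper mixture", {
  ctx <- linked_exon_context(r = c(0.001, 0.002), lengths = c(1000, 1000))
  expect_equal(nearest_exon_weights(ctx, 1e-4), c(0.1, 0.09, 0.81))
  expect_equal(nearest_exon_weights(ctx, 0), c(0, 0, 1))
  expect_equal(nearest_exon_weights(linked_exon_context(), 1e-4), 1)
  # telescoping: sums to one for random configurations
  set.seed(7)
  for (i in 1:20) {
    k <- sample(0:30, 1)
    ctx <- linked_exon_context(r = sort(runif(k, 0, 0.5)),
                               lengths = sample(50:9000, k, replace = TRUE))
    w <- nearest_exon_weights(ctx, 10^runif(1, -6, -4))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  # mu*l >= 1 clamps with a warning
  big <- linked_exon_context(r = 0.001, lengths = 5000)
  expect_warning(w <- nearest_exon_weights(big, 5e-4), "clamping")
  expect_equal(w, c(1, 0))
})

test_that("expected frequency composes weights and reduction factors", {
  ctx <- linked_exon_context(r = 0.001, lengths = 1000)
  par <- model_params(p0 = 0.034, s = 4e-4, t = 2000, mu = 1e-4)
  expect_equal(expected_frequency(ctx, par),
               0.034 * (0.1 * 0.7318316 + 0.9), tolerance = 1e-6)
  # mu = 0 or empty window return p0 exactly
  expect_identical(expected_frequency(ctx, model_params(0.034, 4e-4, 2000, 0)),
                   0.034)
  expect_identical(expected_frequency(linked_exon_context(), par), 0.034)
  # non-increasing in mu and s
  mus <- c(0, 1e-5, 1e-4, 5e-4)
  v <- vapply(mus, function(m)
    expected_frequency(ctx, model_params(0.034, 4e-4, 2000, m)), numeric(1))
  expect_true(all(diff(v) <= 0))
  svals <- c(0, 1e-4, 4e-4, 4e-3)
  v <- vapply(svals, function(s)
    expected_frequency(ctx, model_params(0.034, s, 2000, 1e-4)), numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("model parameter validation enforces the domain", {
  expect_error(model_params(p0 = 1.2, s = 1e-4))
  expect_error(model_params(p0 = 0.03, s = 1))
  expect_error(model_params(p0 = 0.03, s = 1e-4, mu = 2))
  expect_s3_class(model_params(0.03, 1e-4, Inf, 1e-5, "X"), "model_params")
})
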