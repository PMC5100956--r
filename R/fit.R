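# Grid-search RSS inference of (p0, s, mu).

#' Per-SNP expected reduction factor g
#'
#' Evaluates the nearest-selected-exon mixture factor `g_l(r, s, t, mu)`
#' for every SNP in a call table, so that `E[p_n] = p0 * g_l`. SNPs with
#' no exon in their window have `g = 1`.
#'
#' @param calls a [call_table()].
#' @param exons an [exon_annotation()].
#' @param map a [genetic_map()].
#' @param s selection coefficient.
#' @param mu per-exonic-base density of selected sites.
#' @param t generations since admixture (`Inf` for the equilibrium model).
#' @param mode `"autosome"` or `"X"`.
#' @param window_cM window size in cM.
#' @return Numeric vector of per-SNP `g` values in (0, 1\].
#' @export
expected_g <- function(calls, exons, map, s, mu, t = 2000,
                       mode = c("autosome", "X"), window_cM = 1) {
  mode <- match.arg(mode)
  pairs <- site_windows(calls, exons, map, window_cM)
  g_from_pairs(pairs, s, mu, t, mode)
}

#' Analytic RSS-minimizing initial admixture proportion
#'
#' The residual sum of squares `sum((pn - p0 * g)^2)` is quadratic in
#' `p0`; its unconstrained minimizer is `sum(pn * g) / sum(g^2)`, clamped
#' to \[0, 1\].
#'
#' @param pn observed frequencies.
#' @param g matching per-SNP reduction factors.
#' @return The profile value of `p0`.
#' @export
p0_analytic <- function(pn, g) {
  if (!length(pn) || length(pn) != length(g))
    stop("pn and g must be non-empty vectors of equal length")
  den <- sum(g * g)
  if (den <= 0) stop("sum(g^2) must be positive")
  clamp01(sum(pn * g) / den)
}

#' Residual sum of squares of the frequency model
#'
#' @inheritParams p0_analytic
#' @param p0 initial admixture proportion.
#' @return `sum((pn - p0 * g)^2)`.
#' @export
rss_value <- function(pn, g, p0) {
  stopifnot(length(pn) == length(g))
  sum((pn - p0 * g)^2)
}

log_grid <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# profile p0 and RSS over all (s, mu) cells from block-wise sufficient
# statistics; cells are ordered s-major so that ties resolve toward
# smaller s, then smaller mu
profile_surface <- function(num_tot, den_tot, pn2_tot, s_grid, mu_grid) {
  p0 <- clamp01(num_tot / den_tot)
  rss <- pmax(pn2_tot - 2 * p0 * num_tot + p0^2 * den_tot, 0)
  best <- which.min(rss)
  cells <- expand.grid(mu = mu_grid, s = s_grid)[, 2:1]  # s-major order
  list(surface = data.frame(s = cells$s, mu = cells$mu, p0_min = p0, rss = rss),
       best = list(s = cells$s[best], mu = cells$mu[best], p0 = p0[best],
                   rss = rss[best], index = best))
}

#' Fit the introgression selection model by grid search
#'
#' Minimizes the residual sum of squares between observed per-SNP
#' introgressed-allele frequencies and the model expectation
#' `p0 * g_l(r, s, t, mu)` over a logarithmic grid of `(s, mu)`, with the
#' initial admixture proportion profiled out analytically at each cell
#' ([p0_analytic()]). A coarse search over the full ranges is followed by
#' a fine 26 x 26 grid spanning one coarse cell on either side of the
#' coarse optimum. Ties are broken toward smaller `s`, then smaller `mu`.
#'
#' Per-5-cM-block sufficient statistics for every fine-grid cell are
#' retained in the fitted object so that [bootstrap_fit()] can reassemble
#' the objective for resampled genomes without touching SNP-level data.
#'
#' @inheritParams expected_g
#' @param s_range,mu_range ranges of the coarse search (log-spaced).
#' @param n_coarse,n_fine number of grid points per axis for the coarse
#'   and fine searches.
#' @param s_grid,mu_grid optional explicit grids; if supplied the coarse
#'   stage is skipped and the surface is evaluated on these grids alone.
#' @param refine set to `FALSE` to skip grid refinement (the coarse grid
#'   becomes the final one).
#' @param block_cM block length for the stored bootstrap sufficient
#'   statistics.
#' @param weighted also compute a variance-weighted RSS surface (each
#'   residual weighted by `1 / (phat * (1 - phat))` with `phat` the model
#'   mean); a robustness diagnostic, reported alongside the main fit.
#' @return An object of class `introg_fit`; see [coef.introg_fit()],
#'   [predict.introg_fit()], [confint.introg_fit()], [plot.introg_fit()].
#' @examples
#' \donttest{
#' gen <- synthetic_genome(n_chrom = 2, chrom_cM = 40, seed = 1)
#' calls <- synthetic_calls(gen, p0 = 0.034, s = 4e-4, mu = 8e-5,
#'                          noise = "none")
#' fit <- fit_introgression(calls, gen$exons, gen$map)
#' coef(fit)
#' }
#' @export
fit_introgression <- function(calls, exons, map, t = 2000,
                              mode = c("autosome", "X"), window_cM = 1,
                              s_range = c(1e-5, 4e-3),
                              mu_range = c(1e-6, 1e-3),
                              n_coarse = 13, n_fine = 26,
                              s_grid = NULL, mu_grid = NULL,
                              refine = TRUE, block_cM = 5,
                              weighted = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(calls, "call_table"))
  if (!nrow(calls)) stop("empty call table")
  if (is.null(calls$gpos)) calls <- annotate_calls(calls, map)
  pairs <- site_windows(calls, exons, map, window_cM)
  blocks <- assign_blocks(calls, block_cM = block_cM)
  pn <- calls$pn

  explicit <- !is.null(s_grid) || !is.null(mu_grid)
  s1 <- s_grid %||% log_grid(s_range[1], s_range[2], n_coarse)
  m1 <- mu_grid %||% log_grid(mu_range[1], mu_range[2], n_coarse)
  coarse <- NULL
  if (!explicit && refine) {
    cs <- grid_sums(pairs, pn, rep(0L, length(pn)), 1L, s1, m1, t, mode)
    coarse <- profile_surface(drop(cs$num), drop(cs$den), sum(pn^2), s1, m1)
    s_fine <- refine_grid(s1, coarse$best$s, n_fine)
    mu_fine <- refine_grid(m1, coarse$best$mu, n_fine)
  } else {
    s_fine <- s1
    mu_fine <- m1
  }

  bs <- grid_sums(pairs, pn, blocks$block, blocks$n_blocks, s_fine, mu_fine,
                  t, mode)
  pn2_block <- as.vector(rowsum(pn^2, blocks$block + 1L,
                                reorder = TRUE))
  prof <- profile_surface(colSums(bs$num), colSums(bs$den), sum(pn^2),
                          s_fine, mu_fine)

  fit <- structure(list(
    best = c(prof$best,
             list(mus = prof$best$s * prof$best$mu)),
    surface = prof$surface,
    coarse = coarse,
    grid = list(s = s_fine, mu = mu_fine),
    t = t, mode = mode, window_cM = window_cM,
    calls = calls, pairs = pairs,
    block_sums = list(num = bs$num, den = bs$den, pn2 = pn2_block,
                      block_chrom = blocks$block_chrom,
                      block_cM = block_cM),
    n_snps = length(pn)), class = "introg_fit")
  fit$g_hat <- g_from_pairs(pairs, prof$best$s, prof$best$mu, t, mode,
                            warn_clamp = FALSE)
  if (weighted) fit$weighted <- weighted_surface(fit)
  fit
}

# two coarse cells on either side of the optimum, log-spaced; the wider
# span keeps bootstrap replicate estimates off the fine-grid boundary
refine_grid <- function(grid, center, n, span = 2L) {
  i <- which.min(abs(grid - center))
  lo <- grid[max(i - span, 1L)]
  hi <- grid[min(i + span, length(grid))]
  log_grid(lo, hi, n)
}

# C++ grid pass: per-block numerators/denominators of the analytic p0 for
# every (s, mu) cell
grid_sums <- function(pairs, pn, block, n_blocks, s_grid, mu_grid, t, mode) {
  equilibrium <- is.infinite(t)
  cpp_profile_sums(pairs$r, pairs$l, pairs$off, pn, as.integer(block),
                   as.integer(n_blocks), as.numeric(s_grid),
                   as.numeric(mu_grid), if (equilibrium) 0 else t,
                   equilibrium, mode == "X")
}

# variance-weighted profile surface (robustness check): weights
# 1/(phat(1-phat)) from the unweighted profile mean, then one reweighted
# p0 update per cell; pure-R, intended for diagnostic use
weighted_surface <- function(fit) {
  pn <- fit$calls$pn
  cells <- fit$surface
  rssw <- numeric(nrow(cells))
  p0w <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    g <- g_from_pairs(fit$pairs, cells$s[i], cells$mu[i], fit$t, fit$mode,
                      warn_clamp = FALSE)
    phat <- pmax(pmin(cells$p0_min[i] * g, 1 - 1e-12), 1e-12)
    w <- 1 / (phat * (1 - phat))
    p0 <- clamp01(sum(w * pn * g) / sum(w * g * g))
    p0w[i] <- p0
    rssw[i] <- sum(w * (pn - p0 * g)^2)
  }
  best <- which.min(rssw)
  list(surface = data.frame(s = cells$s, mu = cells$mu, p0_min = p0w,
                            rss = rssw),
       best = list(s = cells$s[best], mu = cells$mu[best], p0 = p0w[best],
                   rss = rssw[best]))
}

# ---- S3 methods -------------------------------------------------------

#' @export
print.introg_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf("Introgression selection fit (%s, t = %s, window %g cM)\n",
              x$mode, format(x$t), x$window_cM))
  cat(sprintf("  %d SNPs, %d x %d (s, mu) grid\n", x$n_snps,
              length(x$grid$s), length(x$grid$mu)))
  cat(sprintf("  p0 = %.4g   s = %.4g   mu = %.4g   mu*s = %.4g\n",
              b$p0, b$s, b$mu, b$mus))
  cat(sprintf("  RSS = %.6g\n", b$rss))
  invisible(x)
}

#' Coefficients of an introgression selection fit
#'
#' @param object an `introg_fit`.
#' @param ... unused.
#' @return Named vector `c(p0, s, mu, mus)`.
#' @export
coef.introg_fit <- function(object, ...) {
  b <- object$best
  c(p0 = b$p0, s = b$s, mu = b$mu, mus = b$mus)
}

#' @export
summary.introg_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.introg_fit")
}

#' @export
print.summary.introg_fit <- function(x, ...) {
  print(x$fit)
  s <- x$fit$surface
  cat("\nScaled RSS surface (RSS_min - RSS) summary:\n")
  print(summary(x$fit$best$rss - s$rss))
  near <- s[s$rss <= x$fit$best$rss * 1.0001, , drop = FALSE]
  cat(sprintf("\n%d of %d grid cells within 0.01%% of the minimum RSS\n",
              nrow(near), nrow(s)))
  invisible(x)
}

#' Model-expected frequencies from a fit
#'
#' @param object an `introg_fit`.
#' @param params optional [model_params()] to predict under parameters
#'   other than the fitted ones.
#' @param ... unused.
#' @return Per-SNP expected frequencies `p0 * g_l`.
#' @export
predict.introg_fit <- function(object, params = NULL, ...) {
  if (is.null(params)) return(object$best$p0 * object$g_hat)
  stopifnot(inherits(params, "model_params"))
  params$p0 * g_from_pairs(object$pairs, params$s, params$mu, params$t,
                           params$mode, warn_clamp = FALSE)
}

#' @export
fitted.introg_fit <- function(object, ...) object$best$p0 * object$g_hat

#' @export
residuals.introg_fit <- function(object, ...) {
  object$calls$pn - fitted(object)
}

#' Simulate call tables from a fitted model
#'
#' Parametric resampling: regenerates observed frequencies on the fitted
#' genome geometry with the fitted `(p0, s, mu)` as truth and
#' Balding-Nichols drift noise.
#'
#' @param object an `introg_fit`.
#' @param nsim number of simulated call tables.
#' @param seed optional integer seed.
#' @param Ne,t_drift drift-noise parameters (see [synthetic_calls()]).
#' @param ... unused.
#' @return A list of `nsim` [call_table()] objects.
#' @export
simulate.introg_fit <- function(object, nsim = 1, seed = NULL,
                                Ne = 10000, t_drift = 2000, ...) {
  m <- fitted(object)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    pn <- drift_noise(m, Ne, t_drift)
    call_table(object$calls$chrom, object$calls$pos, pn)
  }))
}

#' Plot the scaled profile RSS surface
#'
#' Image of `RSS_min - RSS` over the `(s, mu)` grid (darker = better),
#' with the optimum marked.
#'
#' @param x an `introg_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.introg_fit <- function(x, ...) {
  z <- matrix(x$best$rss - x$surface$rss, nrow = length(x$grid$mu))
  graphics::image(log10(x$grid$s), log10(x$grid$mu), t(z),
                  col = grDevices::hcl.colors(64, "Oranges"),
                  xlab = "log10(s)", ylab = "log10(mu)",
                  main = "Scaled profile RSS (RSS_min - RSS)", ...)
  graphics::points(log10(x$best$s), log10(x$best$mu), pch = 4, lwd = 2)
  invisible(x)
}
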