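# Blockwise bootstrap confidence intervals.

#' Assign SNPs to non-overlapping genetic blocks
#'
#' Tiles each chromosome with blocks of `block_cM` centimorgans starting
#' at the chromosome's first SNP; a SNP at genetic position `g` falls in
#' the right-open interval `[start + k*block_cM, start + (k+1)*block_cM)`.
#' Partial terminal blocks are kept; tiles containing no SNP carry no data
#' and are dropped.
#'
#' @param calls a [call_table()] with genetic positions (`gpos`).
#' @param block_cM block length in cM (default 5).
#' @return A list with `block` (0-based dense block index per SNP),
#'   `n_blocks`, and `block_chrom` (chromosome of each block).
#' @export
assign_blocks <- function(calls, block_cM = 5) {
  stopifnot(inherits(calls, "call_table"), block_cM > 0)
  if (is.null(calls$gpos))
    stop("call table has no genetic positions; use annotate_calls() first")
  block <- integer(nrow(calls))
  chroms <- character(0)
  nb <- 0L
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    raw <- floor((calls$gpos[i] - min(calls$gpos[i])) / block_cM)
    ids <- sort(unique(raw))
    block[i] <- nb + match(raw, ids) - 1L
    nb <- nb + length(ids)
    chroms <- c(chroms, rep(ch, length(ids)))
  }
  list(block = block, n_blocks = nb, block_chrom = chroms)
}

# reassemble the profile surface for a weighted multiset of blocks
refit_from_counts <- function(fit, counts) {
  bs <- fit$block_sums
  stopifnot(length(counts) == nrow(bs$num))
  num <- drop(crossprod(bs$num, counts))
  den <- drop(crossprod(bs$den, counts))
  pn2 <- sum(bs$pn2 * counts)
  profile_surface(num, den, pn2, fit$grid$s, fit$grid$mu)
}

#' Blockwise bootstrap of an introgression selection fit
#'
#' Resamples 5-cM blocks with replacement, chromosome by chromosome (each
#' bootstrap chromosome has as many blocks as the original), reassembles
#' the RSS objective on the fitted fine grid from the stored per-block
#' sufficient statistics, re-optimizes `(s, mu, p0)` for each replicate
#' genome, and reports 2.5% / 97.5% percentile confidence intervals for
#' `p0`, `s`, `mu` and the compound parameter `mu*s`.
#'
#' @param fit an [fit_introgression()] result.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer seed; replicates are fully reproducible
#'   given the seed.
#' @return An object of class `introg_boot` with elements `replicates`
#'   (one row per replicate) and `ci`.
#' @export
bootstrap_fit <- function(fit, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(fit, "introg_fit"))
  if (n_boot < 2) stop("n_boot must be at least 2")
  bs <- fit$block_sums
  nb <- nrow(bs$num)
  chrom <- bs$block_chrom
  with_seed(seed, {
    W <- matrix(0, nb, n_boot)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      k <- length(idx)
      draw <- matrix(sample.int(k, k * n_boot, replace = TRUE), k, n_boot)
      W[idx, ] <- apply(draw, 2, tabulate, nbins = k)
    }
    NUM <- crossprod(bs$num, W)          # n_cells x n_boot
    DEN <- crossprod(bs$den, W)
    PN2 <- drop(crossprod(bs$pn2, W))
    P0 <- clamp01(NUM / DEN)
    RSS <- sweep(-2 * P0 * NUM + P0^2 * DEN, 2, PN2, "+")
    best <- apply(RSS, 2, which.min)
    cells <- expand.grid(mu = fit$grid$mu, s = fit$grid$s)[, 2:1]
    rep_df <- data.frame(
      s = cells$s[best], mu = cells$mu[best],
      p0 = P0[cbind(best, seq_len(n_boot))],
      rss = pmax(RSS[cbind(best, seq_len(n_boot))], 0))
    rep_df$mus <- rep_df$s * rep_df$mu
    ci <- t(vapply(c("p0", "s", "mu", "mus"), function(p)
      quantile(rep_df[[p]], c(0.025, 0.975), names = FALSE),
      numeric(2)))
    colnames(ci) <- c("2.5%", "97.5%")
    structure(list(replicates = rep_df, ci = ci, n_boot = n_boot,
                   seed = seed, best = fit$best),
              class = "introg_boot", counts = W)
  })
}

#' @export
print.introg_boot <- function(x, ...) {
  cat(sprintf("Blockwise bootstrap: %d replicates\n", x$n_boot))
  est <- c(p0 = x$best$p0, s = x$best$s, mu = x$best$mu, mus = x$best$mus)
  out <- cbind(estimate = est, x$ci)
  print(signif(out, 4))
  invisible(x)
}

#' Bootstrap confidence intervals for a fit
#'
#' @param object an `introg_fit`.
#' @param parm parameters to report (subset of `p0`, `s`, `mu`, `mus`).
#' @param level confidence level (percentile intervals).
#' @param n_boot,seed passed to [bootstrap_fit()].
#' @param ... unused.
#' @return Matrix of lower/upper bounds.
#' @export
confint.introg_fit <- function(object, parm = c("p0", "s", "mu", "mus"),
                               level = 0.95, n_boot = 1000, seed = NULL,
                               ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  bt <- bootstrap_fit(object, n_boot = n_boot, seed = seed)
  a <- (1 - level) / 2
  ci <- t(vapply(parm, function(p)
    quantile(bt$replicates[[p]], c(a, 1 - a), names = FALSE), numeric(2)))
  colnames(ci) <- sprintf("%.1f%%", 100 * c(a, 1 - a))
  ci
}

#' Plot bootstrap replicate estimates
#'
#' Scatter of `p0` against `mu*s` across replicates, visualizing the
#' confounding ridge between the initial admixture proportion and the
#' per-exonic-base strength of selection.
#'
#' @param x an `introg_boot`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.introg_boot <- function(x, ...) {
  graphics::plot(x$replicates$mus, x$replicates$p0,
                 xlab = "mu * s", ylab = "p0",
                 main = "Bootstrap estimates", pch = 16,
                 col = grDevices::adjustcolor("grey30", 0.4), ...)
  graphics::points(x$best$mus, x$best$p0, pch = 4, col = 2, lwd = 2)
  invisible(x)
}
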