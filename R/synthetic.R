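# Synthetic input data with the statistical structure the inference assumes.

#' Generate a synthetic genome (map, exons, SNP positions)
#'
#' Builds a piecewise-linear genetic map with optional lognormal
#' recombination-rate heterogeneity, an exon annotation from a renewal
#' process (exponential lengths and gaps), and SNP positions on a jittered
#' regular grid in genetic coordinates. Defaults emulate a genome of 22
#' chromosomes of 150 cM / 150 Mb with ~3% exonic sequence in merged exon
#' clusters of mean 1200 bp, and ~50,000 SNPs genome-wide.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_cM,chrom_Mb genetic and physical chromosome length.
#' @param rate_sdlog lognormal sd of per-segment recombination rates
#'   (0 gives a uniform map).
#' @param rate_segment_Mb length of constant-rate map segments.
#' @param exon_mean_bp,exon_gap_bp mean exon length and mean inter-exon
#'   gap of the renewal process (set `exon_gap_bp = Inf` for no exons).
#' @param snp_spacing_cM mean SNP spacing in genetic coordinates.
#' @param snp_jitter jitter as a fraction of the spacing.
#' @param seed optional integer seed; identical seeds give identical
#'   genomes.
#' @return A list of class `synthetic_genome` with elements `map`
#'   ([genetic_map()]), `exons` ([exon_annotation()]) and `snps`
#'   (data.frame of chrom, pos).
#' @export
synthetic_genome <- function(n_chrom = 22, chrom_cM = 150, chrom_Mb = 150,
                             rate_sdlog = 0.3, rate_segment_Mb = 5,
                             exon_mean_bp = 1200, exon_gap_bp = 36000,
                             snp_spacing_cM = 0.066, snp_jitter = 0.25,
                             seed = NULL) {
  stopifnot(n_chrom >= 1, chrom_cM > 0, chrom_Mb > 0, exon_mean_bp >= 1,
            snp_spacing_cM > 0)
  with_seed(seed, {
    L <- round(chrom_Mb * 1e6)
    seg <- round(rate_segment_Mb * 1e6)
    map_l <- list(); ex_l <- list(); snp_l <- list()
    for (k in seq_len(n_chrom)) {
      ch <- paste0("chr", k)
      bp <- seq(0, L, by = seg)
      if (bp[length(bp)] < L) bp <- c(bp, L)
      nseg <- length(bp) - 1L
      rate <- if (rate_sdlog > 0) rlnorm(nseg, sdlog = rate_sdlog) else rep(1, nseg)
      cm <- c(0, cumsum(rate * diff(bp)))
      cm <- cm * (chrom_cM / cm[length(cm)])
      map_l[[k]] <- data.frame(chrom = ch, pos = bp, cM = cm)

      if (is.finite(exon_gap_bp) && exon_gap_bp > 0) {
        n_guess <- ceiling(1.3 * L / (exon_mean_bp + exon_gap_bp)) + 10
        gaps <- rexp(n_guess, 1 / exon_gap_bp)
        # exponential lengths truncated to a realistic range for merged
        # exon clusters
        lens <- pmin(pmax(round(rexp(n_guess, 1 / exon_mean_bp)), 50), 6000)
        st <- cumsum(gaps + c(0, lens[-n_guess]))
        keep <- st + lens < L
        if (any(keep))
          ex_l[[length(ex_l) + 1L]] <- data.frame(
            chrom = ch, start = round(st[keep]),
            end = round(st[keep]) + lens[keep])
      }

      g <- seq(snp_spacing_cM / 2, chrom_cM - snp_spacing_cM / 2,
               by = snp_spacing_cM)
      g <- g + runif(length(g), -snp_jitter, snp_jitter) * snp_spacing_cM
      g <- pmin(pmax(g, 0), chrom_cM)
      pos <- round(stats::approx(cm, bp, xout = g, ties = "ordered")$y)
      pos <- unique(sort(pos))
      snp_l[[k]] <- data.frame(chrom = ch, pos = pos)
    }
    mp <- do.call(rbind, map_l)
    ex <- if (length(ex_l)) do.call(rbind, ex_l) else NULL
    structure(list(
      map = genetic_map(mp$chrom, mp$pos, mp$cM),
      exons = if (is.null(ex))
        structure(data.frame(chrom = character(), start = numeric(),
                             end = numeric(), midpoint = numeric(),
                             length = numeric()),
                  class = c("exon_annotation", "data.frame"))
        else exon_annotation(ex$chrom, ex$start, ex$end),
      snps = do.call(rbind, snp_l)), class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosomes, %d exons, %d SNPs\n",
              length(unique(x$map$chrom)), nrow(x$exons), nrow(x$snps)))
  invisible(x)
}

# Balding-Nichols drift noise around a mean frequency: Beta with the given
# mean and variance m(1-m)*F, F = 1 - (1 - 1/(2Ne))^t (the neutral drift
# variance accumulated over t generations)
drift_noise <- function(m, Ne, t) {
  F <- 1 - pow1m(1 / (2 * Ne), t)
  k <- (1 - F) / F
  out <- numeric(length(m))
  pos <- m > 0 & m < 1
  out[pos] <- rbeta(sum(pos), m[pos] * k, (1 - m[pos]) * k)
  out[!pos] <- m[!pos]
  out
}

#' Generate synthetic introgressed-allele frequency calls
#'
#' Produces a [call_table()] whose per-SNP mean follows the linked-selection
#' model `E[p_n] = p0 * g_l(r, s, t, mu)` on a synthetic genome, with a
#' choice of noise around the mean:
#' \describe{
#'   \item{`"drift"`}{Balding-Nichols Beta noise with variance
#'     `m (1-m) (1 - (1 - 1/(2*Ne))^t_drift)`, the neutral drift variance
#'     (the default; `Ne = 10000`, `t_drift = 2000`).}
#'   \item{`"binomial"`}{sampling noise, `Binomial(n_samples, m)/n_samples`.}
#'   \item{`"none"`}{exact model means.}
#' }
#'
#' With `mechanistic = TRUE` the mean is instead built by placing actual
#' selected sites (each exon carries one with probability `min(mu*l, 1)`)
#' and applying the single-site reduction factor of the nearest selected
#' exon, which matches the mixture expectation on average.
#'
#' @param genome a [synthetic_genome()].
#' @param p0,s,mu,t,mode true model parameters (defaults near genome-wide
#'   autosomal estimates for European samples: p0 0.0338, s 4.12e-4,
#'   mu 8.1e-5, t 2000).
#' @param window_cM window used to evaluate the model mean.
#' @param noise noise model.
#' @param Ne,t_drift drift-noise parameters.
#' @param n_samples binomial sample size.
#' @param mechanistic place explicit selected sites instead of using the
#'   mixture expectation.
#' @param seed optional integer seed.
#' @return A [call_table()] with genetic positions attached.
#' @export
synthetic_calls <- function(genome, p0 = 0.0338, s = 4.12e-4, mu = 8.1e-5,
                            t = 2000, mode = c("autosome", "X"),
                            window_cM = 1,
                            noise = c("drift", "binomial", "none"),
                            Ne = 10000, t_drift = 2000, n_samples = 1000,
                            mechanistic = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  stopifnot(inherits(genome, "synthetic_genome"))
  calls <- call_table(genome$snps$chrom, genome$snps$pos,
                      rep(0, nrow(genome$snps)), map = genome$map)
  with_seed(seed, {
    if (mechanistic) {
      m <- mechanistic_means(calls, genome, p0, s, mu, t, mode, window_cM)
    } else {
      g <- expected_g(calls, genome$exons, genome$map, s, mu, t, mode,
                      window_cM)
      m <- p0 * g
    }
    calls$pn <- switch(noise,
      none = m,
      binomial = rbinom(length(m), n_samples, m) / n_samples,
      drift = drift_noise(m, Ne, t_drift))
    calls
  })
}

# explicit selected-site placement: each exon is selected with probability
# min(mu*l, 1); a SNP's frequency is p0 * f(r) to the nearest selected
# exon midpoint within its window (p0 if none)
mechanistic_means <- function(calls, genome, p0, s, mu, t, mode, window_cM) {
  exons <- genome$exons
  sel <- runif(nrow(exons)) < pmin(mu * exons$length, 1)
  m <- rep(p0, nrow(calls))
  if (!any(sel)) return(m)
  sel_ex <- exons[sel, , drop = FALSE]
  class(sel_ex) <- c("exon_annotation", "data.frame")
  pairs <- site_windows(calls, sel_ex, genome$map, window_cM)
  first <- pairs$off[seq_len(pairs$n_snp)] + 1L
  has <- diff(pairs$off) > 0L
  r1 <- pairs$r[first[has]]
  f <- if (mode == "X") f_xchr(r1, s, t) else f_autosome(r1, s, t)
  m[has] <- p0 * f
  m
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the three input files the fitting pipeline reads: `map.tsv`,
#' `exons.bed` and `calls.tsv`.
#'
#' @param genome a [synthetic_genome()].
#' @param calls a [call_table()].
#' @param dir output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(genome, calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, "map.tsv"),
             exons = file.path(dir, "exons.bed"),
             calls = file.path(dir, "calls.tsv"))
  write_genetic_map(genome$map, paths["map"])
  write_exons(genome$exons, paths["exons"])
  write_calls(calls, paths["calls"])
  invisible(paths)
}
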