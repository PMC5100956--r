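# Exon-density diagnostic: observed vs predicted frequency by gene density.

#' Observed vs predicted frequency binned by exon density
#'
#' Splits the genome into segments of `segment_cM` centimorgans, counts
#' exonic bases per segment (exons assigned by midpoint), ranks the
#' segments by exon content and groups them into `n_bins` bins of equal
#' segment count. For each bin the mean observed frequency and the mean
#' model-predicted frequency are reported, along with the segment-level
#' Pearson correlation between observed and predicted means. Under the
#' fitted model, predicted means decrease with exon-density rank; good
#' agreement with the observed means indicates the model captures the
#' relationship between functional density, recombination and
#' introgression levels.
#'
#' Bins whose segments all contain zero exonic bases are collapsed into
#' one (rank ties carry no ordering information); if there are fewer
#' segments than requested bins, the bin count is reduced with a warning.
#'
#' @param fit an [fit_introgression()] result.
#' @param segment_cM segment length in cM (0.5, 1, 1.5 and 2 supported).
#' @param n_bins number of exon-density bins (default 10).
#' @param exons optional [exon_annotation()]; defaults to reusing the
#'   fit's window exon content is not possible, so pass the annotation
#'   used for fitting.
#' @param map the [genetic_map()] used for fitting.
#' @return An object of class `introg_diag`: list with `bins` (per-bin
#'   means), `segments` (per-segment summaries) and `pearson`.
#' @export
exon_density_diagnostic <- function(fit, exons, map, segment_cM = 1,
                                    n_bins = 10) {
  stopifnot(inherits(fit, "introg_fit"), segment_cM > 0, n_bins >= 1)
  calls <- fit$calls
  pred <- fitted(fit)
  seg_of <- function(chrom, gpos) {
    id <- integer(length(gpos))
    base <- 0L
    for (ch in unique(calls$chrom)) {
      i <- which(chrom == ch)
      ic <- which(calls$chrom == ch)
      g0 <- min(calls$gpos[ic])
      if (length(i)) id[i] <- base + as.integer(floor((gpos[i] - g0) / segment_cM))
      base <- base + as.integer(ceiling((max(calls$gpos[ic]) - g0 + 1e-9) / segment_cM))
    }
    id
  }
  snp_seg <- seg_of(calls$chrom, calls$gpos)
  em <- exons[exons$chrom %in% unique(calls$chrom), , drop = FALSE]
  eg <- numeric(nrow(em))
  for (ch in unique(em$chrom)) {
    i <- em$chrom == ch
    eg[i] <- interpolate_cM(map, ch, em$midpoint[i])
  }
  ex_seg <- seg_of(em$chrom, eg)

  segs <- sort(unique(snp_seg))
  obs <- as.vector(rowsum(calls$pn, snp_seg)) / tabulate(factor(snp_seg, segs))
  prd <- as.vector(rowsum(pred, snp_seg)) / tabulate(factor(snp_seg, segs))
  exbp <- vapply(segs, function(sg) sum(em$length[ex_seg == sg]), numeric(1))

  nseg <- length(segs)
  if (nseg < n_bins) {
    warning("fewer segments (", nseg, ") than bins; reducing bins")
    n_bins <- nseg
  }
  rk <- rank(exbp, ties.method = "first")
  bin <- ceiling(rk / (nseg / n_bins))
  # collapse bins made entirely of zero-exon segments
  zero_bins <- vapply(split(exbp, bin), function(v) all(v == 0), logical(1))
  if (sum(zero_bins) > 1) {
    first0 <- min(as.integer(names(zero_bins)[zero_bins]))
    bin[bin %in% as.integer(names(zero_bins)[zero_bins])] <- first0
    bin <- match(bin, sort(unique(bin)))
  }
  bins <- data.frame(
    bin = sort(unique(bin)),
    n_segments = as.vector(table(bin)),
    mean_exonic_bp = as.vector(tapply(exbp, bin, mean)),
    observed = as.vector(tapply(obs, bin, mean)),
    predicted = as.vector(tapply(prd, bin, mean)))
  structure(list(bins = bins,
                 segments = data.frame(segment = segs, exonic_bp = exbp,
                                       observed = obs, predicted = prd,
                                       bin = bin),
                 pearson = cor(obs, prd)),
            class = "introg_diag")
}

#' @export
print.introg_diag <- function(x, ...) {
  cat("Exon-density diagnostic\n")
  print(x$bins, row.names = FALSE, digits = 4)
  cat(sprintf("Segment-level Pearson correlation (obs, pred): %.3f\n",
              x$pearson))
  invisible(x)
}

#' @export
plot.introg_diag <- function(x, ...) {
  rng <- range(c(x$bins$observed, x$bins$predicted))
  graphics::plot(x$bins$bin, x$bins$observed, ylim = rng, pch = 16,
                 xlab = "exon density rank (low to high)",
                 ylab = "mean introgressed-allele frequency", ...)
  graphics::points(x$bins$bin, x$bins$predicted, pch = 2, col = 2)
  graphics::legend("topright", c("observed", "predicted"),
                   pch = c(16, 2), col = c(1, 2), bty = "n")
  invisible(x)
}
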