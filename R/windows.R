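# Batch construction of per-SNP linked-exon windows.
#
# The window geometry depends only on the map, the exons and the window
# size -- not on (s, mu) -- so it is computed once per fit and cached as a
# flat pair representation: for SNP i the pairs off[i]+1 .. off[i+1] (in
# 1-based R indexing) hold the recombination fractions and lengths of its
# window exons, nearest first.

site_windows <- function(calls, exons, map, window_cM = 1) {
  stopifnot(inherits(calls, "call_table"), inherits(exons, "exon_annotation"),
            window_cM > 0)
  if (is.null(calls$gpos)) calls <- annotate_calls(calls, map)
  n <- nrow(calls)
  h <- window_cM / 2
  counts <- integer(n)
  r_list <- vector("list", 0L)
  snp_list <- vector("list", 0L)
  l_list <- vector("list", 0L)
  d_all <- rep(list(NULL), 0L)
  pieces <- list()
  for (ch in unique(calls$chrom)) {
    si <- which(calls$chrom == ch)
    ei <- which(exons$chrom == ch)
    if (!length(ei)) next
    gmid <- interpolate_cM(map, ch, exons$midpoint[ei])
    gs <- calls$gpos[si]
    lo <- findInterval(gs - h, gmid, left.open = TRUE) + 1L
    hi <- findInterval(gs + h, gmid)
    cnt <- pmax(hi - lo + 1L, 0L)
    counts[si] <- cnt
    if (!sum(cnt)) next
    keep <- cnt > 0L
    eidx <- sequence(cnt[keep], from = lo[keep])
    sidx <- rep(si[keep], cnt[keep])
    pieces[[length(pieces) + 1L]] <- data.frame(
      snp = sidx,
      d = abs(gmid[eidx] - calls$gpos[sidx]),
      start = exons$start[ei][eidx],
      len = exons$length[ei][eidx])
  }
  if (!length(pieces)) {
    return(list(r = numeric(0), l = numeric(0),
                off = rep(0L, n + 1L), n_snp = n))
  }
  p <- do.call(rbind, pieces)
  p <- p[order(p$snp, p$d, p$start), , drop = FALSE]
  off <- c(0L, cumsum(tabulate(p$snp, nbins = n)))
  list(r = recomb_fraction(p$d), l = p$len, off = as.integer(off), n_snp = n)
}

# per-SNP g values from a pair representation (pure R; the C++ grid path
# is the production route and this is its cross-check and single-cell API)
g_from_pairs <- function(pairs, s, mu, t, mode, warn_clamp = TRUE) {
  n <- pairs$n_snp
  g <- rep(1, n)
  if (mu == 0 || !length(pairs$r)) return(g)
  f <- if (mode == "X") f_xchr(pairs$r, s, t) else f_autosome(pairs$r, s, t)
  ml <- mu * pairs$l
  if (any(ml >= 1)) {
    if (warn_clamp) warning("mu * length >= 1 for some exons; clamping to 1")
    ml <- pmin(ml, 1)
  }
  counts <- diff(pairs$off)
  grp <- rep(seq_len(n), counts)
  logq <- log1p(-ml)
  logq[!is.finite(logq)] <- -745  # clamped ml = 1: zero weight downstream
  cs0 <- c(0, cumsum(logq))
  start_cs <- cs0[pairs$off[grp] + 1L]
  before <- exp(cs0[seq_along(ml)] - start_cs)
  w <- ml * before
  with_pairs <- which(counts > 0L)
  gsum <- rowsum(w * f, grp)
  resid <- exp(cs0[pairs$off[with_pairs + 1L] + 1L] - cs0[pairs$off[with_pairs] + 1L])
  g[with_pairs] <- as.vector(gsum) + resid
  g
}
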