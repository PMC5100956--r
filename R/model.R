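# Deterministic single-linked-site model of the expected present-day
# frequency of a neutral introgressed allele.
#
# A neutral allele N1 enters the recipient population at frequency p0, on a
# haplotype carrying a deleterious allele S1 (fixed in the donor) at a
# linked selected site. Heterozygous (or hemizygous, on the X) carriers of
# S1 have relative fitness 1 - s; homozygous S1 carriers are ignored as
# vanishingly rare. After t generations E[p_t] = p0 * f(r, s, t).

#' Reduction factor for a neutral introgressed allele, autosomal transmission
#'
#' Expected frequency of a neutral introgressed allele linked (at
#' recombination fraction `r`) to a deleterious allele with heterozygote
#' fitness `1 - s`, `t` generations after a single admixture pulse, as a
#' fraction of the initial admixture proportion:
#' \deqn{f_a(r,s,t) = \frac{[(1-s)(1-r)]^t [1 - r - (1-s)(1-r)] + r}{1 - (1-s)(1-r)}.}
#'
#' Powers are evaluated in log space (`exp(t*log1p(-x))`), so the function
#' is stable for `t` up to at least 1e7. `t = Inf` routes to
#' [f_autosome_equilibrium()].
#'
#' @param r recombination fraction between the neutral and selected site,
#'   in \[0, 0.5\].
#' @param s selection coefficient against a heterozygous carrier, in \[0, 1).
#' @param t generations since admixture (non-negative; may be `Inf`).
#' @return The fraction `f` in \[0, 1\] such that `E[p_t] = p0 * f`.
#'   Arguments are recycled to a common length.
#' @seealso [f_xchr()], [haplotype_recursion()]
#' @examples
#' f_autosome(0, 4e-4, 2000)       # unlinked-site decay (1-s)^t
#' f_autosome(0.001, 4e-4, 2000)
#' @export
f_autosome <- function(r, s, t) {
  check_rst(r, s, t)
  n <- max(length(r), length(s), length(t))
  r <- rep_len(r, n); s <- rep_len(s, n); t <- rep_len(t, n)
  if (any(r == 0 & s == 0 & is.infinite(t)))
    stop("f_autosome: r = s = 0 with t = Inf is degenerate")
  denom <- s + r - s * r
  f <- numeric(n)
  eq <- is.infinite(t)
  if (any(eq)) f[eq] <- r[eq] / denom[eq]
  if (any(!eq)) {
    At <- pow1m(s[!eq], t[!eq]) * pow1m(r[!eq], t[!eq])
    f[!eq] <- (At * (1 - r[!eq]) * s[!eq] + r[!eq]) / denom[!eq]
  }
  f[s == 0 & !eq] <- 1
  f[s == 0 & eq & r > 0] <- 1
  f
}

#' Equilibrium (gene flow factor) limit of the autosomal reduction factor
#'
#' The long-time limit of [f_autosome()],
#' `r / (1 - (1-s)(1-r))`, i.e. the classical gene flow factor of a
#' single barrier locus: the equilibrium fraction of neutral gene flow that
#' survives linked selection.
#'
#' @inheritParams f_autosome
#' @return Equilibrium fraction in \[0, 1\]. Requires `r + s > 0`.
#' @export
f_autosome_equilibrium <- function(r, s) {
  check_rst(r, s, 0)
  n <- max(length(r), length(s))
  r <- rep_len(r, n); s <- rep_len(s, n)
  if (any(r == 0 & s == 0))
    stop("f_autosome_equilibrium: degenerate input r = s = 0")
  f <- r / (s + r - s * r)
  f[s == 0] <- 1
  f
}

#' Reduction factor for a neutral introgressed allele on the non-PAR X
#'
#' X-chromosomal analogue of [f_autosome()]. The non-pseudoautosomal X does
#' not recombine in males and spends 2/3 of its time in females, so the
#' female recombination fraction `r` enters as an effective per-generation
#' rate of (2/3) r, while selection (heterozygous females, hemizygous
#' males, both with fitness `1 - s`) acts every generation:
#' \deqn{f_X(r,s,t) = \frac{s\,(1-\tfrac{2}{3}r)^{t+1}(1-s)^t + \tfrac{2}{3}r}{1 - (1-\tfrac{2}{3}r)(1-s)}.}
#'
#' @param r female recombination fraction between the two sites, in \[0, 0.5\].
#' @inheritParams f_autosome
#' @return The fraction `f` in \[0, 1\]; `t = Inf` gives the equilibrium
#'   limit.
#' @export
f_xchr <- function(r, s, t) {
  check_rst(r, s, t)
  n <- max(length(r), length(s), length(t))
  r <- rep_len(r, n); s <- rep_len(s, n); t <- rep_len(t, n)
  if (any(r == 0 & s == 0 & is.infinite(t)))
    stop("f_xchr: r = s = 0 with t = Inf is degenerate")
  b <- (2 / 3) * r
  denom <- s + b - s * b
  f <- numeric(n)
  eq <- is.infinite(t)
  if (any(eq)) f[eq] <- b[eq] / denom[eq]
  if (any(!eq))
    f[!eq] <- (s[!eq] * pow1m(b[!eq], t[!eq] + 1) * pow1m(s[!eq], t[!eq]) +
                 b[!eq]) / denom[!eq]
  f[s == 0 & !eq] <- 1
  f[s == 0 & eq & r > 0] <- 1
  f
}

#' @rdname f_xchr
#' @export
f_xchr_equilibrium <- function(r, s) f_xchr(r, s, Inf)

#' Iterated two-locus haplotype recursion (validation oracle)
#'
#' Iterates the deterministic haplotype-frequency recursion for a neutral
#' introgressed allele N1 linked to a deleterious allele S1 and returns the
#' frequency of N1 after `t` generations. The recursion is linear in the
#' introgressed haplotype frequencies (the resident background is treated
#' as fixed and every S1 copy sits in a heterozygote, i.e. homozygous S1
#' carriers are ignored): each generation, recombination first moves a
#' fraction `r` of N1S1 haplotypes onto the neutral resident background,
#' then selection multiplies the remaining N1S1 class by `1 - s`.
#'
#' For `mode = "X"` the recursion uses the effective per-generation
#' recombination rate (2/3) `r` (the non-PAR X recombines only in females,
#' where it spends 2/3 of its time) with selection `1 - s` every
#' generation; this is exactly the recursion whose solution is
#' [f_xchr()]. An explicit two-sex recursion that tracks female and male
#' haplotype pools separately is available via `two_sex = TRUE`; it agrees
#' with [f_xchr()] only to first order in `r` (differences of order 1e-5
#' on genome-like grids).
#'
#' This function is deliberately implemented as a generation-by-generation
#' loop, independent of the closed forms, and serves as their test oracle.
#'
#' @inheritParams f_autosome
#' @param p0 initial frequency of the introgressed N1S1 haplotype.
#' @param mode `"autosome"` or `"X"`.
#' @param two_sex for `mode = "X"`, iterate the explicit female/male
#'   two-pool recursion instead of the time-averaged one.
#' @return Frequency of the neutral introgressed allele after `t`
#'   generations (equals `p0 * f(r, s, t)` up to floating-point error for
#'   the default recursions).
#' @export
haplotype_recursion <- function(r, s, t, p0 = 1,
                                mode = c("autosome", "X"),
                                two_sex = FALSE) {
  mode <- match.arg(mode)
  check_rst(r, s, t)
  stopifnot(length(r) == 1, length(s) == 1, is.finite(t), t == round(t),
            p0 >= 0, p0 <= 1)
  if (mode == "X" && two_sex) {
    af <- p0; bf <- 0; am <- p0; bm <- 0
    for (i in seq_len(t)) {
      ae <- (1 - r) * af            # eggs: recombination in females
      be <- bf + r * af
      af2 <- (1 - s) * (ae + am) / 2  # daughters: one egg X, one sperm X
      bf2 <- (be + bm) / 2
      am2 <- (1 - s) * ae             # sons: egg X, hemizygous selection
      bm2 <- be
      af <- af2; bf <- bf2; am <- am2; bm <- bm2
    }
    return((2 / 3) * (af + bf) + (1 / 3) * (am + bm))
  }
  re <- if (mode == "X") (2 / 3) * r else r
  a <- p0   # introgressed haplotype still carrying the selected allele
  b <- 0    # introgressed neutral allele recombined onto resident background
  for (i in seq_len(t)) {
    d <- re * a
    a <- (1 - s) * (a - d)
    b <- b + d
  }
  a + b
}

#' Linked-exon context around a focal neutral site
#'
#' Bundles the recombination fractions and lengths of the exons in the
#' window around a focal SNP, ordered by increasing genetic distance. This
#' is the per-SNP input of the nearest-selected-exon mixture model.
#'
#' @param r recombination fractions to the exon midpoints, in \[0, 0.5\].
#' @param lengths exon lengths in bp (positive).
#' @return An object of class `linked_exon_context`.
#' @seealso [build_window()], [expected_frequency()]
#' @export
linked_exon_context <- function(r = numeric(), lengths = numeric()) {
  stopifnot(length(r) == length(lengths))
  if (length(r)) {
    if (any(r < 0 | r > 0.5)) stop("recombination fractions must be in [0, 0.5]")
    if (any(lengths <= 0)) stop("exon lengths must be positive")
    o <- order(r)
    r <- r[o]; lengths <- lengths[o]
  }
  structure(list(r = as.numeric(r), lengths = as.numeric(lengths)),
            class = "linked_exon_context")
}

#' @export
print.linked_exon_context <- function(x, ...) {
  cat("Linked-exon context:", length(x$r), "exon(s)\n")
  if (length(x$r))
    print(data.frame(r = x$r, length_bp = x$lengths), ...)
  invisible(x)
}

#' Model parameters for the introgression frequency model
#'
#' @param p0 effective initial admixture proportion, in \[0, 1\].
#' @param s selection coefficient against a heterozygous (or hemizygous)
#'   carrier, in \[0, 1).
#' @param t generations since the admixture pulse (non-negative; `Inf`
#'   selects the equilibrium model).
#' @param mu probability that an exonic base harbors a deleterious
#'   introgressed allele, in \[0, 1\].
#' @param mode `"autosome"` or `"X"`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(p0, s, t = 2000, mu = 0,
                         mode = c("autosome", "X")) {
  mode <- match.arg(mode)
  stopifnot(length(p0) == 1, p0 >= 0, p0 <= 1,
            length(s) == 1, s >= 0, s < 1,
            length(mu) == 1, mu >= 0, mu <= 1,
            length(t) == 1, t >= 0)
  structure(list(p0 = p0, s = s, t = t, mu = mu, mode = mode),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model parameters (%s, t = %s):\n  p0 = %g  s = %g  mu = %g\n",
              x$mode, format(x$t), x$p0, x$s, x$mu))
  invisible(x)
}

#' Nearest-selected-exon mixture weights
#'
#' Probability that the i-th nearest exon carries the (single) nearest
#' selected site: an exon of length `l` carries a selected site with
#' probability `mu * l`, so
#' `w_i = mu*l_i * prod_{j<i} (1 - mu*l_j)`, with a final residual weight
#' `prod_j (1 - mu*l_j)` for the case that no exon in the window carries
#' one. The weights sum to one by telescoping. Values of `mu * l >= 1`
#' (outside the model's `mu*l << 1` regime) are clamped to 1 with a
#' warning.
#'
#' @param ctx a [linked_exon_context()].
#' @param mu per-exonic-base probability of harboring a selected site.
#' @return Numeric vector of length `I + 1`: one weight per exon in `ctx`
#'   (nearest first) plus the residual weight last.
#' @export
nearest_exon_weights <- function(ctx, mu) {
  stopifnot(inherits(ctx, "linked_exon_context"), mu >= 0, mu <= 1)
  ml <- mu * ctx$lengths
  if (any(ml >= 1)) {
    warning("mu * length >= 1 for some exons; clamping to 1")
    ml <- pmin(ml, 1)
  }
  before <- cumprod(c(1, 1 - ml))
  c(ml * before[seq_along(ml)], before[length(before)])
}

#' Expected present-day frequency of a neutral introgressed allele
#'
#' Mixture over which exon in the window (if any) carries the nearest
#' selected site: `E[p_t] = p0 * ( sum_i w_i f(r_i, s, t) + w_resid )`,
#' with `f` the autosomal or X reduction factor according to
#' `params$mode`. Equals `p0` exactly when `mu = 0` or the window is
#' empty.
#'
#' @param ctx a [linked_exon_context()] for the focal site.
#' @param params a [model_params()] object.
#' @return Expected frequency in \[0, 1\].
#' @export
expected_frequency <- function(ctx, params) {
  stopifnot(inherits(ctx, "linked_exon_context"),
            inherits(params, "model_params"))
  if (params$mu == 0 || length(ctx$r) == 0) return(params$p0)
  w <- nearest_exon_weights(ctx, params$mu)
  f <- if (params$mode == "X") f_xchr(ctx$r, params$s, params$t)
       else f_autosome(ctx$r, params$s, params$t)
  params$p0 * (sum(w[seq_along(f)] * f) + w[length(w)])
}
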