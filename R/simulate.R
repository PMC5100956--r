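# Forward Wright-Fisher simulation of deleterious alleles in two diverging
# populations of unequal effective size.

#' Sample selection coefficients from a gamma distribution of fitness effects
#'
#' Draws `n` additive (no-dominance) deleterious selection coefficients
#' from a gamma DFE with the given shape and mean. Draws are truncated
#' just below 1 (a lethal bound irrelevant at the default parameters).
#'
#' @param n number of draws.
#' @param shape gamma shape parameter (default 0.184).
#' @param mean_s mean |s| (default 0.03).
#' @param seed optional integer seed.
#' @return Vector of `n` selection coefficients `>= 0`.
#' @export
sample_dfe <- function(n, shape = 0.184, mean_s = 0.03, seed = NULL) {
  if (shape <= 0 || mean_s <= 0 || mean_s >= 1)
    stop("invalid DFE: need shape > 0 and mean_s in (0, 1)")
  with_seed(seed, pmin(rgamma(n, shape = shape, scale = mean_s / shape),
                       0.999))
}

#' Simulate a population split with deleterious mutations
#'
#' Per-site forward Wright-Fisher simulation of unlinked exonic sites in
#' two populations that split `t_split` generations before secondary
#' contact: a small donor population (default diploid Ne 1000) and a
#' large recipient population (default Ne 10000). Each site carries a
#' deleterious allele with selection coefficient drawn from a gamma DFE
#' (additive: genotype fitnesses 1, 1-s, 1-2s), irreversible mutation
#' wild-type to deleterious at rate `u` per copy per generation, and
#' binomial resampling of `2*Ne` copies each generation.
#'
#' Standing ancestral variation is produced by a burn-in of `burn_in`
#' generations (default `10 * Ne_ancestral`) in an ancestral population of
#' size `Ne_ancestral` (default `Ne_recipient`); the split then seeds both
#' daughter populations binomially from the ancestral frequency.
#' Alternatively `init_freq` sets a fixed deterministic starting frequency
#' in both populations and skips the ancestral phase (useful for neutral
#' calibration checks). An optional bottleneck contracts the recipient to
#' `bottleneck$size` for the final `bottleneck$duration` generations
#' before contact.
#'
#' @param n_sites number of independently simulated sites.
#' @param Ne_donor,Ne_recipient diploid effective sizes after the split.
#' @param t_split generations between split and contact (default 20000).
#' @param u per-copy per-generation mutation rate (default 1e-8).
#' @param dfe_shape,dfe_mean gamma DFE parameters (see [sample_dfe()]).
#' @param Ne_ancestral diploid size of the ancestral population.
#' @param burn_in ancestral burn-in generations (default `10 * Ne_ancestral`).
#' @param init_freq optional fixed initial frequency (skips burn-in).
#' @param bottleneck optional `list(duration =, size =)` recipient
#'   bottleneck immediately before contact (duration 10-1000 generations
#'   in the intended regime).
#' @param s optional explicit vector of selection coefficients (overrides
#'   the DFE; recycled to `n_sites`).
#' @param seed optional integer seed.
#' @return A `data.frame` of class `split_sim` with columns `s`,
#'   `freq_donor`, `freq_recipient`; configuration stored in
#'   `attr(, "config")`.
#' @examples
#' sim <- simulate_split(n_sites = 1000, t_split = 500, seed = 1)
#' classify_fixed_differences(sim)
#' @export
simulate_split <- function(n_sites = 200000, Ne_donor = 1000,
                           Ne_recipient = 10000, t_split = 20000,
                           u = 1e-8, dfe_shape = 0.184, dfe_mean = 0.03,
                           Ne_ancestral = Ne_recipient, burn_in = NULL,
                           init_freq = NULL, bottleneck = NULL, s = NULL,
                           seed = NULL) {
  stopifnot(n_sites >= 1, Ne_donor >= 2, Ne_recipient >= 2,
            Ne_ancestral >= 2, t_split > 0, u >= 0)
  if (!is.null(bottleneck)) {
    stopifnot(is.list(bottleneck), !is.null(bottleneck$duration),
              !is.null(bottleneck$size), bottleneck$size >= 2,
              bottleneck$duration >= 1)
  }
  burn_in <- burn_in %||% (10 * Ne_ancestral)
  with_seed(seed, {
    svec <- if (is.null(s)) sample_dfe(n_sites, dfe_shape, dfe_mean)
            else rep_len(as.numeric(s), n_sites)
    if (any(svec < 0 | svec >= 1)) stop("selection coefficients must be in [0, 1)")
    res <- cpp_simulate_split(
      svec, as.integer(Ne_ancestral), as.integer(Ne_donor),
      as.integer(Ne_recipient), u, as.numeric(burn_in),
      as.numeric(t_split),
      as.integer(bottleneck$duration %||% 0),
      as.integer(bottleneck$size %||% 0),
      as.numeric(init_freq %||% -1), !is.null(init_freq))
    out <- data.frame(s = svec, freq_donor = res$freq_donor,
                      freq_recipient = res$freq_recipient)
    class(out) <- c("split_sim", "data.frame")
    attr(out, "config") <- list(
      n_sites = n_sites, Ne_donor = Ne_donor, Ne_recipient = Ne_recipient,
      t_split = t_split, u = u, dfe_shape = dfe_shape, dfe_mean = dfe_mean,
      Ne_ancestral = Ne_ancestral, burn_in = burn_in,
      init_freq = init_freq, bottleneck = bottleneck, seed = seed)
    out
  })
}

#' Fractions of population-specific fixed deleterious differences
#'
#' Bins simulated sites by selection coefficient and reports, per bin, the
#' fraction of sites where the deleterious allele is fixed in the donor
#' and absent from the recipient (donor-specific fixed difference), and
#' vice versa. All simulated sites, monomorphic ones included, enter the
#' denominators.
#'
#' @param sim a [simulate_split()] result.
#' @param s_breaks bin breaks for the selection coefficient; the default
#'   covers \[0, 1\] with half-decade log bins from 1e-6.
#' @return A `data.frame` with per-bin site counts and donor-/
#'   recipient-specific fixed-difference fractions.
#' @export
classify_fixed_differences <- function(sim,
                                       s_breaks = c(0, 10^seq(-6, 0, by = 0.5))) {
  stopifnot(inherits(sim, "split_sim"))
  if (any(sim$s < min(s_breaks)) || any(sim$s > max(s_breaks)))
    stop("s_breaks must span the simulated selection coefficients")
  bin <- cut(sim$s, breaks = s_breaks, include.lowest = TRUE)
  donor_fixed <- sim$freq_donor == 1 & sim$freq_recipient == 0
  recip_fixed <- sim$freq_recipient == 1 & sim$freq_donor == 0
  data.frame(
    bin = levels(bin),
    s_lo = s_breaks[-length(s_breaks)],
    s_hi = s_breaks[-1],
    n_sites = as.vector(table(bin)),
    donor_specific = as.vector(tapply(donor_fixed, bin, mean, default = NA)),
    recipient_specific = as.vector(tapply(recip_fixed, bin, mean, default = NA)))
}

#' @export
print.split_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Split simulation: %d sites, Ne donor %d / recipient %d, t = %d\n",
              nrow(x), cfg$Ne_donor, cfg$Ne_recipient, as.integer(cfg$t_split)))
  cat(sprintf("  donor-fixed & recipient-absent: %d sites (%.2g%%)\n",
              sum(x$freq_donor == 1 & x$freq_recipient == 0),
              100 * mean(x$freq_donor == 1 & x$freq_recipient == 0)))
  cat(sprintf("  recipient-fixed & donor-absent: %d sites (%.2g%%)\n",
              sum(x$freq_recipient == 1 & x$freq_donor == 0),
              100 * mean(x$freq_recipient == 1 & x$freq_donor == 0)))
  invisible(x)
}
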