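# Aggregate implications of the fitted parameters.

#' Genome-wide implications of weak selection against introgression
#'
#' Back-of-envelope quantities implied by the fitted strength and density
#' of selection:
#' \describe{
#'   \item{`freq_decline_pct`}{average percentage decline in frequency of
#'     an (unlinked) deleterious introgressed allele after `t`
#'     generations, `100 * (1 - (1-s)^t)`.}
#'   \item{`n_segregating_loci`}{expected number of exonic loci still
#'     segregating for deleterious introgressed alleles, `mu * exome_bp`.}
#'   \item{`f1_load_pct`}{multiplicative fitness reduction of a
#'     first-generation hybrid carrying one deleterious allele at each of
#'     `n_loci` loci, `100 * (1 - (1-s)^n_loci)`; `n_loci` defaults to
#'     `mu * exome_bp`.}
#' }
#'
#' @param s selection coefficient per deleterious allele.
#' @param mu per-exonic-base probability of harboring a deleterious
#'   allele.
#' @param t generations since admixture.
#' @param exome_bp total exonic target size in bp (default 82e6).
#' @param n_loci number of deleterious loci carried by an F1 hybrid;
#'   defaults to `mu * exome_bp`.
#' @return Named list with the three quantities above.
#' @examples
#' selection_implications(s = 4.12e-4, mu = 8.1e-5)
#' @export
selection_implications <- function(s, mu, t = 2000, exome_bp = 82e6,
                                   n_loci = NULL) {
  stopifnot(s >= 0, s < 1, mu >= 0, mu <= 1, t >= 0, exome_bp > 0)
  n <- n_loci %||% (mu * exome_bp)
  list(freq_decline_pct = 100 * (1 - pow1m(s, t)),
       n_segregating_loci = mu * exome_bp,
       f1_load_pct = 100 * (1 - pow1m(s, n)))
}

#' Recipe for external validation on published human data
#'
#' The package's acceptance-grade checks run entirely on synthetic data;
#' the genome-wide human point estimates (for example p0 = 0.0338 and
#' s = 4.12e-4 for European autosomes under t = 2000) additionally depend
#' on two published external inputs that are not redistributed here. This
#' function returns the steps needed to reproduce them.
#'
#' @return Character vector of steps.
#' @export
external_validation_recipe <- function() {
  c("1. Download the Neanderthal ancestry call tables of Sankararaman et al. (2014) from the Reich lab website: per-SNP average marginal probabilities that a haplotype carries a Neanderthal allele, for the EUR and ASN panels (hg19 coordinates).",
    "2. Convert each per-SNP record to the three-column call-table format (chrom, pos, pn) read by read_calls(); the marginal probability is used directly as the observed introgressed-allele frequency pn.",
    "3. Download the deCODE genetic map (Kong et al. 2010) and reformat to (chrom, pos, cumulative cM) for read_genetic_map(); download an exon list for hg19 (e.g. UCSC knownGene exons) as BED for read_exons().",
    "4. Run fit_introgression(calls, exons, map, t = 2000) per panel (mode = 'X' with the X-chromosome calls and female map for the X analysis), then bootstrap_fit(fit, n_boot = 1000) for 95% confidence intervals.",
    "5. Expect autosomal estimates near p0 ~ 0.034, s ~ 4e-4, mu ~ 8e-5 (EUR); results depend on the exact call set, map and exon list used.")
}
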