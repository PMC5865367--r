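#' Genomic estimated breeding values
#'
#' Evaluates the breeding-value sum over the SNP panel with estimated
#' effects: per SNP, `x(p a + q d) + (1 - x)(-q a + p d)` with `x` in
#' {1, 0.5, 0}. With `(p, q)` taken from the candidate's own breed this is
#' the GEBV for purebred performance (GEBV-P); with the opposite breed's
#' frequencies it is the GEBV for crossbred performance (GEBV-C). Reference
#' frequencies are computed from the SNP genotypes of all current selection
#' candidates of the relevant breed. Frequencies of 0 or 1 are legal.
#'
#' @param panel Candidate [hap_panel()].
#' @param fit A [brr_dom()] fit (or any list with elements `a` and `d`).
#' @param snp_idx SNP column indices in the haplotype matrix.
#' @param ref_freq Allele-1 frequencies at the SNPs in the reference breed.
#' @return Numeric vector of GEBVs.
#' @export
gebv <- function(panel, fit, snp_idx, ref_freq) {
  if (length(fit$a) != length(snp_idx))
    stop("alignment error: SNP set does not match estimates", call. = FALSE)
  breeding_value_kernel(dosage(panel, snp_idx), fit$a, fit$d, ref_freq)
}

#' Selection criterion
#'
#' Affine blend of the two genomic breeding values,
#' `SC = (1 - w) * GEBV-P + w * GEBV-C`, with no re-scaling of either
#' component. `w = 0` selects on purebred performance, `w = 1` on crossbred
#' performance.
#'
#' @param gebv_p,gebv_c Aligned GEBV vectors.
#' @param w Weight in `[0, 1]`.
#' @return Numeric vector of selection scores.
#' @export
selection_criterion <- function(gebv_p, gebv_c, w) {
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1)
    stop("configuration error: w must be a single value in [0, 1]", call. = FALSE)
  if (length(gebv_p) != length(gebv_c))
    stop("alignment error: GEBV vectors differ in length", call. = FALSE)
  (1 - w) * gebv_p + w * gebv_c
}

#' Accuracy of selection
#'
#' Pearson correlation between the selection criterion and the true breeding
#' value for crossbred performance, over the candidates of one breed.
#'
#' @param sc Selection-criterion scores.
#' @param tbv_c True breeding values for crossbred performance.
#' @return Pearson correlation.
#' @export
selection_accuracy <- function(sc, tbv_c) {
  if (length(sc) < 3L) stop("need at least 3 candidates", call. = FALSE)
  if (stats::sd(sc) == 0 || stats::sd(tbv_c) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(sc, tbv_c)
}
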