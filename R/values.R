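#' Genotypic values
#'
#' Sum over QTL of `+a` for the 1/1 homozygote, `d` for the heterozygote and
#' `-a` for the 0/0 homozygote.
#'
#' @param panel A [hap_panel()].
#' @param effects A `qtl_effects` data frame.
#' @param qtl_idx Column indices of the QTL in the haplotype matrix.
#' @return Numeric vector, one genotypic value per individual.
#' @export
genotypic_value <- function(panel, effects, qtl_idx) {
  g <- dosage(panel, qtl_idx)
  if (ncol(g) != nrow(effects))
    stop("data error: QTL set does not match effects", call. = FALSE)
  drop(g %*% effects$a) - sum(effects$a) + drop((g == 1L) %*% effects$d)
}

#' Simulate phenotypes
#'
#' Adds an independent normal residual with variance `sigma2_e` to each
#' genotypic value.
#'
#' @param values Genotypic values.
#' @param sigma2_e Residual variance.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(values, sigma2_e) {
  if (sigma2_e < 0) stop("configuration error: sigma2_e must be >= 0", call. = FALSE)
  values + stats::rnorm(length(values), 0, sqrt(sigma2_e))
}

# Shared kernel for true and genomic breeding values: the expected genotypic
# value of offspring when the counted genotype is mated at random to a
# population with allele-1 frequencies `p`. Per locus the contribution is
# x(p a + q d) + (1 - x)(-q a + p d) with x in {1, 0.5, 0}, which collapses
# to x * alpha + const with alpha = a + (q - p) d.
breeding_value_kernel <- function(dsg, a, d, p) {
  if (ncol(dsg) != length(a) || length(a) != length(d) || length(d) != length(p))
    stop("alignment error: genotypes, effects and frequencies must match",
         call. = FALSE)
  q <- 1 - p
  alpha <- a + (q - p) * d
  drop((dsg / 2) %*% alpha) + sum(d * p - a * q)
}

#' True breeding values for purebred or crossbred performance
#'
#' The TBV of a candidate is the expected genotypic value of its offspring
#' when mated at random to a reference population: the candidate's own breed
#' gives the TBV for purebred performance (TBV-P), the opposite breed the
#' TBV for crossbred performance (TBV-C). Only the QTL frequencies of the
#' reference population enter; the candidate's own genotype is used in full.
#'
#' @param panel Candidate [hap_panel()].
#' @param effects `qtl_effects` (true effects).
#' @param qtl_idx QTL column indices.
#' @param ref_freq Allele-1 frequencies at the QTL in the reference breed
#'   (own breed for TBV-P, opposite breed for TBV-C), computed from all of
#'   that breed's current selection candidates.
#' @return Numeric vector of TBVs.
#' @export
true_breeding_values <- function(panel, effects, qtl_idx, ref_freq) {
  breeding_value_kernel(dosage(panel, qtl_idx), effects$a, effects$d, ref_freq)
}

#' Heterosis
#'
#' The excess of the crossbred mean over the parental breed average:
#' `H = CP - (mean_A + mean_B) / 2`.
#'
#' @param crossbred_mean Mean performance of the crossbred cohort (CP).
#' @param breed_means Numeric vector of the two purebred cohort means.
#' @return The heterosis H.
#' @export
heterosis <- function(crossbred_mean, breed_means) {
  crossbred_mean - mean(breed_means)
}

#' Expected F1 heterosis from allele-frequency divergence
#'
#' Closed form under Hardy-Weinberg and linkage equilibrium:
#' `sum_j d_j (p_Aj - p_Bj)^2`.
#'
#' @param effects `qtl_effects`.
#' @param p_A,p_B QTL allele-1 frequencies in the two parental breeds.
#' @return Expected heterosis of the F1.
#' @export
expected_f1_heterosis <- function(effects, p_A, p_B) {
  sum(effects$d * (p_A - p_B)^2)
}

#' Purebred-crossbred genetic correlation
#'
#' Pearson correlation between TBV-P and TBV-C across the candidates of one
#' breed. It is 1 when the two breeds share allele frequencies or when all
#' dominance deviations are zero, and drops below 1 as dominance and
#' frequency divergence grow.
#'
#' @param tbv_p,tbv_c Aligned TBV vectors.
#' @return Pearson correlation.
#' @export
rpc <- function(tbv_p, tbv_c) {
  if (length(tbv_p) < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(tbv_p) == 0 || stats::sd(tbv_c) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(tbv_p, tbv_c)
}
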