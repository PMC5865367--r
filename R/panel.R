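#' Haplotype panel
#'
#' A `hap_panel` holds the phased genomes of one cohort: an integer matrix of
#' 0/1 alleles with one row per gamete (individual `i` occupies rows
#' `2i - 1` and `2i`; the first row of each pair is the paternal, the second
#' the maternal haplotype) plus per-individual metadata (id, sire, dam, sex,
#' breed label, generation index).
#'
#' @param haps Integer matrix of 0/1 alleles, `2n` rows by `L` loci.
#' @param id Integer ids, unique within the panel.
#' @param sire,dam Parent ids (NA for founders).
#' @param sex Character vector of `"M"`/`"F"`.
#' @param breed Breed label(s): `"A"`, `"B"`, `"AB"`, or `"HIST"`.
#' @param generation Generation index of the cohort.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, id = seq_len(nrow(haps) %/% 2L),
                      sire = NA_integer_, dam = NA_integer_,
                      sex = NULL, breed = "HIST", generation = 0L) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  n <- nrow(haps) %/% 2L
  if (2L * n != nrow(haps))
    stop("haplotype matrix must have an even number of rows", call. = FALSE)
  if (is.null(sex)) sex <- rep(c("M", "F"), each = ceiling(n / 2))[seq_len(n)]
  id <- rep_len(as.integer(id), n)
  if (anyDuplicated(id)) stop("ids must be unique within a panel", call. = FALSE)
  obj <- list(haps = haps,
              id = id,
              sire = rep_len(as.integer(sire), n),
              dam = rep_len(as.integer(dam), n),
              sex = rep_len(as.character(sex), n),
              breed = rep_len(as.character(breed), n),
              generation = as.integer(generation))
  class(obj) <- "hap_panel"
  obj
}

#' @export
print.hap_panel <- function(x, ...) {
  n <- n_ind(x)
  cat(sprintf("<hap_panel> %d individuals (%d M / %d F), %d loci, breed %s, generation %d\n",
              n, sum(x$sex == "M"), sum(x$sex == "F"), ncol(x$haps),
              paste(unique(x$breed), collapse = "/"), x$generation))
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel A [hap_panel()].
#' @return Integer count.
#' @export
n_ind <- function(panel) length(panel$id)

#' Subset a panel by individual
#'
#' @param panel A [hap_panel()].
#' @param idx Integer positions (not ids) of the individuals to keep.
#' @return A [hap_panel()] with the selected individuals, in the given order.
#' @export
subset_panel <- function(panel, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_ind(panel))) stop("index out of range", call. = FALSE)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  out <- panel
  out$haps <- panel$haps[rows, , drop = FALSE]
  out$id <- panel$id[idx]
  out$sire <- panel$sire[idx]
  out$dam <- panel$dam[idx]
  out$sex <- panel$sex[idx]
  out$breed <- panel$breed[idx]
  out
}

#' Genotype dosage matrix
#'
#' Counts of the `1` allele per individual and locus (0, 1 or 2).
#'
#' @param panel A [hap_panel()].
#' @param loci Optional column indices restricting the loci.
#' @return Integer matrix, individuals by loci.
#' @export
dosage <- function(panel, loci = NULL) {
  h <- panel$haps
  n <- n_ind(panel)
  odd <- seq.int(1L, 2L * n, by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  d
}

#' Allele frequencies of a panel
#'
#' Frequency of the `1` allele over the `2n` gametes, computed from all
#' individuals of the panel (the selection candidates, when called on a
#' candidate cohort).
#'
#' @param panel A [hap_panel()].
#' @param loci Optional column indices restricting the loci.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freq <- function(panel, loci = NULL) {
  h <- panel$haps
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  colMeans(h)
}

#' Expected heterozygosity of a panel
#'
#' Mean of `2 p q` across loci, where `p` is the panel allele frequency.
#'
#' @param panel A [hap_panel()].
#' @param loci Optional column indices restricting the loci.
#' @return Mean expected heterozygosity.
#' @export
expected_heterozygosity <- function(panel, loci = NULL) {
  p <- allele_freq(panel, loci)
  mean(2 * p * (1 - p))
}
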