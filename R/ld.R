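#' Signed LD between SNP pairs from phased haplotypes
#'
#' For every within-chromosome SNP pair up to `max_dist_M` apart, computes
#' the signed Pearson correlation `r` of the allele indicators across the
#' `2n` gametes of the panel. The sign convention is fixed globally by the
#' allele labelling of the map (allele 1 everywhere), so `r` values are
#' comparable across populations. SNPs whose minor allele frequency in this
#' panel is `maf_min` or lower are excluded (a monomorphic SNP has no
#' defined `r`).
#'
#' @param panel A [hap_panel()].
#' @param map The matching `genetic_map`.
#' @param snp_idx SNP column indices (defaults to the map's SNP class).
#' @param maf_min MAF threshold for inclusion (default 0.01).
#' @param max_dist_M Maximum pair distance in Morgans (default 0.1 = 10 cM).
#' @return An `ld_table`: data frame with columns `locus_i`, `locus_j`
#'   (global locus indices, `locus_i < locus_j`), `dist_cM` and `r`.
#' @export
haplotype_ld <- function(panel, map, snp_idx = loci_of_class(map, "SNP"),
                         maf_min = 0.01, max_dist_M = 0.1) {
  p <- allele_freq(panel, snp_idx)
  keep <- pmin(p, 1 - p) > maf_min
  snp_idx <- snp_idx[keep]
  out <- vector("list", length(unique(map$chrom[snp_idx])))
  k <- 0L
  for (c in unique(map$chrom[snp_idx])) {
    idx <- snp_idx[map$chrom[snp_idx] == c]
    if (length(idx) < 2L) next
    H <- panel$haps[, idx, drop = FALSE]
    R <- suppressWarnings(stats::cor(H))
    pos <- map$pos[idx]
    D <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(D) & D <= max_dist_M, arr.ind = TRUE)
    k <- k + 1L
    out[[k]] <- data.frame(locus_i = idx[sel[, 1]], locus_j = idx[sel[, 2]],
                           dist_cM = D[sel] * 100, r = R[sel])
  }
  tab <- do.call(rbind, out[seq_len(k)])
  tab <- tab[is.finite(tab$r), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ld_table", "data.frame")
  tab
}

#' Correlation of LD phase between two populations
#'
#' Pairs are matched between the two tables (the intersection of pairs that
#' pass the MAF filter in both populations), binned by map distance into
#' half-open intervals `[k b, (k+1) b)` of width `b` cM, and within each bin
#' the Pearson correlation of the paired signed `r` values is computed.
#' Positive values indicate that SNP pairs tend to have the same linkage
#' phase in the two populations. Bins with fewer than 3 shared pairs yield
#' `NA`.
#'
#' @param ld_x,ld_y `ld_table`s from [haplotype_ld()] for populations X and
#'   Y over the same map.
#' @param bin_width Bin width in cM (default 0.1).
#' @param max_cM Upper distance limit in cM (default 10).
#' @return Data frame with columns `bin_low_cM`, `bin_high_cM`, `n_pairs`
#'   and `R`.
#' @export
phase_correlation <- function(ld_x, ld_y, bin_width = 0.1, max_cM = 10) {
  key <- function(t) t$locus_i * 1e5 + t$locus_j
  m <- match(key(ld_x), key(ld_y))
  ok <- !is.na(m)
  rx <- ld_x$r[ok]
  ry <- ld_y$r[m[ok]]
  dist <- ld_x$dist_cM[ok]
  bin <- floor(dist / bin_width)
  n_bins <- ceiling(max_cM / bin_width)
  lows <- (seq_len(n_bins) - 1L) * bin_width
  R <- n_pairs <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == (b - 1L)
    n_pairs[b] <- sum(sel)
    R[b] <- if (n_pairs[b] >= 3L) suppressWarnings(stats::cor(rx[sel], ry[sel]))
            else NA_real_
  }
  data.frame(bin_low_cM = lows, bin_high_cM = lows + bin_width,
             n_pairs = as.integer(n_pairs), R = R)
}

#' Mean phase correlation over a distance range
#'
#' Averages the per-bin phase correlations whose bins fall inside
#' `[from_cM, to_cM)`; a convenience for summaries such as "mean correlation
#' for pairs less than 0.5 cM apart".
#'
#' @param phase Result of [phase_correlation()].
#' @param from_cM,to_cM Distance range in cM.
#' @return Mean of the non-missing bin correlations in the range.
#' @export
mean_phase_correlation <- function(phase, from_cM = 0, to_cM = 0.5) {
  sel <- phase$bin_low_cM >= from_cM & phase$bin_high_cM <= to_cM
  mean(phase$R[sel], na.rm = TRUE)
}
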