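#' Write the trait architecture to CSV
#'
#' One row per locus: id, chromosome, position (Morgans), class, and for QTL
#' the additive effect, dominance deviation, degree of dominance and base
#' allele frequency.
#'
#' @param map A `genetic_map` with SNP/QTL classes assigned.
#' @param effects `qtl_effects` aligned to the map's QTL.
#' @param base_freq Base-population allele frequencies at the QTL.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_architecture_csv <- function(map, effects, base_freq, path) {
  qtl <- loci_of_class(map, "QTL")
  out <- data.frame(locus = map$locus, chrom = map$chrom,
                    pos_Morgan = map$pos, class = map$class,
                    a = NA_real_, d = NA_real_, h = NA_real_,
                    base_freq = NA_real_)
  out$a[qtl] <- effects$a
  out$d[qtl] <- effects$d
  out$h[qtl] <- effects$h
  out$base_freq[qtl] <- base_freq
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a panel as PLINK PED/MAP
#'
#' Alleles are recoded 0 -> 1 and 1 -> 2; the two allele columns per locus
#' preserve the phased order (first the paternal, then the maternal allele).
#' The MAP file reports the genetic position in cM and a base-pair position
#' of `pos * 1e6`.
#'
#' @param panel A [hap_panel()].
#' @param map The matching `genetic_map`.
#' @param prefix Output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(panel, map, prefix) {
  map_df <- data.frame(chrom = map$chrom,
                       id = paste0("L", map$locus),
                       cM = map$pos * 100,
                       bp = round(map$pos * 1e6))
  utils::write.table(map_df, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- n_ind(panel)
  odd <- seq.int(1L, 2L * n, by = 2L)
  h1 <- panel$haps[odd, , drop = FALSE] + 1L
  h2 <- panel$haps[odd + 1L, , drop = FALSE] + 1L
  L <- ncol(h1)
  geno <- matrix(0L, n, 2L * L)
  geno[, seq.int(1L, 2L * L, 2L)] <- h1
  geno[, seq.int(2L, 2L * L, 2L)] <- h2
  ped <- cbind(panel$breed, panel$id,
               ifelse(is.na(panel$sire), 0L, panel$sire),
               ifelse(is.na(panel$dam), 0L, panel$dam),
               ifelse(panel$sex == "M", 1L, 2L),
               -9L, geno)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

#' Write a pedigree CSV for a panel
#'
#' @param panel A [hap_panel()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pedigree_csv <- function(panel, path) {
  utils::write.csv(data.frame(id = panel$id, sire = panel$sire, dam = panel$dam,
                              sex = panel$sex, breed = panel$breed,
                              generation = panel$generation),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write marker-effect estimates (CSV + JSON sidecar)
#'
#' The CSV holds one row per SNP with the posterior-mean additive and
#' dominance effects; the JSON sidecar records the intercept, the
#' posterior-mean variance components, the chain configuration and the
#' Geweke z-scores.
#'
#' @param fit A [brr_dom()] fit.
#' @param snp_idx SNP locus indices used in training.
#' @param prefix Output prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_estimates <- function(fit, snp_idx, prefix) {
  utils::write.csv(data.frame(locus = snp_idx, a_hat = fit$a, d_hat = fit$d),
                   paste0(prefix, ".csv"), row.names = FALSE)
  sidecar <- list(mu = fit$mu, s2a = fit$s2a, s2d = fit$s2d, s2e = fit$s2e,
                  niter = fit$chain_config$niter,
                  burnin = fit$chain_config$burnin,
                  geweke_z = as.list(fit$geweke))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
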