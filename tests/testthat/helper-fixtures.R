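# Shared fixtures: small deterministic maps and panels built in code.

# A map with explicit positions on one or more chromosomes of given lengths.
toy_map <- function(pos, chrom = rep(1L, length(pos)), chrom_len = NULL) {
  if (is.null(chrom_len)) chrom_len <- rep(max(pos) + 0.01, max(chrom))
  ord <- order(chrom, pos)
  map <- data.frame(locus = seq_along(pos), chrom = chrom[ord], pos = pos[ord],
                    class = "none", stringsAsFactors = FALSE)
  map$locus <- seq_along(pos)
  attr(map, "chrom_len") <- chrom_len
  class(map) <- c("genetic_map", "data.frame")
  map
}

# Panel from an explicit gamete matrix (rows = gametes).
toy_panel <- function(haps, breed = "A", sex = NULL) {
  hap_panel(as.matrix(haps), breed = breed, sex = sex)
}

# HWE panel: n individuals at given allele-1 frequencies, linkage equilibrium.
hwe_panel <- function(n, p, breed = "A") {
  L <- length(p)
  haps <- matrix(stats::rbinom(2L * n * L, 1L, rep(p, each = 2L * n)),
                 nrow = 2L * n, ncol = L)
  hap_panel(haps, breed = breed)
}

# Tiny genome configuration for fast end-to-end runs.
tiny_genome <- function(...) {
  args <- list(n_snps_target = 40L, n_qtl_target = 8L,
               historical_size = 60L, historical_generations = 30L)
  args[names(list(...))] <- list(...)
  do.call(genome_config, args)
}

tiny_study <- function(...) {
  args <- list(
    w = c(0, 1), n_generations = 2L, n_replicates = 1L,
    n_founders = 20L, n_breed_generations = 5L,
    genome = tiny_genome(),
    selection = selection_config(n_candidates = 40L, n_males_selected = 4L,
                                 n_females_selected = 8L,
                                 n_crossbred_offspring = 40L),
    chain = chain_config(niter = 300L, burnin = 100L, thin = 1L))
  args[names(list(...))] <- list(...)
  do.call(study_config, args)
}

# Effects table with explicit values.
toy_effects <- function(a, d) {
  eff <- data.frame(a = a, d = d, h = d / ifelse(abs(a) > 0, abs(a), 1))
  class(eff) <- c("qtl_effects", "data.frame")
  eff
}
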