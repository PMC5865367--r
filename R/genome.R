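#' Build a genetic map of candidate loci
#'
#' Candidate loci are spread evenly across chromosomes (equal counts per
#' chromosome) with positions drawn uniformly along each chromosome and
#' sorted. All loci start as class `"none"`; [sample_architecture()] later
#' promotes a subset to `"SNP"` or `"QTL"`.
#'
#' @param config A [genome_config()].
#' @return A `genetic_map`: data frame with columns `locus`, `chrom`, `pos`
#'   (Morgans) and `class`, ordered by (chrom, pos), with the chromosome
#'   lengths stored in attribute `chrom_len`.
#' @export
build_map <- function(config) {
  config <- validate_genome_config(config)
  n_chr <- config$n_chromosomes
  per_chr <- distribute_evenly(config$n_candidate_loci, n_chr)
  chrom <- rep(seq_len(n_chr), per_chr)
  pos <- unlist(lapply(seq_len(n_chr), function(c)
    sort(stats::runif(per_chr[c], 0, config$chromosome_length))), use.names = FALSE)
  map <- data.frame(locus = seq_along(chrom), chrom = chrom, pos = pos,
                    class = rep("none", length(chrom)),
                    stringsAsFactors = FALSE)
  attr(map, "chrom_len") <- rep(config$chromosome_length, n_chr)
  class(map) <- c("genetic_map", "data.frame")
  map
}

distribute_evenly <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

# 0-based [start, end) locus ranges per chromosome plus positions, in the
# form the compiled gene-drop routines expect.
map_cpp_args <- function(map) {
  chrom_len <- attr(map, "chrom_len")
  n_chr <- length(chrom_len)
  counts <- tabulate(map$chrom, nbins = n_chr)
  end <- cumsum(counts)
  start <- c(0L, end[-n_chr])
  list(chrom_start = as.integer(start), chrom_end = as.integer(end),
       chrom_len = as.numeric(chrom_len), pos = as.numeric(map$pos))
}

#' Simulate the historical (ancestral) population
#'
#' Initializes the candidate loci with allele frequencies drawn from a
#' uniform(0, 1) distribution, in linkage equilibrium, and randomly mates the
#' population for the configured number of generations at constant size.
#' Recurrent symmetric allele-flip mutation at `mutation_rate` is applied per
#' gamete per locus during these historical generations (and only here):
#' mutation exists to keep enough loci segregating after the long drift
#' phase.
#'
#' @param config A [genome_config()].
#' @return A list with elements `panel` (the final-generation [hap_panel()])
#'   and `map` (the [build_map()] result).
#' @export
simulate_historical <- function(config) {
  config <- validate_genome_config(config)
  map <- build_map(config)
  L <- nrow(map)
  n <- config$historical_size
  p0 <- stats::runif(L)
  haps <- matrix(stats::rbinom(2L * n * L, 1L, rep(p0, each = 2L * n)),
                 nrow = 2L * n, ncol = L)
  ma <- map_cpp_args(map)
  haps <- cpp_random_mate_generations(haps, config$historical_generations,
                                      ma$chrom_start, ma$chrom_end,
                                      ma$chrom_len, ma$pos,
                                      config$mutation_rate)
  panel <- hap_panel(haps, breed = "HIST",
                     generation = config$historical_generations)
  list(panel = panel, map = map)
}

#' Assign SNP and QTL status to candidate loci
#'
#' Draws the configured numbers of SNPs and QTL per chromosome, without
#' replacement and disjointly, from the loci whose minor allele frequency in
#' the supplied panel exceeds the architecture threshold (0.05 by default).
#'
#' @param panel The final-generation historical [hap_panel()].
#' @param map The [build_map()] result for the same loci.
#' @param config A [genome_config()].
#' @return The map with `class` set to `"SNP"`/`"QTL"` for the sampled loci.
#' @export
sample_architecture <- function(panel, map, config) {
  config <- validate_genome_config(config)
  p <- allele_freq(panel)
  maf <- pmin(p, 1 - p)
  eligible <- maf > config$maf_threshold_arch
  n_chr <- config$n_chromosomes
  snp_per_chr <- distribute_evenly(config$n_snps_target, n_chr)
  qtl_per_chr <- distribute_evenly(config$n_qtl_target, n_chr)
  cls <- map$class
  for (c in seq_len(n_chr)) {
    idx <- which(map$chrom == c & eligible)
    need <- snp_per_chr[c] + qtl_per_chr[c]
    if (length(idx) < need)
      stop(sprintf(paste0("insufficient polymorphism: chromosome %d has %d loci ",
                          "with MAF > %g but %d are required (shortfall %d)"),
                   c, length(idx), config$maf_threshold_arch, need,
                   need - length(idx)), call. = FALSE)
    pick <- sample(idx, need)
    cls[pick[seq_len(snp_per_chr[c])]] <- "SNP"
    cls[pick[snp_per_chr[c] + seq_len(qtl_per_chr[c])]] <- "QTL"
  }
  map$class <- cls
  map
}

#' Indices of SNP or QTL loci in a map
#' @param map A `genetic_map`.
#' @param class `"SNP"` or `"QTL"`.
#' @return Integer locus indices (columns of the haplotype matrix).
#' @export
loci_of_class <- function(map, class) which(map$class == class)

#' Sample QTL effects
#'
#' The absolute additive effect `|a|` of each QTL is drawn from a gamma
#' distribution with shape 0.4 and scale 1.66 (heavy-tailed: many small,
#' few large effects); the sign of `a` is random, i.e. either allele is
#' equally likely to be the increasing one. The degree of dominance `h` is
#' drawn from N(0.5, 1) and the dominance deviation is `d = h * |a|`, so
#' large-effect QTL also tend to have large dominance deviations. A QTL is
#' over-dominant when `|h| > 1`. When `overdominance_allowed` is `FALSE`
#' (genetic model 3), QTL sampled as over-dominant get `d = |a|` (complete
#' dominance) instead.
#'
#' @param n_qtl Number of QTL.
#' @param overdominance_allowed Logical; see above.
#' @param gamma_shape,gamma_scale Parameters of the gamma distribution of
#'   `|a|` (shape/scale convention).
#' @return A `qtl_effects` data frame with columns `a`, `d`, `h`.
#' @export
sample_effects <- function(n_qtl, overdominance_allowed = TRUE,
                           gamma_shape = 0.4, gamma_scale = 1.66) {
  n_qtl <- as.integer(n_qtl)
  if (n_qtl < 1L) stop("n_qtl must be positive", call. = FALSE)
  amag <- stats::rgamma(n_qtl, shape = gamma_shape, scale = gamma_scale)
  a <- amag * sample(c(-1, 1), n_qtl, replace = TRUE)
  h <- stats::rnorm(n_qtl, 0.5, 1)
  d <- h * amag
  if (!overdominance_allowed) {
    od <- abs(h) > 1
    d[od] <- amag[od]
  }
  effects <- data.frame(a = a, d = d, h = d / ifelse(amag > 0, amag, 1))
  class(effects) <- c("qtl_effects", "data.frame")
  effects
}

#' Additive and dominance variance of a QTL architecture
#'
#' Under Hardy-Weinberg and linkage equilibrium at allele frequencies `p`,
#' the additive variance is `sum(2 p q alpha^2)` with allele substitution
#' effect `alpha = a + (q - p) d`, and the dominance variance is
#' `sum((2 p q d)^2)`.
#'
#' @param effects A `qtl_effects` data frame.
#' @param p Allele-1 frequency per QTL, same length as `effects` rows.
#' @return Named numeric vector `c(sigma2_a, sigma2_d)`.
#' @export
compute_variances <- function(effects, p) {
  if (length(p) != nrow(effects))
    stop("dimension error: one frequency per QTL required", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("frequencies must be in [0, 1]", call. = FALSE)
  q <- 1 - p
  alpha <- effects$a + (q - p) * effects$d
  c(sigma2_a = sum(2 * p * q * alpha^2),
    sigma2_d = sum((2 * p * q * effects$d)^2))
}

#' Scale QTL effects to target variance components
#'
#' Alternates multiplicative updates `d <- d * sqrt(target_d / current_d)`
#' and `a <- a * sqrt(target_a / current_a)` until both realized variances
#' (at the supplied base-population frequencies) are within relative
#' tolerance of the targets. The two updates interact because the allele
#' substitution effect couples `a` and `d`, hence the iteration. When
#' over-dominance is suppressed, `|d|` is clamped to `|a|` inside the loop so
#' the constraint holds in the returned architecture.
#'
#' @param effects A `qtl_effects` data frame (from [sample_effects()]).
#' @param p Base-population allele frequencies, one per QTL.
#' @param trait A [trait_config()] carrying the targets.
#' @param tol Relative tolerance on both variances.
#' @param max_iter Iteration cap.
#' @return The rescaled `qtl_effects`, with realized variances in attribute
#'   `realized`.
#' @export
scale_effects <- function(effects, p, trait, tol = 1e-4, max_iter = 5000L) {
  if (length(p) != nrow(effects))
    stop("dimension error: one frequency per QTL required", call. = FALSE)
  seg <- p > 0 & p < 1
  if (!any(seg))
    stop("scaling impossible: no segregating QTL", call. = FALSE)
  ta <- trait$sigma2_a
  td <- trait$sigma2_d
  a <- effects$a
  d <- effects$d
  dom_var <- function(d) (2 * p * (1 - p) * d)^2
  for (it in seq_len(max_iter)) {
    v <- compute_variances(data.frame(a = a, d = d), p)
    if (trait$overdominance_allowed) {
      if (v[["sigma2_d"]] > 0) d <- d * sqrt(td / v[["sigma2_d"]])
    } else if (td > 0 && v[["sigma2_d"]] > 0) {
      # the clamp caps |d| at |a|; spread the remaining dominance-variance
      # deficit over the unclamped QTL, re-clamping as they hit the bound
      for (inner in 1:20) {
        clamped <- abs(d) >= abs(a)
        dv <- dom_var(d)
        vd_clamped <- sum(dv[clamped])
        vd_free <- sum(dv[!clamped])
        if (vd_clamped >= td || vd_free == 0) {
          d <- d * sqrt(td / sum(dom_var(d)))
        } else {
          d[!clamped] <- d[!clamped] * sqrt((td - vd_clamped) / vd_free)
        }
        over <- abs(d) > abs(a)
        if (!any(over)) break
        d[over] <- sign(d[over]) * abs(a[over])
      }
    }
    v <- compute_variances(data.frame(a = a, d = d), p)
    if (v[["sigma2_a"]] > 0) a <- a * sqrt(ta / v[["sigma2_a"]])
    if (!trait$overdominance_allowed) {
      over <- abs(d) > abs(a)
      d[over] <- sign(d[over]) * abs(a[over])
    }
    v <- compute_variances(data.frame(a = a, d = d), p)
    ok_a <- abs(v[["sigma2_a"]] - ta) <= tol * max(ta, .Machine$double.eps)
    ok_d <- if (td > 0) abs(v[["sigma2_d"]] - td) <= tol * td
            else v[["sigma2_d"]] <= tol
    if (ok_a && ok_d) {
      out <- data.frame(a = a, d = d, h = d / ifelse(abs(a) > 0, abs(a), 1))
      class(out) <- c("qtl_effects", "data.frame")
      attr(out, "realized") <- v
      return(out)
    }
  }
  if (!trait$overdominance_allowed && v[["sigma2_d"]] < td &&
      abs(v[["sigma2_a"]] - ta) <= tol * ta) {
    # the |d| <= |a| constraint caps the attainable dominance variance for
    # some effect draws; return the saturated architecture rather than fail
    warning(sprintf(paste0("dominance variance saturated at %.4f (target %.4f) ",
                           "under the no-over-dominance constraint"),
                    v[["sigma2_d"]], td), call. = FALSE)
    out <- data.frame(a = a, d = d, h = d / ifelse(abs(a) > 0, abs(a), 1))
    class(out) <- c("qtl_effects", "data.frame")
    attr(out, "realized") <- v
    attr(out, "dominance_saturated") <- TRUE
    return(out)
  }
  stop(sprintf(paste0("scaling did not converge after %d iterations ",
                      "(last residuals: sigma2_a %.3g, sigma2_d %.3g)"),
               max_iter, v[["sigma2_a"]] - ta, v[["sigma2_d"]] - td),
       call. = FALSE)
}

#' Fraction of over-dominant QTL
#'
#' A QTL is over-dominant when its heterozygote lies outside the homozygote
#' range, i.e. `|d| > |a|`.
#'
#' @param effects A `qtl_effects` data frame.
#' @return Fraction in `[0, 1]`.
#' @export
overdominant_fraction <- function(effects) mean(abs(effects$d) > abs(effects$a))
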