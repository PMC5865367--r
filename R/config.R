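#' Genome and historical-population configuration
#'
#' Bundles the parameters that define the simulated genome and the historical
#' (ancestral) population from which both breeds are later founded. The
#' defaults describe a compact genome of 4 chromosomes of 1 Morgan each
#' carrying 4000 SNPs and 400 QTL, sampled from roughly twice as many
#' candidate loci that segregate after 2000 generations of random mating in a
#' population of 2000 individuals with recurrent symmetric mutation at rate
#' 2.5e-5 per locus per gamete.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in Morgans.
#' @param n_snps_target Total number of SNP loci in the final architecture.
#' @param n_qtl_target Total number of QTL in the final architecture.
#' @param n_candidate_loci Number of biallelic loci simulated in the
#'   historical population; defaults to twice the SNP + QTL target so that
#'   enough loci remain polymorphic after drift.
#' @param mutation_rate Per-locus, per-gamete probability of a symmetric
#'   allele flip, applied during the historical generations only.
#' @param historical_size Number of individuals in the historical population.
#' @param historical_generations Number of generations of random mating in
#'   the historical population.
#' @param maf_threshold_arch Minimum minor allele frequency for a locus to be
#'   eligible as a SNP or QTL.
#' @return An object of class `genome_config` (a validated list).
#' @export
genome_config <- function(n_chromosomes = 4L,
                          chromosome_length = 1,
                          n_snps_target = 4000L,
                          n_qtl_target = 400L,
                          n_candidate_loci = 2L * (n_snps_target + n_qtl_target),
                          mutation_rate = 2.5e-5,
                          historical_size = 2000L,
                          historical_generations = 2000L,
                          maf_threshold_arch = 0.05) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    n_snps_target = as.integer(n_snps_target),
    n_qtl_target = as.integer(n_qtl_target),
    n_candidate_loci = as.integer(n_candidate_loci),
    mutation_rate = as.numeric(mutation_rate),
    historical_size = as.integer(historical_size),
    historical_generations = as.integer(historical_generations),
    maf_threshold_arch = as.numeric(maf_threshold_arch)
  )
  class(cfg) <- "genome_config"
  validate_genome_config(cfg)
}

validate_genome_config <- function(cfg) {
  stopifnot(inherits(cfg, "genome_config"))
  if (cfg$historical_size < 2L)
    stop("configuration error: historical_size must be at least 2", call. = FALSE)
  if (cfg$n_candidate_loci < 1L)
    stop("configuration error: n_candidate_loci must be positive", call. = FALSE)
  if (cfg$n_candidate_loci < cfg$n_snps_target + cfg$n_qtl_target)
    stop("configuration error: n_candidate_loci must be >= n_snps_target + n_qtl_target",
         call. = FALSE)
  if (cfg$chromosome_length <= 0)
    stop("configuration error: chromosome_length must be > 0", call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("configuration error: mutation_rate must be in [0, 1]", call. = FALSE)
  if (cfg$maf_threshold_arch < 0 || cfg$maf_threshold_arch > 0.5)
    stop("configuration error: maf_threshold_arch must be in [0, 0.5]", call. = FALSE)
  if (cfg$n_chromosomes < 1L)
    stop("configuration error: need at least one chromosome", call. = FALSE)
  if (cfg$historical_generations < 0L)
    stop("configuration error: historical_generations must be >= 0", call. = FALSE)
  cfg
}

#' Trait (variance-component) configuration
#'
#' Defines the phenotypic variance, narrow-sense heritability and target
#' dominance variance of the simulated trait. The additive-variance target is
#' derived as `h2 * sigma2_p`. The residual variance defaults to
#' `sigma2_p - sigma2_a - sigma2_d` so that the phenotypic variance in the
#' base population equals `sigma2_p`; set `literal_standard_normal_residual =
#' TRUE` to instead draw residuals from N(0, 1) regardless of the variance
#' budget.
#'
#' @param sigma2_p Phenotypic variance (default 1).
#' @param h2 Narrow-sense heritability (default 0.3).
#' @param sigma2_d Target dominance variance (0.1 for models 1 and 3, 0.05
#'   for model 2).
#' @param overdominance_allowed If `FALSE`, dominance deviations are clamped
#'   so that no QTL is over-dominant (`|d| <= |a|` everywhere).
#' @param literal_standard_normal_residual Use residual variance 1 instead of
#'   the variance-budget residual.
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(sigma2_p = 1, h2 = 0.3, sigma2_d = 0.1,
                         overdominance_allowed = TRUE,
                         literal_standard_normal_residual = FALSE) {
  sigma2_a <- h2 * sigma2_p
  if (sigma2_p <= 0 || h2 < 0 || sigma2_d < 0)
    stop("configuration error: variances must be non-negative and sigma2_p > 0",
         call. = FALSE)
  if (sigma2_a + sigma2_d >= sigma2_p)
    stop("configuration error: sigma2_a + sigma2_d must be < sigma2_p", call. = FALSE)
  cfg <- list(
    sigma2_p = sigma2_p, h2 = h2,
    sigma2_a = sigma2_a, sigma2_d = sigma2_d,
    sigma2_e = if (literal_standard_normal_residual) 1 else sigma2_p - sigma2_a - sigma2_d,
    overdominance_allowed = isTRUE(overdominance_allowed)
  )
  class(cfg) <- "trait_config"
  cfg
}

#' Predefined genetic models
#'
#' Model 1: dominance variance 0.1, over-dominance allowed (about a quarter
#' of the QTL end up over-dominant after variance scaling). Model 2:
#' dominance variance 0.05 (about a tenth over-dominant). Model 3: dominance
#' variance 0.1 but over-dominance suppressed.
#'
#' @param model_id 1, 2 or 3.
#' @return A [trait_config()] for the requested model.
#' @export
genetic_model <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3", call. = FALSE)
  switch(model_id,
         trait_config(sigma2_d = 0.1, overdominance_allowed = TRUE),
         trait_config(sigma2_d = 0.05, overdominance_allowed = TRUE),
         trait_config(sigma2_d = 0.1, overdominance_allowed = FALSE))
}

#' Selection-program configuration
#'
#' @param n_candidates Selection candidates per breed per generation.
#' @param n_males_selected,n_females_selected Numbers of sires and dams kept
#'   by truncation selection each generation.
#' @param n_purebred_offspring Purebred replacement offspring per breed.
#' @param n_crossbred_offspring Crossbred progeny per generation (doubled
#'   automatically when training is on crossbreds, so that a training cohort
#'   of 2000 exists).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_candidates = 1000L,
                             n_males_selected = 100L,
                             n_females_selected = 200L,
                             n_purebred_offspring = n_candidates,
                             n_crossbred_offspring = 1000L) {
  cfg <- list(
    n_candidates = as.integer(n_candidates),
    n_males_selected = as.integer(n_males_selected),
    n_females_selected = as.integer(n_females_selected),
    n_purebred_offspring = as.integer(n_purebred_offspring),
    n_crossbred_offspring = as.integer(n_crossbred_offspring)
  )
  class(cfg) <- "selection_config"
  n_m <- cfg$n_candidates %/% 2L
  n_f <- cfg$n_candidates - n_m
  if (cfg$n_males_selected > n_m || cfg$n_females_selected > n_f)
    stop("configuration error: selected counts exceed available candidates by sex",
         call. = FALSE)
  if (cfg$n_purebred_offspring < 1L || cfg$n_crossbred_offspring < 1L)
    stop("configuration error: offspring counts must be positive", call. = FALSE)
  cfg
}

#' Gibbs-chain configuration for marker-effect estimation
#'
#' @param niter Total chain length (default 20000).
#' @param burnin Burn-in iterations discarded before posterior means are
#'   accumulated (default 3000).
#' @param thin Thinning interval for the recorded monitoring chains.
#' @param df_prior Degrees of freedom of the scaled-inverse-chi-square
#'   hyperpriors on the three variance components.
#' @param R2 Assumed proportion of phenotypic variance captured by markers,
#'   used to set the hyperprior scales (split equally between the additive
#'   and dominance effect classes).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(niter = 20000L, burnin = 3000L, thin = 10L,
                         df_prior = 5, R2 = 0.5) {
  cfg <- list(niter = as.integer(niter), burnin = as.integer(burnin),
              thin = as.integer(thin), df_prior = df_prior, R2 = R2)
  class(cfg) <- "chain_config"
  if (cfg$niter <= cfg$burnin)
    stop("configuration error: chain length must exceed burn-in", call. = FALSE)
  if (cfg$thin < 1L) stop("configuration error: thin must be >= 1", call. = FALSE)
  cfg
}

#' Full study configuration
#'
#' Combines all module configurations into one description of a simulation
#' scenario set: genetic model, training mode, the grid of selection-index
#' weights, number of generations and replicates, and the master seed.
#'
#' @param model_id Genetic model (1, 2 or 3), see [genetic_model()].
#' @param training_mode `"purebred"` (one model per breed, trained on that
#'   breed's candidates) or `"crossbred"` (one model trained on the current
#'   crossbred cohort, applied to both breeds).
#' @param w Numeric vector of selection-index weights in `[0, 1]`; `w = 0`
#'   selects on purebred performance, `w = 1` on crossbred performance.
#' @param n_generations Generations of selection.
#' @param n_replicates Number of replicate simulations.
#' @param genome A [genome_config()].
#' @param selection A [selection_config()].
#' @param chain A [chain_config()].
#' @param n_founders Founders drawn per breed from the historical population.
#' @param n_breed_generations Generations of random mating after breed
#'   founding, before selection starts.
#' @param master_seed Integer master seed; per-replicate seeds are derived
#'   from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(model_id = 1L,
                         training_mode = c("purebred", "crossbred"),
                         w = c(0, 0.25, 0.5, 0.75, 1),
                         n_generations = 40L,
                         n_replicates = 50L,
                         genome = genome_config(),
                         selection = selection_config(),
                         chain = chain_config(),
                         n_founders = 100L,
                         n_breed_generations = 100L,
                         master_seed = 1L) {
  training_mode <- match.arg(training_mode)
  if (any(w < 0 | w > 1))
    stop("configuration error: all w must be in [0, 1]", call. = FALSE)
  cfg <- list(model_id = as.integer(model_id),
              training_mode = training_mode,
              w = as.numeric(w),
              n_generations = as.integer(n_generations),
              n_replicates = as.integer(n_replicates),
              genome = validate_genome_config(genome),
              selection = selection,
              chain = chain,
              n_founders = as.integer(n_founders),
              n_breed_generations = as.integer(n_breed_generations),
              master_seed = as.integer(master_seed))
  class(cfg) <- "study_config"
  cfg
}

#' Ready-made study profiles
#'
#' `"paper"` is the full-scale study design (40 generations, 50 replicates,
#' 4000 SNPs / 400 QTL, 1000 candidates per breed, 20000-iteration chains);
#' it is intended for cluster use. `"test"` is a reduced profile (400 SNPs /
#' 40 QTL, 300 candidates, 2000/500 chains, 15 generations, 5 replicates,
#' and a smaller historical population) that preserves the qualitative
#' behaviour of the program at a fraction of the cost.
#'
#' @param profile `"paper"` or `"test"`.
#' @param ... Overrides passed on to [study_config()].
#' @return A [study_config()].
#' @export
study_profile <- function(profile = c("paper", "test"), ...) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    study_config(...)
  } else {
    args <- list(
      w = c(0, 0.5, 1),
      n_generations = 15L,
      n_replicates = 5L,
      genome = genome_config(n_snps_target = 400L, n_qtl_target = 40L,
                             historical_size = 500L,
                             historical_generations = 300L),
      selection = selection_config(n_candidates = 300L,
                                   n_males_selected = 30L,
                                   n_females_selected = 60L,
                                   n_crossbred_offspring = 300L),
      chain = chain_config(niter = 2000L, burnin = 500L)
    )
    override <- list(...)
    args[names(override)] <- override
    do.call(study_config, args)
  }
}

#' Read a study configuration from a YAML file
#'
#' The YAML document mirrors the fields of [study_config()]; nested blocks
#' `genome`, `selection` and `chain` mirror the fields of the corresponding
#' constructors. Missing fields take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- doc[setdiff(names(doc), c("genome", "selection", "chain"))]
  if (!is.null(doc$genome)) args$genome <- do.call(genome_config, doc$genome)
  if (!is.null(doc$selection)) args$selection <- do.call(selection_config, doc$selection)
  if (!is.null(doc$chain)) args$chain <- do.call(chain_config, doc$chain)
  do.call(study_config, args)
}
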