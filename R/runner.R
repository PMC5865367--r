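#' Set up the base populations and trait architecture for one replicate
#'
#' Runs the historical simulation, samples the SNP/QTL architecture and the
#' QTL effects, scales effects to the target variance components at the
#' historical (generation-2000) allele frequencies, founds breeds A and B,
#' and phenotypes the generation-0 candidate cohorts. In crossbred-training
#' mode an initial crossbred cohort from randomly selected parents is also
#' produced, so that a training population exists in the first generation.
#'
#' The returned state is shared by all selection-criterion scenarios of the
#' replicate (common random numbers): scenarios branch only through the
#' selection decisions.
#'
#' @param config A [study_config()].
#' @return A list with the map, SNP/QTL indices, scaled effects, trait
#'   config, phenotyped base cohorts `A` and `B`, and (crossbred mode) `AB0`.
#' @export
setup_base <- function(config) {
  trait <- genetic_model(config$model_id)
  hist <- simulate_historical(config$genome)
  map <- sample_architecture(hist$panel, hist$map, config$genome)
  snp_idx <- loci_of_class(map, "SNP")
  qtl_idx <- loci_of_class(map, "QTL")
  effects <- sample_effects(length(qtl_idx), trait$overdominance_allowed)
  base_freq <- allele_freq(hist$panel, qtl_idx)
  effects <- scale_effects(effects, base_freq, trait)
  breeds <- found_breeds(hist$panel, map,
                         n_founders = config$n_founders,
                         n_breed_generations = config$n_breed_generations,
                         n_candidates = config$selection$n_candidates)
  base <- list(map = map, snp_idx = snp_idx, qtl_idx = qtl_idx,
               effects = effects, trait = trait, base_freq = base_freq,
               A = phenotype_cohort(breeds$A, effects, qtl_idx, trait),
               B = phenotype_cohort(breeds$B, effects, qtl_idx, trait))
  if (config$training_mode == "crossbred") {
    n_ab <- 2L * config$selection$n_crossbred_offspring
    sel <- config$selection
    rand_parents <- function(cohort, n_m, n_f)
      select_top(cohort$panel, stats::runif(n_ind(cohort$panel)), n_m, n_f)
    pa <- rand_parents(base$A, sel$n_males_selected, sel$n_females_selected)
    pb <- rand_parents(base$B, sel$n_males_selected, sel$n_females_selected)
    ab <- mate(pa$sires, pb$dams, n_ab, map, breed_label = "AB")
    base$AB0 <- phenotype_cohort(ab, effects, qtl_idx, trait)
  }
  base
}

# A cohort is a panel plus its genotypic values and phenotypes, assigned
# once at creation.
phenotype_cohort <- function(panel, effects, qtl_idx, trait) {
  gv <- genotypic_value(panel, effects, qtl_idx)
  list(panel = panel, gv = gv, y = simulate_phenotypes(gv, trait$sigma2_e))
}

#' Run one selection scenario (one value of w) from a shared base state
#'
#' Per generation: estimate marker effects (per breed on purebred data, or
#' once on the crossbred cohort), compute GEBV-P and GEBV-C from the two
#' breeds' current SNP frequencies, blend them into the selection criterion
#' with weight `w`, record the selection accuracy, truncation-select sires
#' and dams per breed, and produce the next purebred cohorts and the
#' crossbred progeny of the selected A sires and B dams.
#'
#' Reported rows compare contemporaneous cohorts: row `t` holds the mean
#' phenotype of the crossbreds produced by the generation-`t` selection (CP),
#' the means of the purebred replacement cohorts born at the same time, their
#' average (BA), and heterosis `H = CP - BA`.
#'
#' @param base Result of [setup_base()].
#' @param config A [study_config()].
#' @param w Selection-criterion weight in `[0, 1]`.
#' @return A list with `stats` (one data-frame row per generation),
#'   `fixation`, `overdominance` (final-generation summaries) and the final
#'   cohorts.
#' @export
run_scenario <- function(base, config, w) {
  sel <- config$selection
  trait <- base$trait
  map <- base$map
  A <- base$A; B <- base$B
  AB <- if (config$training_mode == "crossbred") base$AB0 else NULL
  n_cross <- if (config$training_mode == "crossbred")
    2L * sel$n_crossbred_offspring else sel$n_crossbred_offspring
  G <- config$n_generations
  rows <- vector("list", G)

  for (t in seq_len(G)) {
    freq_snp_A <- allele_freq(A$panel, base$snp_idx)
    freq_snp_B <- allele_freq(B$panel, base$snp_idx)
    freq_qtl_A <- allele_freq(A$panel, base$qtl_idx)
    freq_qtl_B <- allele_freq(B$panel, base$qtl_idx)

    if (config$training_mode == "purebred") {
      fit_A <- brr_dom(A$y, dosage(A$panel, base$snp_idx), chain = config$chain)
      fit_B <- brr_dom(B$y, dosage(B$panel, base$snp_idx), chain = config$chain)
    } else {
      fit_A <- fit_B <- brr_dom(AB$y, dosage(AB$panel, base$snp_idx),
                                chain = config$chain)
    }

    score_breed <- function(cohort, fit, own_snp, other_snp, other_qtl) {
      gp <- gebv(cohort$panel, fit, base$snp_idx, own_snp)
      gc <- gebv(cohort$panel, fit, base$snp_idx, other_snp)
      sc <- selection_criterion(gp, gc, w)
      tbv_c <- true_breeding_values(cohort$panel, base$effects, base$qtl_idx,
                                    other_qtl)
      list(sc = sc, acc = selection_accuracy(sc, tbv_c))
    }
    sA <- score_breed(A, fit_A, freq_snp_A, freq_snp_B, freq_qtl_B)
    sB <- score_breed(B, fit_B, freq_snp_B, freq_snp_A, freq_qtl_A)

    par_A <- select_top(A$panel, sA$sc, sel$n_males_selected, sel$n_females_selected)
    par_B <- select_top(B$panel, sB$sc, sel$n_males_selected, sel$n_females_selected)

    AB <- phenotype_cohort(
      mate(par_A$sires, par_B$dams, n_cross, map, breed_label = "AB"),
      base$effects, base$qtl_idx, trait)
    A_next <- phenotype_cohort(
      mate(par_A$sires, par_A$dams, sel$n_purebred_offspring, map, "A"),
      base$effects, base$qtl_idx, trait)
    B_next <- phenotype_cohort(
      mate(par_B$sires, par_B$dams, sel$n_purebred_offspring, map, "B"),
      base$effects, base$qtl_idx, trait)

    cp <- mean(AB$y)
    mean_A <- mean(A_next$y); mean_B <- mean(B_next$y)
    ba <- mean(c(mean_A, mean_B))
    p_next_A <- allele_freq(A_next$panel, base$qtl_idx)
    p_next_B <- allele_freq(B_next$panel, base$qtl_idx)
    rows[[t]] <- data.frame(
      generation = t, w = w,
      mean_A = mean_A, mean_B = mean_B, BA = ba, CP = cp,
      H = heterosis(cp, c(mean_A, mean_B)),
      # drift/selection-driven divergence component of heterosis, free of
      # cohort sampling noise: sum_j d_j (p_Aj - p_Bj)^2 at the QTL
      H_expected = expected_f1_heterosis(base$effects, p_next_A, p_next_B),
      accuracy_A = sA$acc, accuracy_B = sB$acc,
      n_fixed_A = sum(p_next_A == 0 | p_next_A == 1),
      n_fixed_B = sum(p_next_B == 0 | p_next_B == 1))
    A <- A_next; B <- B_next
  }

  stats <- do.call(rbind, rows)
  list(stats = stats,
       fixation = fixation_summary(A$panel, B$panel, base$effects, base$qtl_idx),
       overdominance = overdominant_fixation_summary(A$panel, B$panel,
                                                     base$effects, base$qtl_idx),
       final = list(A = A, B = B, AB = AB))
}

#' Run one replicate over the configured grid of selection weights
#'
#' Draws the base state once (common random numbers), then runs each `w`
#' scenario from a scenario seed derived from the replicate seed and `w`, so
#' the whole replicate is deterministic given its seed.
#'
#' @param config A [study_config()].
#' @param replicate_seed Integer seed of this replicate.
#' @return A list with `stats`, `fixation` and `overdominance` data frames
#'   (all carrying `replicate_seed` and `w` columns).
#' @export
run_replicate <- function(config, replicate_seed) {
  set.seed(replicate_seed)
  base <- setup_base(config)
  stats <- fix <- od <- vector("list", length(config$w))
  for (k in seq_along(config$w)) {
    w <- config$w[k]
    set.seed(scenario_seed(replicate_seed, w))
    res <- run_scenario(base, config, w)
    res$stats$replicate_seed <- replicate_seed
    stats[[k]] <- res$stats
    fix[[k]] <- cbind(data.frame(replicate_seed = replicate_seed, w = w),
                      as.data.frame(res$fixation))
    od[[k]] <- cbind(data.frame(replicate_seed = replicate_seed, w = w),
                     as.data.frame(res$overdominance))
  }
  list(stats = do.call(rbind, stats),
       fixation = do.call(rbind, fix),
       overdominance = do.call(rbind, od))
}

scenario_seed <- function(replicate_seed, w) {
  (as.integer(replicate_seed) %% 1000000L) * 101L + as.integer(round(100 * w)) + 17L
}

replicate_seeds <- function(config) {
  (as.integer(config$master_seed) %% 100000L) * 10000L +
    7L * seq_len(config$n_replicates)
}

#' Run the full study (all replicates and selection weights)
#'
#' @param config A [study_config()].
#' @param progress Print one line per replicate.
#' @return A list of data frames `stats`, `fixation`, `overdominance` pooled
#'   over replicates, plus the `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  seeds <- replicate_seeds(config)
  out <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    if (progress) message(sprintf("replicate %d/%d (seed %d)",
                                  i, length(seeds), seeds[i]))
    out[[i]] <- run_replicate(config, seeds[i])
  }
  list(stats = do.call(rbind, lapply(out, `[[`, "stats")),
       fixation = do.call(rbind, lapply(out, `[[`, "fixation")),
       overdominance = do.call(rbind, lapply(out, `[[`, "overdominance")),
       config = config)
}

#' QTL fixation summary at the final generation
#'
#' Total fixation is the percentage of QTL fixed for either allele, averaged
#' over the two breeds. Common/alternate percentages partition the QTL that
#' are fixed in *both* breeds into same-allele and opposite-allele fixation.
#' The favorable allele of a QTL is the one whose homozygote has genotypic
#' value `+|a|` (the sign of the additive effect decides); favorable and
#' unfavorable percentages are computed per breed over that breed's fixed
#' QTL and then averaged. Empty denominators give `NA`, never 0.
#'
#' @param panel_A,panel_B Final-generation purebred [hap_panel()]s.
#' @param effects `qtl_effects` of the realized architecture.
#' @param qtl_idx QTL column indices.
#' @return A list with `total`, `common`, `alternate`, `favorable`,
#'   `unfavorable` percentages.
#' @export
fixation_summary <- function(panel_A, panel_B, effects, qtl_idx) {
  p_A <- allele_freq(panel_A, qtl_idx)
  p_B <- allele_freq(panel_B, qtl_idx)
  fixation_from_freqs(p_A, p_B, effects$a)
}

fixation_from_freqs <- function(p_A, p_B, a) {
  fix_A <- p_A == 0 | p_A == 1
  fix_B <- p_B == 0 | p_B == 1
  both <- fix_A & fix_B
  pct <- function(x) 100 * x
  common <- alternate <- NA_real_
  if (any(both)) {
    same <- p_A[both] == p_B[both]
    common <- pct(mean(same))
    alternate <- pct(mean(!same))
  }
  fav_share <- function(p, fixed) {
    if (!any(fixed)) return(NA_real_)
    fixed_allele_is_1 <- p[fixed] == 1
    favorable <- ifelse(a[fixed] > 0, fixed_allele_is_1, !fixed_allele_is_1)
    pct(mean(favorable))
  }
  fav <- mean(c(fav_share(p_A, fix_A), fav_share(p_B, fix_B)))
  list(total = pct(mean(c(mean(fix_A), mean(fix_B)))),
       common = common, alternate = alternate,
       favorable = fav,
       unfavorable = if (is.na(fav)) NA_real_ else 100 - fav)
}

#' Fixation of over-dominant QTL at the final generation
#'
#' Restricts the fixation summary to the QTL whose realized dominance
#' deviation exceeds the additive effect in magnitude (`|d| > |a|`). When the
#' architecture contains no over-dominant QTL (genetic model 3) the result
#' is flagged not applicable.
#'
#' @inheritParams fixation_summary
#' @return A list with `applicable`, `n_overdominant`, `total`, `common`,
#'   `alternate` (percentages; `NA` where denominators are empty).
#' @export
overdominant_fixation_summary <- function(panel_A, panel_B, effects, qtl_idx) {
  od <- abs(effects$d) > abs(effects$a)
  if (!any(od))
    return(list(applicable = FALSE, n_overdominant = 0L,
                total = NA_real_, common = NA_real_, alternate = NA_real_))
  p_A <- allele_freq(panel_A, qtl_idx)[od]
  p_B <- allele_freq(panel_B, qtl_idx)[od]
  fx <- fixation_from_freqs(p_A, p_B, effects$a[od])
  list(applicable = TRUE, n_overdominant = sum(od),
       total = fx$total, common = fx$common, alternate = fx$alternate)
}

#' Response curves relative to a reference selection criterion
#'
#' Per generation, the replicate-mean crossbred performance of each `w` is
#' compared to the reference weight (`w = 0` by default), either as a
#' difference (default) or a ratio. A cumulative-response column (CP minus
#' the first-generation replicate-mean CP of the same `w`) is included.
#'
#' @param stats Generation statistics from [run_study()] / [run_replicate()].
#' @param reference_w Reference weight (default 0).
#' @param type `"difference"` or `"ratio"`.
#' @return Data frame with columns `w`, `generation`, `CP_mean`, `relative`
#'   and `cumulative`.
#' @export
relative_response <- function(stats, reference_w = 0,
                              type = c("difference", "ratio")) {
  type <- match.arg(type)
  if (!any(stats$w == reference_w))
    stop("configuration error: reference weight not present in stats", call. = FALSE)
  agg <- stats::aggregate(CP ~ w + generation, data = stats, FUN = mean)
  ref <- agg[agg$w == reference_w, c("generation", "CP")]
  names(ref)[2] <- "CP_ref"
  out <- merge(agg, ref, by = "generation")
  out$relative <- if (type == "difference") out$CP - out$CP_ref
                  else out$CP / out$CP_ref
  first <- stats::aggregate(CP ~ w, data = agg[agg$generation == min(agg$generation), ],
                            FUN = mean)
  names(first)[2] <- "CP_first"
  out <- merge(out, first, by = "w")
  out$cumulative <- out$CP - out$CP_first
  names(out)[names(out) == "CP"] <- "CP_mean"
  out[order(out$w, out$generation),
      c("w", "generation", "CP_mean", "relative", "cumulative")]
}

#' Replicate means and standard errors of generation statistics
#'
#' @param stats Generation statistics with a `replicate_seed` column.
#' @param value Name of the column to aggregate (default `"CP"`).
#' @return Data frame with `w`, `generation`, `mean`, `se` and `n`.
#' @export
aggregate_replicates <- function(stats, value = "CP") {
  split_by <- interaction(stats$w, stats$generation, drop = TRUE)
  res <- lapply(split(stats, split_by), function(g) {
    x <- g[[value]]
    n <- length(x)
    data.frame(w = g$w[1], generation = g$generation[1],
               mean = mean(x),
               se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
               n = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$w, out$generation), ]
}
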