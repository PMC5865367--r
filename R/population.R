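#' Found two breeds from the historical population
#'
#' Draws two disjoint random samples of founders from the historical panel,
#' randomly mates each at constant size for `n_breed_generations`
#' generations (no mutation), and finally expands each breed to
#' `n_candidates` individuals by one round of random mating. The expanded
#' cohorts are the generation-0 selection candidates of breeds A and B.
#'
#' @param historical The historical [hap_panel()].
#' @param map The matching `genetic_map`.
#' @param n_founders Founders per breed.
#' @param n_breed_generations Generations of within-breed random mating.
#' @param n_candidates Size of the expanded generation-0 cohorts.
#' @return A list with [hap_panel()]s `A` and `B`.
#' @export
found_breeds <- function(historical, map, n_founders = 100L,
                         n_breed_generations = 100L, n_candidates = 1000L) {
  n <- n_ind(historical)
  if (n < 2L * n_founders)
    stop("configuration error: historical panel too small for 2 disjoint founder samples",
         call. = FALSE)
  picks <- sample(n, 2L * n_founders)
  ma <- map_cpp_args(map)
  make_breed <- function(idx, label) {
    founders <- subset_panel(historical, idx)
    haps <- founders$haps
    if (n_breed_generations > 0L)
      haps <- cpp_random_mate_generations(haps, n_breed_generations,
                                          ma$chrom_start, ma$chrom_end,
                                          ma$chrom_len, ma$pos, 0)
    breed <- hap_panel(haps,
                       sex = rep(c("M", "F"), each = ceiling(n_founders / 2))[seq_len(n_founders)],
                       breed = label, generation = 0L)
    if (n_candidates != n_ind(breed) || n_breed_generations > 0L) {
      sires <- which(breed$sex == "M")
      dams <- which(breed$sex == "F")
      breed <- mate(subset_panel(breed, sires), subset_panel(breed, dams),
                    n_candidates, map, breed_label = label)
      breed$generation <- 0L
    }
    breed
  }
  list(A = make_breed(picks[seq_len(n_founders)], "A"),
       B = make_breed(picks[n_founders + seq_len(n_founders)], "B"))
}

#' Simulate one meiosis
#'
#' Produces a single gamete from one individual: per chromosome, the number
#' of crossovers is Poisson with mean equal to the chromosome length in
#' Morgans, crossover positions are uniform, and there is no interference
#' (Haldane model). Chromosomes segregate independently.
#'
#' @param panel A [hap_panel()].
#' @param individual Position (not id) of the parent in the panel.
#' @param map The matching `genetic_map`.
#' @return Integer vector: the gamete's 0/1 alleles.
#' @export
meiosis <- function(panel, individual, map) {
  ma <- map_cpp_args(map)
  drop(cpp_gametes(panel$haps, as.integer(individual),
                   ma$chrom_start, ma$chrom_end, ma$chrom_len, ma$pos, 0))
}

#' Random mating between a sire panel and a dam panel
#'
#' Each offspring draws an independent uniform (sire, dam) pair, with
#' replacement. The paternal gamete becomes the offspring's first haplotype,
#' the maternal gamete the second; for an A-sire x B-dam cross every
#' crossbred therefore carries one A-origin and one B-origin haplotype.
#' Sexes are assigned deterministically, alternating M/F, so each cohort
#' splits exactly half and half.
#'
#' @param sires,dams [hap_panel()]s of the selected parents (may come from
#'   different breeds).
#' @param n_offspring Number of offspring to produce.
#' @param map The matching `genetic_map`.
#' @param breed_label Breed label of the offspring cohort (e.g. `"A"` or
#'   `"AB"`); defaults to the sires' label when both parents share it.
#' @return A [hap_panel()] of the offspring, generation = sire generation + 1.
#' @export
mate <- function(sires, dams, n_offspring, map, breed_label = NULL) {
  if (n_ind(sires) < 1L || n_ind(dams) < 1L)
    stop("configuration error: need at least one sire and one dam", call. = FALSE)
  n_offspring <- as.integer(n_offspring)
  if (n_offspring < 1L) stop("configuration error: n_offspring must be positive",
                             call. = FALSE)
  if (is.null(breed_label)) {
    lab_s <- unique(sires$breed); lab_d <- unique(dams$breed)
    breed_label <- if (identical(lab_s, lab_d)) lab_s[1] else paste0(lab_s[1], lab_d[1])
  }
  ns <- n_ind(sires); nd <- n_ind(dams)
  s_draw <- sample.int(ns, n_offspring, replace = TRUE)
  d_draw <- sample.int(nd, n_offspring, replace = TRUE)
  combined <- rbind(sires$haps, dams$haps)
  ma <- map_cpp_args(map)
  haps <- cpp_mate(combined, s_draw, ns + d_draw,
                   ma$chrom_start, ma$chrom_end, ma$chrom_len, ma$pos, 0)
  hap_panel(haps,
            id = seq_len(n_offspring),
            sire = sires$id[s_draw], dam = dams$id[d_draw],
            sex = rep_len(c("M", "F"), n_offspring),
            breed = breed_label,
            generation = sires$generation + 1L)
}

#' Truncation selection of parents
#'
#' Keeps the `n_males` highest-scoring males and the `n_females`
#' highest-scoring females. Ties are broken by ascending individual id.
#'
#' @param panel Candidate [hap_panel()].
#' @param scores Numeric selection scores aligned to the panel.
#' @param n_males,n_females Numbers to keep per sex.
#' @return A list of [hap_panel()]s `sires` and `dams`.
#' @export
select_top <- function(panel, scores, n_males, n_females) {
  if (length(scores) != n_ind(panel))
    stop("scores must align with candidates", call. = FALSE)
  pick_sex <- function(sex, k) {
    idx <- which(panel$sex == sex)
    if (length(idx) < k)
      stop(sprintf("selection error: %d %s candidates available, %d requested",
                   length(idx), if (sex == "M") "male" else "female", k),
           call. = FALSE)
    ord <- idx[order(-scores[idx], panel$id[idx])]
    ord[seq_len(k)]
  }
  list(sires = subset_panel(panel, pick_sex("M", n_males)),
       dams = subset_panel(panel, pick_sex("F", n_females)))
}
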