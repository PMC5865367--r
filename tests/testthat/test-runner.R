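test_that("a small study runs end to end and satisfies its accounting identities", {
  cfg <- tiny_study()
  res <- run_replicate(cfg, 4242L)
  expect_equal(nrow(res$stats), 2L * 2L)  # 2 generations x 2 weights
  expect_true(all(is.finite(res$stats$CP)))
  expect_equal(res$stats$H, res$stats$CP - res$stats$BA, tolerance = 1e-12)
  expect_equal(res$stats$BA, (res$stats$mean_A + res$stats$mean_B) / 2,
               tolerance = 1e-12)
  expect_true(all(res$stats$accuracy_A >= -1 & res$stats$accuracy_A <= 1))
  expect_equal(sort(unique(res$stats$w)), c(0, 1))
  expect_named(res$fixation,
               c("replicate_seed", "w", "total", "common", "alternate",
                 "favorable", "unfavorable"))
  # fixation counters never decrease: fixation is absorbing without mutation
  for (w in unique(res$stats$w)) {
    s <- res$stats[res$stats$w == w, ]
    expect_true(all(diff(s$n_fixed_A) >= 0))
    expect_true(all(diff(s$n_fixed_B) >= 0))
  }
})

test_that("replicates are deterministic and share the base state across weights", {
  cfg <- tiny_study()
  r1 <- run_replicate(cfg, 99L)
  r2 <- run_replicate(cfg, 99L)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$fixation, r2$fixation)
  # common random numbers: the w = 0 scenario is unchanged when the weight
  # grid changes, because scenarios branch only after the shared base setup
  cfg0 <- tiny_study(w = 0)
  r0 <- run_replicate(cfg0, 99L)
  expect_identical(r0$stats, r1$stats[r1$stats$w == 0, ])
})

test_that("crossbred training mode trains on a doubled crossbred cohort", {
  cfg <- tiny_study(training_mode = "crossbred", w = 1)
  set.seed(77)
  base <- setup_base(cfg)
  expect_false(is.null(base$AB0))
  expect_equal(n_ind(base$AB0$panel), 2L * cfg$selection$n_crossbred_offspring)
  expect_equal(unique(base$AB0$panel$breed), "AB")
  res <- run_replicate(cfg, 7L)
  expect_equal(nrow(res$stats), cfg$n_generations)
})

test_that("fixation summaries count alleles the way the definitions state", {
  eff <- toy_effects(a = c(1, -1, 0.5, 2), d = rep(0.1, 4))
  all1 <- toy_panel(matrix(1L, 10L, 4L), breed = "A")
  all0 <- toy_panel(matrix(0L, 10L, 4L), breed = "B")
  # A fixed for allele 1 everywhere, B for allele 0: all alternate
  fx <- fixation_summary(all1, all0, eff, 1:4)
  expect_equal(fx$total, 100)
  expect_equal(fx$common, 0)
  expect_equal(fx$alternate, 100)
  # identical full fixation on allele 1: common 100; favorable follows sign(a)
  fx2 <- fixation_summary(all1, all1, eff, 1:4)
  expect_equal(fx2$common, 100)
  expect_equal(fx2$favorable, 75)  # 3 of 4 have a > 0
  expect_equal(fx2$unfavorable, 25)
  # nothing fixed: total 0, shares undefined (missing, never zero)
  set.seed(701)
  seg <- hwe_panel(50, rep(0.5, 4))
  fx3 <- fixation_summary(seg, seg, eff, 1:4)
  expect_equal(fx3$total, 0)
  expect_true(is.na(fx3$common) && is.na(fx3$alternate) && is.na(fx3$favorable))
})

test_that("over-dominant fixation is restricted to the over-dominant set", {
  # 4 over-dominant QTL; fix 3 of them in both breeds
  eff <- toy_effects(a = rep(0.5, 5), d = c(rep(1, 4), 0.1))
  hapsA <- cbind(matrix(1L, 10, 3), matrix(0L, 10, 1),
                 rep(0:1, 5))
  hapsB <- cbind(matrix(1L, 10, 2), matrix(0L, 10, 2), rep(0:1, 5))
  fx <- overdominant_fixation_summary(toy_panel(hapsA), toy_panel(hapsB),
                                      eff, 1:5)
  expect_true(fx$applicable)
  expect_equal(fx$n_overdominant, 4L)
  expect_equal(fx$total, 100)       # all 4 od QTL fixed in each breed
  expect_equal(fx$common, 75)       # 3 of the 4 share the fixed allele
  expect_equal(fx$alternate, 25)
  # no over-dominance (model 3): not applicable
  eff3 <- toy_effects(a = rep(1, 5), d = rep(0.5, 5))
  fx3 <- overdominant_fixation_summary(toy_panel(hapsA), toy_panel(hapsB),
                                       eff3, 1:5)
  expect_false(fx3$applicable)
  expect_true(is.na(fx3$total))
})

test_that("relative and cumulative response curves follow their definitions", {
  stats <- expand.grid(replicate_seed = 1:3, generation = 1:4, w = c(0, 1))
  stats$CP <- stats$generation * 0.5 + ifelse(stats$w == 1, 1, 0)
  rr <- relative_response(stats, reference_w = 0)
  expect_equal(rr$relative[rr$w == 0], rep(0, 4))
  expect_equal(rr$relative[rr$w == 1], rep(1, 4))
  expect_equal(rr$cumulative[rr$w == 1 & rr$generation == 4], 1.5)
  rat <- relative_response(stats, reference_w = 0, type = "ratio")
  expect_equal(rat$relative[rat$w == 0], rep(1, 4))
  expect_error(relative_response(stats, reference_w = 0.5), "reference weight")
})

test_that("replicate aggregation reproduces direct computation", {
  stats <- data.frame(replicate_seed = c(1, 2, 3), generation = 1, w = 0,
                      CP = c(1, 2, 4))
  agg <- aggregate_replicates(stats)
  expect_equal(agg$mean, mean(c(1, 2, 4)))
  expect_equal(agg$se, stats::sd(c(1, 2, 4)) / sqrt(3))
  expect_equal(agg$n, 3L)
  one <- aggregate_replicates(stats[1, ])
  expect_true(is.na(one$se))
  two <- aggregate_replicates(data.frame(replicate_seed = 1:2, generation = 1,
                                         w = 0, CP = c(5, 5)))
  expect_equal(two$se, 0)
})

test_that("study configurations round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("model_id: 2", "training_mode: purebred",
               "w: [0.0, 0.5]", "n_generations: 3", "n_replicates: 2",
               "genome:", "  n_snps_target: 40", "  n_qtl_target: 8",
               "  historical_size: 60", "  historical_generations: 30",
               "selection:", "  n_candidates: 40", "  n_males_selected: 4",
               "  n_females_selected: 8", "chain:", "  niter: 400",
               "  burnin: 100"), path)
  cfg <- read_study_config(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$model_id, 2L)
  expect_equal(cfg$w, c(0, 0.5))
  expect_equal(cfg$genome$n_snps_target, 40L)
  expect_equal(cfg$chain$niter, 400L)
})

test_that("panel and architecture exports are written and re-readable", {
  set.seed(702)
  cfg <- tiny_genome()
  hist <- simulate_historical(cfg)
  map <- sample_architecture(hist$panel, hist$map, cfg)
  qtl <- loci_of_class(map, "QTL")
  eff <- scale_effects(sample_effects(length(qtl)),
                       allele_freq(hist$panel, qtl), genetic_model(1))
  tmp <- tempfile()
  write_architecture_csv(map, eff, allele_freq(hist$panel, qtl), paste0(tmp, ".csv"))
  arch <- utils::read.csv(paste0(tmp, ".csv"))
  expect_equal(nrow(arch), nrow(map))
  expect_equal(sum(arch$class == "QTL"), length(qtl))
  expect_equal(arch$a[arch$class == "QTL"], eff$a)
  write_plink(hist$panel, map, tmp)
  ped <- utils::read.table(paste0(tmp, ".ped"))
  mp <- utils::read.table(paste0(tmp, ".map"))
  expect_equal(nrow(ped), n_ind(hist$panel))
  expect_equal(ncol(ped), 6L + 2L * nrow(map))
  expect_equal(nrow(mp), nrow(map))
  # phased order preserved: first allele column is the paternal haplotype
  expect_equal(ped[, 7], hist$panel$haps[seq(1, 2 * n_ind(hist$panel), 2), 1] + 1L)
  fit <- list(a = stats::rnorm(3), d = stats::rnorm(3), mu = 0.5, s2a = 1,
              s2d = 1, s2e = 1, chain_config = chain_config(),
              geweke = c(mu = 0.1))
  write_estimates(fit, 1:3, tmp)
  est <- utils::read.csv(paste0(tmp, ".csv"))
  expect_equal(est$a_hat, fit$a)
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(side$mu, 0.5)
})
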