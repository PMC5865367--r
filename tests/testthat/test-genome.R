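test_that("degenerate configurations are rejected", {
  expect_error(genome_config(historical_size = 0), "historical_size")
  expect_error(genome_config(n_candidate_loci = 100, n_snps_target = 90,
                             n_qtl_target = 20), "n_candidate_loci")
  expect_error(genome_config(chromosome_length = 0), "chromosome_length")
  expect_error(genome_config(mutation_rate = 1.5), "mutation_rate")
  expect_error(trait_config(sigma2_d = 0.8), "sigma2_p")
  expect_error(genetic_model(4), "model_id")
})

test_that("historical simulation keeps enough polymorphic loci for the architecture", {
  set.seed(101)
  cfg <- tiny_genome(historical_size = 200L, historical_generations = 100L)
  hist <- simulate_historical(cfg)
  expect_equal(n_ind(hist$panel), 200L)
  expect_equal(ncol(hist$panel$haps), cfg$n_candidate_loci)
  p <- allele_freq(hist$panel)
  # mutation-drift balance: at least half the candidates stay above MAF 0.05
  expect_gte(sum(pmin(p, 1 - p) > cfg$maf_threshold_arch),
             cfg$n_candidate_loci / 2)
  map <- sample_architecture(hist$panel, hist$map, cfg)
  snp <- loci_of_class(map, "SNP"); qtl <- loci_of_class(map, "QTL")
  expect_length(snp, 40L)
  expect_length(qtl, 8L)
  expect_length(intersect(snp, qtl), 0L)
  # per-chromosome counts and the MAF condition
  expect_equal(unname(table(map$chrom[snp])), rep(10L, 4L),
               ignore_attr = TRUE)
  expect_equal(unname(table(map$chrom[qtl])), rep(2L, 4L), ignore_attr = TRUE)
  expect_true(all(pmin(p, 1 - p)[c(snp, qtl)] > cfg$maf_threshold_arch))
})

test_that("architecture sampling fails informatively without polymorphism", {
  set.seed(102)
  cfg <- tiny_genome()
  map <- build_map(cfg)
  fixed <- hap_panel(matrix(1L, 20L, cfg$n_candidate_loci))
  expect_error(sample_architecture(fixed, map, cfg), "insufficient polymorphism")
  expect_error(sample_architecture(fixed, map, cfg), "shortfall")
})

test_that("heterozygosity decays at the neutral drift rate when mutation is off", {
  set.seed(103)
  N <- 50L; t <- 100L
  cfg <- genome_config(n_snps_target = 100L, n_qtl_target = 20L,
                       n_candidate_loci = 300L, mutation_rate = 0,
                       historical_size = N, historical_generations = t)
  ratio <- replicate(20, {
    hist <- simulate_historical(cfg)
    # initial frequencies are uniform, so the expected initial heterozygosity
    # of the realized founder draw is recovered per locus from the founders:
    # compare against the analytic decay of the uniform-start expectation 1/3
    expected_heterozygosity(hist$panel)
  })
  analytic <- (1 / 3) * (1 - 1 / (2 * N))^t
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - analytic), 3 * se + 0.005)
})

test_that("offspring haplotypes are parental when recombination cannot occur", {
  set.seed(104)
  # chromosome short enough that Poisson(len) crossovers are essentially 0
  map <- toy_map(pos = c(0, 1e-9, 2e-9), chrom_len = 1e-8)
  parents <- toy_panel(rbind(c(1L, 1L, 1L), c(0L, 0L, 0L),
                             c(1L, 0L, 1L), c(0L, 1L, 0L)),
                       sex = c("M", "F"))
  off <- mate(subset_panel(parents, 1L), subset_panel(parents, 2L), 10L, map)
  parental <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1), c(0, 1, 0))
  for (r in seq_len(nrow(off$haps)))
    expect_true(any(apply(parental, 1, function(h) all(h == off$haps[r, ]))))
})

test_that("sampled effect magnitudes follow the gamma and normal conventions", {
  set.seed(105)
  eff <- sample_effects(1e6)
  # gamma(shape 0.4, scale 1.66): mean = 0.664
  expect_lt(abs(mean(abs(eff$a)) - 0.4 * 1.66), 0.01)
  # both signs of a occur about equally
  expect_lt(abs(mean(eff$a > 0) - 0.5), 0.005)
  # fraction with |h| > 1 matches the N(0.5, 1) tails
  expected_od <- stats::pnorm(-1, 0.5, 1) + stats::pnorm(1, 0.5, 1, lower.tail = FALSE)
  expect_lt(abs(mean(abs(eff$h) > 1) - expected_od), 0.005)
  # d = h * |a| at sampling time
  expect_equal(eff$d, eff$h * abs(eff$a), tolerance = 1e-12)
})

test_that("suppressing over-dominance clamps the sampled architecture", {
  set.seed(106)
  eff <- sample_effects(5000, overdominance_allowed = FALSE)
  expect_lte(max(abs(eff$d) - abs(eff$a)), 0)
})

test_that("variance decomposition matches closed forms", {
  expect_equal(compute_variances(toy_effects(1, 0), 0.5),
               c(sigma2_a = 0.5, sigma2_d = 0), tolerance = 1e-12)
  # a = 0, d = 1 at p = 0.5: alpha = 0, so all variance is dominance
  expect_equal(compute_variances(toy_effects(0, 1), 0.5),
               c(sigma2_a = 0, sigma2_d = 0.25), tolerance = 1e-12)
  # fixed loci contribute nothing
  expect_equal(compute_variances(toy_effects(c(1, 2), c(1, -1)), c(0, 1)),
               c(sigma2_a = 0, sigma2_d = 0), tolerance = 1e-12)
  expect_error(compute_variances(toy_effects(1, 0), c(0.5, 0.5)), "dimension")
})

test_that("variance decomposition matches an empirical HWE population", {
  set.seed(107)
  p <- c(0.2, 0.5, 0.8, 0.35)
  eff <- toy_effects(a = c(1, -0.5, 0.8, 0.3), d = c(0.5, 0.7, -0.4, 1.2))
  v <- compute_variances(eff, p)
  # oracle: large HWE population, per-locus regression of genotypic value on
  # dosage partitions variance into additive (regression) and dominance
  # (residual) components; loci are independent so components add
  n <- 2e5
  va_emp <- vd_emp <- 0
  for (j in seq_along(p)) {
    g <- stats::rbinom(n, 2, p[j])
    val <- eff$a[j] * (g - 1) + eff$d[j] * (g == 1)
    fit <- stats::lm(val ~ g)
    va_emp <- va_emp + stats::var(stats::fitted(fit))
    vd_emp <- vd_emp + stats::var(stats::resid(fit))
  }
  expect_lt(abs(va_emp - v[["sigma2_a"]]) / v[["sigma2_a"]], 0.03)
  expect_lt(abs(vd_emp - v[["sigma2_d"]]) / v[["sigma2_d"]], 0.05)
})

test_that("iterative scaling reaches the target variances and is idempotent", {
  set.seed(108)
  p <- stats::runif(300, 0.05, 0.95)
  trait <- genetic_model(1)
  eff <- sample_effects(300)
  sc <- scale_effects(eff, p, trait)
  v <- attr(sc, "realized")
  expect_lt(abs(v[["sigma2_a"]] - 0.3), 1e-3)
  expect_lt(abs(v[["sigma2_d"]] - 0.1), 1e-3)
  # idempotence: re-scaling an already-scaled architecture barely moves it
  sc2 <- scale_effects(sc, p, trait)
  expect_lt(max(abs(sc2$a - sc$a)), 1e-3)
  expect_lt(max(abs(sc2$d - sc$d)), 1e-3)
  # degenerate: no dominance anywhere with a zero dominance target
  tr0 <- trait_config(sigma2_d = 0)
  sc0 <- scale_effects(toy_effects(a = stats::rnorm(50), d = rep(0, 50)),
                       stats::runif(50, 0.1, 0.9), tr0)
  expect_equal(attr(sc0, "realized")[["sigma2_a"]], 0.3, tolerance = 1e-3)
  expect_true(all(sc0$d == 0))
  # errors
  expect_error(scale_effects(eff, rep(1, 300), trait), "no segregating")
})

test_that("model 3 scaling never re-introduces over-dominance", {
  set.seed(109)
  p <- stats::runif(400, 0.05, 0.95)
  for (i in 1:3) {
    sc <- suppressWarnings(scale_effects(sample_effects(400, FALSE), p,
                                         genetic_model(3)))
    expect_lte(max(abs(sc$d) - abs(sc$a)), 1e-12)
    expect_equal(attr(sc, "realized")[["sigma2_a"]], 0.3, tolerance = 1e-3)
  }
})
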