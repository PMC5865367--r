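test_that("genotypic values follow the per-locus lookup", {
  # one QTL, a = 1, d = 0.5: AA = 1, Aa = 0.5, aa = -1
  pan <- toy_panel(rbind(1L, 1L, 1L, 0L, 0L, 0L))
  eff <- toy_effects(1, 0.5)
  expect_equal(genotypic_value(pan, eff, 1L), c(1, 0.5, -1))
  # all individuals homozygous for allele 1 at every QTL: sum of a
  set.seed(301)
  eff5 <- toy_effects(stats::rnorm(5), stats::rnorm(5))
  pan5 <- toy_panel(matrix(1L, 6L, 5L))
  expect_equal(genotypic_value(pan5, eff5, 1:5), rep(sum(eff5$a), 3))
})

test_that("genotypic values equal a brute-force per-locus enumeration", {
  set.seed(302)
  pan <- hwe_panel(40, stats::runif(8, 0.2, 0.8))
  eff <- toy_effects(stats::rnorm(8), stats::rnorm(8))
  g <- dosage(pan)
  brute <- vapply(seq_len(40), function(i) {
    s <- 0
    for (j in 1:8)
      s <- s + switch(g[i, j] + 1L, -eff$a[j], eff$d[j], eff$a[j])
    s
  }, numeric(1))
  expect_equal(genotypic_value(pan, eff, 1:8), brute, tolerance = 1e-12)
})

test_that("phenotypes add exactly the configured residual noise", {
  set.seed(303)
  gv <- stats::rnorm(100)
  expect_equal(simulate_phenotypes(gv, 0), gv)
  expect_error(simulate_phenotypes(gv, -1), "configuration error")
  y <- simulate_phenotypes(rep(0, 2e4), 0.6)
  expect_lt(abs(stats::var(y) - 0.6), 0.03)
})

test_that("base-generation phenotypic variance and heritability are on target", {
  set.seed(304)
  n_qtl <- 100L
  p <- stats::runif(n_qtl, 0.1, 0.9)
  trait <- genetic_model(1)
  eff <- scale_effects(sample_effects(n_qtl), p, trait)
  pan <- hwe_panel(2e4, p)
  gv <- genotypic_value(pan, eff, seq_len(n_qtl))
  y <- simulate_phenotypes(gv, trait$sigma2_e)
  expect_lt(abs(stats::var(y) - 1), 0.05)
  # narrow-sense heritability recovered from the breeding values: a parent
  # transmits half its additive deviation, so var(2 * TBV) = sigma2_a
  tbv <- true_breeding_values(pan, eff, seq_len(n_qtl), p)
  h2_emp <- 4 * stats::var(tbv) / stats::var(y)
  expect_lt(abs(h2_emp - 0.3), 0.03)
})

test_that("breeding values match Mendelian offspring enumeration per locus", {
  eff <- toy_effects(0.8, 0.3)
  # expected offspring genotypic value of each parent genotype when mated to
  # a population at frequency p, by exhaustive enumeration of gamete unions
  enum_tbv <- function(x, p) {
    gam_parent <- switch(as.character(x), "2" = c(1, 0), "1" = c(0.5, 0.5),
                         "0" = c(0, 1))
    gam_pop <- c(p, 1 - p)
    val <- 0
    for (i in 1:2) for (j in 1:2) {
      g <- (i == 1) + (j == 1)
      val <- val + gam_parent[i] * gam_pop[j] *
        switch(g + 1L, -eff$a[1], eff$d[1], eff$a[1])
    }
    val
  }
  genos <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L))
  pan <- toy_panel(matrix(t(genos)[TRUE], ncol = 1))
  for (p in c(0, 0.25, 0.6, 1)) {
    tbv <- true_breeding_values(pan, eff, 1L, p)
    expect_equal(tbv, vapply(c(2, 1, 0), enum_tbv, numeric(1), p = p),
                 tolerance = 1e-12)
  }
  # reference breed fixed for allele 1: every offspring of AA is AA
  expect_equal(true_breeding_values(subset_panel(pan, 1L), eff, 1L, 1), eff$a[1])
  # equal spacing: TBV(AA) - TBV(Aa) = TBV(Aa) - TBV(aa) = (a + (q-p)d)/2
  p <- 0.3
  tbv <- true_breeding_values(pan, eff, 1L, p)
  alpha <- eff$a[1] + (1 - 2 * p) * eff$d[1]
  expect_equal(tbv[1] - tbv[2], alpha / 2, tolerance = 1e-12)
  expect_equal(tbv[2] - tbv[3], alpha / 2, tolerance = 1e-12)
})

test_that("offspring genotypic value regresses on parent TBV with slope one", {
  set.seed(305)
  n_qtl <- 60L
  p <- stats::runif(n_qtl, 0.2, 0.8)
  eff <- scale_effects(sample_effects(n_qtl), p, genetic_model(1))
  map <- toy_map(pos = seq(0, 0.99, length.out = n_qtl), chrom_len = 1)
  pop <- hwe_panel(600, p)
  sires <- subset_panel(pop, which(pop$sex == "M"))
  dams <- subset_panel(pop, which(pop$sex == "F"))
  off <- mate(sires, dams, 6000L, map)
  tbv_sire <- true_breeding_values(sires, eff, seq_len(n_qtl),
                                   allele_freq(pop, seq_len(n_qtl)))
  gv_off <- genotypic_value(off, eff, seq_len(n_qtl))
  fit <- stats::lm(gv_off ~ tbv_sire[match(off$sire, sires$id)])
  slope <- stats::coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se + 0.02)
})

test_that("heterosis equals the allele-frequency-divergence closed form", {
  expect_equal(heterosis(2, c(2, 2)), 0)
  expect_equal(heterosis(1.5, c(1, 0.5)), 0.75)
  set.seed(306)
  n_qtl <- 50L
  p_A <- stats::runif(n_qtl, 0.1, 0.9)
  p_B <- pmin(pmax(p_A + stats::rnorm(n_qtl, 0, 0.3), 0), 1)
  eff <- toy_effects(stats::rnorm(n_qtl, 0, 0.3),
                     abs(stats::rnorm(n_qtl, 0.3, 0.3)))
  # identical frequencies: no expected F1 heterosis
  expect_equal(expected_f1_heterosis(eff, p_A, p_A), 0)
  map <- toy_map(pos = seq(0, 0.99, length.out = n_qtl), chrom_len = 1)
  A <- hwe_panel(4000, p_A, "A"); B <- hwe_panel(4000, p_B, "B")
  f1 <- mate(A, B, 8000L, map, breed_label = "AB")
  qtl <- seq_len(n_qtl)
  h_emp <- heterosis(mean(genotypic_value(f1, eff, qtl)),
                     c(mean(genotypic_value(A, eff, qtl)),
                       mean(genotypic_value(B, eff, qtl))))
  h_exp <- expected_f1_heterosis(eff, p_A, p_B)
  se <- sqrt(stats::var(genotypic_value(f1, eff, qtl)) / 8000 +
             stats::var(genotypic_value(A, eff, qtl)) / 4 / 4000 +
             stats::var(genotypic_value(B, eff, qtl)) / 4 / 4000)
  expect_lt(abs(h_emp - h_exp), 4 * se)
})

test_that("purebred-crossbred correlation is one without dominance or divergence", {
  set.seed(307)
  n_qtl <- 30L
  p <- stats::runif(n_qtl, 0.2, 0.8)
  pan <- hwe_panel(200, p)
  eff_d0 <- toy_effects(stats::rnorm(n_qtl), rep(0, n_qtl))
  p_other <- stats::runif(n_qtl, 0.2, 0.8)
  qtl <- seq_len(n_qtl)
  # d = 0: substitution effects are frequency-free, TBV-P = TBV-C + const
  expect_equal(rpc(true_breeding_values(pan, eff_d0, qtl, p),
                   true_breeding_values(pan, eff_d0, qtl, p_other)), 1)
  # identical frequency tables: TBV-P = TBV-C exactly
  eff <- toy_effects(stats::rnorm(n_qtl), stats::rnorm(n_qtl))
  tp <- true_breeding_values(pan, eff, qtl, p)
  expect_identical(tp, true_breeding_values(pan, eff, qtl, p))
  expect_equal(rpc(tp, tp), 1)
  expect_error(rpc(c(1, 2), c(1, 2)), "at least 3")
  expect_error(rpc(rep(1, 5), 1:5), "zero variance")
})
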