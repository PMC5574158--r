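test_that("progeny-test breeding values track genotypic deviations under additivity", {
  # autosomal loci only: the doubled male X dosage breaks the exact
  # equality between breeding value and genotypic deviation
  p <- draw_site_frequencies(300, 0.4, seed = 71)
  autosomes <- data.frame(chrom = c("2", "3"),
                          length_bp = c(48e6, 52e6),
                          length_cm = c(107, 110))
  sites <- make_site_table(300, autosomes, seed = 70)
  panel <- make_founder_panel(p, 150, seed = 72, sites = sites)
  eff <- sample_qtn_effects(n_large = 4, n_small = 16, seed = 73)
  set.seed(74)
  qtn <- assign_qtn_sites(eff, panel_freqs(panel), target_corr = 0,
                          target_mean_p_plus = 0.3)
  trait <- trait_model(qtn, "additive")
  base <- build_base_population(panel, trait, N = 200,
                                burn_generations = 3, seed = 75)
  pop <- base$pop; trait <- base$trait
  bv <- empirical_breeding_value(pop, trait, n_offspring = 1000, seed = 76)
  expect_gte(cor(bv$bv, pop$g - mean(pop$g)), 0.98)
  expect_true(all(bv$n_test_offspring == 1000L))
  # standard error scaling: doubling offspring halves se^2
  bv2 <- empirical_breeding_value(pop, trait, individuals = 1:30,
                                  n_offspring = 500, seed = 77)
  ratio <- mean(bv2$se^2) / mean(bv$se[1:30]^2)
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.7)
})

test_that("additive variance agrees with the 2pq a^2 expectation near HWE", {
  # outbred founders at moderate frequencies keep identity disequilibrium
  # negligible, so Var(BV) should approach the genic expectation;
  # autosomes only, since the doubled male X dosage has variance 4pq
  set.seed(78)
  p <- runif(400, 0.2, 0.8)
  chromosomes <- data.frame(chrom = c("2", "3"),
                            length_bp = c(48e6, 52e6),
                            length_cm = c(107, 110))
  sites <- make_site_table(400, chromosomes)
  panel <- make_founder_panel(p, 400, inbred = FALSE, sites = sites)
  eff <- sample_qtn_effects(n_large = 10, n_small = 60, seed = 79)
  set.seed(80)
  qtn <- assign_qtn_sites(eff, panel_freqs(panel), target_corr = 0,
                          target_mean_p_plus = 0.4)
  trait <- trait_model(qtn, "additive")
  base <- build_base_population(panel, trait, N = 500,
                                burn_generations = 1, seed = 81)
  pf <- colMeans(pop_dosages(base$pop)) / 2
  sub <- substitution_effect(qtn, pf, "additive")
  va <- additive_variance(base$pop, base$trait, n_offspring = 500,
                          seed = 82)
  expect_lt(abs(va / sum(sub$contribution) - 1), 0.12)
})

test_that("substitution effects match exact-enumeration and closed forms", {
  qtn <- manual_qtn(c(1.7, -0.9))
  # numeric least-squares oracle over the full 9-cell genotype table
  oracle <- function(z, p_b, q_c) {
    g <- rep(0:2, each = 3); gc <- rep(0:2, 3)
    w <- dbinom(g, 2, p_b) * dbinom(gc, 2, 1 - q_c)
    val <- z * (g >= 1) * (gc >= 1)
    coef(lm(val ~ g, weights = w))[["g"]]
  }
  set.seed(83)
  for (i in 1:10) {
    p1 <- runif(4, 0.05, 0.95)
    sub <- substitution_effect(qtn, p1, "complementary")
    for (loc in 1:4) {
      partner <- ifelse(loc %% 2 == 0, loc - 1, loc + 1)
      z <- qtn$z[loc]
      p_dom <- p1[loc]; q_c <- 1 - p1[partner]
      expect_equal(sub$alpha[loc], oracle(z, p_dom, q_c),
                   tolerance = 1e-8)
      # closed form alpha = z * q_B * (1 - q_C^2)
      expect_equal(sub$alpha[loc], z * (1 - p_dom) * (1 - q_c^2),
                   tolerance = 1e-8)
    }
  }
  # additive architecture: alpha is the locus additive value itself
  sub_a <- substitution_effect(qtn, runif(4, 0.1, 0.9), "additive")
  expect_equal(sub_a$alpha, qtn$a)
  # fixed locus reports zero contribution
  sub_f <- substitution_effect(qtn, c(1, 0.5, 0.5, 0.5), "complementary")
  expect_equal(sub_f$contribution[1], 0)
})

test_that("contribution spectra have the right boundary behaviour", {
  qtn <- manual_qtn(rep(1, 5))         # 10 loci, equal z
  freqs <- rep(0.5, 10)
  cs <- contribution_spectrum(qtn, freqs, "additive")
  expect_equal(cs$frac_loci_90, 0.9)   # x% of loci explain x%
  # single nonzero contribution: one locus explains everything
  qtn2 <- manual_qtn(c(1, 0, 0))
  qtn2$a <- c(1, 0, 0, 0, 0, 0)
  cs2 <- contribution_spectrum(qtn2, rep(0.5, 6), "additive")
  expect_equal(cs2$frac_loci_90, 1 / 6)
})

test_that("pairwise r2 equals the naive two-loop correlation", {
  set.seed(84)
  sites <- one_chrom_sites(20)
  D <- matrix(rbinom(50 * 20, 2, 0.4), 50, 20)
  got <- ld_r2(D, sites)
  for (r in sample(nrow(got), 25)) {
    i <- which(sites$pos_bp == got$bp1[r])
    j <- which(sites$pos_bp == got$bp2[r])
    expect_equal(got$r2[r], cor(D[, i], D[, j])^2, tolerance = 1e-12)
  }
  # perfectly coupled loci
  D2 <- cbind(D[, 1], D[, 1])
  expect_equal(ld_r2(D2, sites[1:2, ])$r2, 1)
  # distance restriction
  near <- ld_r2(D, sites, max_dist_bp = 1e5)
  expect_true(all(near$dist <= 1e5))
})

test_that("the Hill-Weir fit recovers a known decay scale", {
  n <- 100
  d <- seq(1e3, 2e6, length.out = 60)
  c_true <- 4e-6
  pairs <- data.frame(dist = d, r2 = hill_weir_expectation(c_true * d, n))
  fit <- fit_hill_weir(pairs, n)
  expect_lt(abs(fit$C_per_bp / c_true - 1), 0.01)
  expect_false(fit$flat)
  # fitted curve decreases monotonically with distance
  curve <- fit$curve(seq(1e3, 5e6, length.out = 50))
  expect_true(all(diff(curve) < 0))
  expect_error(fit_hill_weir(pairs[1:2, ], n),
               class = "episel_invalid_parameter")
})

test_that("excess-homozygosity inbreeding matches its definition", {
  p <- rep(0.5, 10)
  hom <- matrix(2L, 1, 10)
  expect_equal(genomic_inbreeding(hom, p)$F_h, 1)   # fully homozygous
  # O = E gives F = 0: E = 10 * 0.5 = 5
  half <- matrix(c(rep(1L, 5), rep(2L, 5)), 1)
  expect_equal(genomic_inbreeding(half, p)$F_h, 0)
  # naive oracle on a random instance
  set.seed(85)
  D <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  bf <- runif(30, 0.2, 0.8)
  got <- genomic_inbreeding(D, bf)
  E <- sum(1 - 2 * bf * (1 - bf))
  for (i in c(1, 17, 40)) {
    O <- sum(D[i, ] != 1L)
    expect_equal(got$F_h[i], (O - E) / (30 - E), tolerance = 1e-12)
  }
  # HWE population at the base frequencies: mean F ~ 0
  set.seed(86)
  Dh <- matrix(rbinom(1e4 * 50, 2, rep(seq(0.1, 0.9, length.out = 50),
                                       each = 1e4)), 1e4, 50)
  expect_lt(abs(mean(genomic_inbreeding(Dh,
                                        seq(0.1, 0.9,
                                            length.out = 50))$F_h)), 0.01)
})

test_that("prediction accuracy is the Pearson correlation", {
  x <- rnorm(100)
  expect_equal(prediction_accuracy(x, x), 1)
  set.seed(87)
  expect_lt(abs(prediction_accuracy(rnorm(2000), rnorm(2000))), 0.08)
  expect_error(prediction_accuracy(1:3, 1:4),
               class = "episel_invalid_parameter")
})

test_that("allele frequency bookkeeping handles fixation", {
  panel <- make_founder_panel(rep(0.5, 4), 10, seed = 88,
                              sites = one_chrom_sites(4))
  qtn <- manual_qtn(c(1, 1))
  pop0 <- founder_population(panel)
  pop7 <- pop0
  pop7$H[] <- 1L                            # increasing allele fixed
  ch <- allele_frequency_change(pop0, pop7, qtn)
  expect_equal(ch$delta_p, 1 - ch$p0)
  expect_equal(ch$p7, rep(1, 4))
})
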