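test_that("allele frequencies count scored calls only", {
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 100L), c(100L, 100L),
                       c(100L, 100L), c(100L, 100L)), rep("P", 5))
  af <- allele_frequencies(gm, "P")
  expect_equal(unname(af$freq$L01["100"]), 1)
  gm2 <- build_gm(rbind(c(100L, 100L), c(100L, 102L)), c("P", "P"))
  af2 <- allele_frequencies(gm2, "P")
  expect_equal(unname(af2$freq$L01["100"]), 0.75)
  # dead locus excluded with a warning
  gm3 <- build_gm(rbind(c(NA, NA, 100L, 102L), c(NA, NA, 100L, 100L)),
                  c("P", "P"))
  expect_warning(af3 <- allele_frequencies(gm3, "P"), "no scored calls")
  expect_equal(names(af3$freq), "L02")
})

test_that("simulated deme frequencies converge to the configured truth", {
  cfg <- sim_config(n_demes = 1L, deme_sizes = 400L, n_loci = 2L,
                    alleles_per_locus = 4L, target_F = 0, clonality_c = 0,
                    missing_rate = 0, seed = 6L)
  sim <- simulate_dataset(cfg)
  af <- allele_frequencies(sim$genotypes, "deme_1")
  for (l in 1:2) {
    truth <- sim$frequencies$freq[[l]][1, ]
    est <- af$freq[[l]][names(truth)]
    est[is.na(est)] <- 0
    expect_lt(max(abs(unname(est) - unname(truth))), 0.06)
  }
})

test_that("private alleles are counted against all other populations", {
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 100L),
                       c(102L, 102L), c(102L, 102L)),
                 c("A", "A", "B", "B"))
  res <- allelic_richness_and_private(gm)
  expect_equal(res$Np_mean, c(1, 1))
  expect_equal(res$Na_mean, c(1, 1))  # monomorphic within each population
  gm_same <- build_gm(rbind(c(100L, 102L), c(100L, 102L),
                            c(100L, 102L), c(100L, 102L)),
                      c("A", "A", "B", "B"))
  expect_equal(allelic_richness_and_private(gm_same)$Np_mean, c(0, 0))
  expect_error(allelic_richness_and_private(pop_subset(gm, "A")),
               "at least two")
})

test_that("heterozygosities hit closed forms and the unbiased correction dominates", {
  gm_het <- build_gm(matrix(rep(c(100L, 102L), 8), 4, byrow = TRUE),
                     rep("P", 4))
  h <- heterozygosity(gm_het, "P")
  expect_equal(h$Ho, 1)
  expect_equal(h$He_biased, 0.5)
  gm_hom <- build_gm(matrix(100L, 4, 4), rep("P", 4))
  h2 <- heterozygosity(gm_hom, "P")
  expect_equal(h2$Ho, 0); expect_equal(h2$He_biased, 0)
  # property: unbiased >= biased, both within [0, 1]
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(n_demes = 1L, deme_sizes = 15L,
                                       missing_rate = 0.1, seed = s))
    hh <- heterozygosity(sim$genotypes, "deme_1")
    expect_gte(hh$He_unbiased, hh$He_biased)
    expect_true(all(c(hh$Ho, hh$He_biased, hh$He_unbiased) >= 0))
    expect_true(all(c(hh$Ho, hh$He_biased, hh$He_unbiased) <= 1))
  }
})

test_that("Weir-Cockerham f reaches -1 for fully heterozygous data and matches the ANOVA oracle", {
  gm <- build_gm(matrix(rep(c(100L, 102L), 50), 50, byrow = TRUE),
                 rep("P", 50))
  expect_equal(fis(gm, "P", n_boot = 0)$fis, -1)
  # oracle equality on small random datasets
  set.seed(14)
  for (rep in 1:5) {
    calls <- matrix(sample(c(100L, 102L, 104L), 6 * 2 * 3, TRUE), 6)
    gm2 <- build_gm(calls, rep("P", 6))
    f_pkg <- fis(gm2, "P", n_boot = 0)$fis
    comp <- rowSums(vapply(1:3, function(l)
      wc_anova_locus(gm2$alleles[, l, ], gm2$populations), numeric(3)))
    f_oracle <- 1 - comp["c"] / (comp["b"] + comp["c"])
    if (is.na(f_pkg)) expect_true(comp["b"] + comp["c"] <= 1e-12)
    else expect_equal(f_pkg, unname(f_oracle), tolerance = 1e-12)
  }
  # monomorphic population: undefined
  mono <- build_gm(matrix(100L, 5, 4), rep("P", 5))
  expect_true(is.na(fis(mono, "P", n_boot = 0)$fis))
})

test_that("f is near zero with a covering CI on Hardy-Weinberg data", {
  sim <- simulate_dataset(sim_config(n_demes = 1L, deme_sizes = 200L,
                                     n_loci = 6L, clonality_c = 0,
                                     missing_rate = 0, seed = 33L))
  res <- fis(sim$genotypes, "deme_1", n_boot = 500L, seed = 1L)
  expect_lt(abs(res$fis), 0.1)
  expect_true(res$ci[1] <= 0.05 && res$ci[2] >= -0.05)
})

test_that("HWE exact enumeration matches the permutation-pairing oracle on toy tables", {
  cases <- list(list(a1 = c(100L, 100L, 102L), a2 = c(100L, 102L, 102L)),
                list(a1 = c(100L, 100L, 100L, 102L),
                     a2 = c(100L, 102L, 104L, 104L)))
  for (cs in cases) {
    gm <- build_gm(cbind(cs$a1, cs$a2), rep("P", length(cs$a1)))
    res <- hwe_exact(gm, "P", 1, mode = "enumerate")
    oracle <- hwe_permutation_oracle(cs$a1, cs$a2)
    expect_equal(res$p_two_sided, oracle$p_two, tolerance = 1e-10)
    expect_equal(res$p_deficit, oracle$p_deficit, tolerance = 1e-10)
  }
})

test_that("HWE degenerate and forced tables give p = 1", {
  mono <- build_gm(matrix(100L, 5, 2), rep("P", 5))
  expect_warning(res <- hwe_exact(mono, "P", 1), "monomorphic")
  expect_equal(res$p_two_sided, 1)
  # n = 2 with allele counts (3, 1): the genotype array is forced
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 102L)), c("P", "P"))
  expect_equal(hwe_exact(gm, "P", 1)$p_two_sided, 1)
})

test_that("HWE enumeration and Monte Carlo agree within sampling error", {
  set.seed(19)
  calls <- t(replicate(20, sort(sample(c(100L, 102L), 2, TRUE,
                                       prob = c(0.6, 0.4)))))
  gm <- build_gm(calls, rep("P", 20))
  en <- hwe_exact(gm, "P", 1, mode = "enumerate")
  mc <- hwe_exact(gm, "P", 1, mode = "mc", n_mc = 4000L, seed = 4L)
  se <- sqrt(en$p_two_sided * (1 - en$p_two_sided) / 4000)
  expect_lt(abs(en$p_two_sided - mc$p_two_sided), 4 * se + 0.01)
  expect_lt(abs(en$p_deficit - mc$p_deficit), 4 * se + 0.01)
})

test_that("HWE p-values are roughly uniform under the null", {
  ps <- vapply(1:60, function(s) {
    sim <- simulate_dataset(sim_config(n_demes = 1L, deme_sizes = 40L,
                                       n_loci = 1L, alleles_per_locus = 3L,
                                       clonality_c = 0, missing_rate = 0,
                                       seed = 1000L + s))
    suppressWarnings(hwe_exact(sim$genotypes, "deme_1", 1,
                               mode = "mc", n_mc = 400L,
                               seed = s)$p_two_sided)
  }, numeric(1))
  # exact conditional tests are discrete; check gross calibration
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
})

test_that("null-allele screen estimates r and flags simulated null alleles", {
  # Ho == He exactly -> r = 0
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 102L), c(102L, 102L),
                       c(100L, 102L)), rep("P", 4))
  scr <- null_allele_screen(gm, "P", 1)
  expect_equal(scr$r_estimate, 0)
  expect_false(scr$flagged)
  # simulated null allele at locus 1 is flagged most of the time
  flags <- vapply(1:8, function(s) {
    sim <- simulate_dataset(sim_config(n_demes = 1L, deme_sizes = 100L,
                                       n_loci = 4L, alleles_per_locus = 6L,
                                       clonality_c = 0, missing_rate = 0,
                                       null_allele_freq = 0.2,
                                       null_locus = 1L, seed = 300L + s))
    null_allele_screen(sim$genotypes, "deme_1", 1, mode = "mc",
                       n_mc = 400L, seed = s)$flagged
  }, logical(1))
  expect_gte(mean(flags), 0.625)
  r_est <- {
    sim <- simulate_dataset(sim_config(n_demes = 1L, deme_sizes = 200L,
                                       n_loci = 2L, alleles_per_locus = 6L,
                                       clonality_c = 0, missing_rate = 0,
                                       null_allele_freq = 0.2,
                                       null_locus = 1L, seed = 77L))
    null_allele_screen(sim$genotypes, "deme_1", 1, mode = "mc",
                       n_mc = 200L)$r_estimate
  }
  expect_gt(r_est, 0.05)  # positive null-frequency estimate
})

test_that("population summary table assembles all panels", {
  sim <- simulate_dataset(sim_config(n_demes = 3L, deme_sizes = 12L,
                                     missing_rate = 0.1, seed = 2L))
  tab <- pop_stats_table(sim$genotypes, n_boot = 50L, hwe = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("He", "Ho", "FIS", "Na_mean", "Np_mean",
                    "pct_missing") %in% names(tab)))
  expect_true(all(tab$He >= 0 & tab$He <= 1))
})
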