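test_that("probability of identity matches closed forms and the pair-enumeration oracle", {
  expect_equal(probability_of_identity(list(c(0.5, 0.5)))$combined, 0.375)
  expect_equal(probability_of_identity(list(c(1)))$combined, 1)
  # two loci, four equifrequent alleles each, vs exhaustive genotype pairs
  p <- rep(0.25, 4)
  res <- probability_of_identity(list(p, p))
  expect_equal(unname(res$per_locus[1]), pid_oracle_locus(p))
  expect_equal(res$combined, pid_oracle_locus(p)^2)
  expect_lte(res$combined, min(res$per_locus))
  # combined P_ID decreases weakly as loci are added
  set.seed(4)
  for (rep in 1:5) {
    freqs <- lapply(1:4, function(i) {
      v <- stats::runif(sample(2:5, 1)); v / sum(v)
    })
    vals <- vapply(1:4, function(k)
      probability_of_identity(freqs[seq_len(k)])$combined, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
  expect_error(probability_of_identity(list()), "no loci")
})

test_that("MLG assignment distinguishes single-allele differences and honors policies", {
  calls <- rbind(rep(c(100L, 102L), 6),          # i1
                 rep(c(100L, 102L), 6),          # i2: identical -> same MLG
                 c(rep(c(100L, 102L), 5), 100L, 104L),  # i3: one allele off
                 rep(c(100L, 102L), 6))          # i4
  calls[4, 1:4] <- NA                            # i4 missing at 2 of 6 loci
  gm <- build_gm(calls, rep("P", 4))
  part <- assign_mlg(gm)
  grp <- function(id) names(Filter(function(g) id %in% g, part$groups))
  expect_equal(grp("ind001"), grp("ind002"))
  expect_false(grp("ind003") == grp("ind001"))
  expect_equal(grp("ind004"), grp("ind001"))  # matches on 4-locus overlap
  # strict policy: the incomplete individual no longer joins
  strict <- assign_mlg(gm, missing_policy = "strict")
  grp_s <- function(id) names(Filter(function(g) id %in% g, strict$groups))
  expect_false(grp_s("ind004") == grp_s("ind001"))
  # min_loci above the overlap also separates it
  part5 <- assign_mlg(gm, min_loci = 5L)
  grp5 <- function(id) names(Filter(function(g) id %in% g, part5$groups))
  expect_false(grp5("ind004") == grp5("ind001"))
})

test_that("individuals missing at every locus are reported as unassigned", {
  calls <- rbind(rep(c(100L, 102L), 4), rep(NA_integer_, 8))
  gm <- build_gm(calls, c("P", "P"))
  part <- assign_mlg(gm)
  expect_equal(part$unassigned, "ind002")
  expect_equal(length(part$groups), 1L)
})

test_that("stepwise-mutation distances follow the best allele pairing and merge by single linkage", {
  # A vs B: one allele 102 -> 104 at a dinucleotide locus = 1 step
  calls <- rbind(c(100L, 102L, 200L, 202L),
                 c(100L, 104L, 200L, 202L),   # 1 step from A
                 c(100L, 108L, 200L, 204L),   # 3 steps from B, 4 from A... chain
                 c(100L, 112L, 200L, 206L))   # far from A
  gm <- build_gm(calls, rep("P", 4))
  expect_equal(smm_distance(gm, 1, 2), 1)
  part <- assign_mlg(gm)
  expect_equal(length(part$groups), 4L)
  mll <- collapse_mll(part, gm, threshold_steps = 4)
  # all chained within threshold 4 of a neighbor -> single linkage joins all
  expect_equal(length(mll$groups), 1L)
  mll1 <- collapse_mll(part, gm, threshold_steps = 1)
  expect_equal(length(mll1$groups), 3L)  # only the 1-step pair merges
  # distance 5 pair stays separate at threshold 4
  far <- build_gm(rbind(c(100L, 100L), c(110L, 110L)), c("P", "P"))
  expect_equal(smm_distance(far, 1, 2), 10)
  pf <- assign_mlg(far, min_loci = 1L)
  expect_equal(length(collapse_mll(pf, far, 4)$groups), 2L)
})

test_that("non-motif-multiple size differences round to the nearest step with a warning", {
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 103L)), c("P", "P"))
  expect_warning(d <- smm_distance(gm, 1, 2), "motif multiple")
  expect_equal(d, 2)  # 1.5 steps rounds to the nearest whole step
})

test_that("collapsing at threshold 0 recovers the MLG partition on complete data", {
  sim <- make_fixture("clonal", seed = 31L)
  part <- assign_mlg(sim$genotypes)
  mll0 <- collapse_mll(part, sim$genotypes, threshold_steps = 0)
  expect_equal(lengths(mll0$groups), lengths(part$groups),
               ignore_attr = TRUE)
})

test_that("sexuality randomization test hits its bounds on degenerate populations", {
  # 10 copies of one genotype with a diverse allele pool across loci
  calls <- matrix(rep(c(100L, 110L, 200L, 210L, 300L, 310L, 400L, 410L,
                        500L, 510L, 600L, 610L), 10), 10, byrow = TRUE)
  gm <- build_gm(calls, rep("P", 10))
  res <- sexual_null_test(gm, "P", n_rand = 99L, seed = 2L)
  expect_equal(res$p_value, 1 / 100)
  # monomorphic loci: always one MLG, p = 1
  mono <- build_gm(matrix(100L, 6, 12), rep("P", 6))
  expect_equal(sexual_null_test(mono, "P", n_rand = 99L)$p_value, 1)
  # all-unique population: high p
  sim <- make_fixture("panmictic", seed = 17L)
  res2 <- sexual_null_test(sim$genotypes, "deme_1", n_rand = 199L, seed = 3L)
  expect_gt(res2$p_value, 0.5)
  expect_error(sexual_null_test(gm[1, ], "P"), "population of 1")
  expect_error(sexual_null_test(gm, "P", n_rand = 10L), "at least 99")
})

test_that("clonal statistics reproduce hand-computed diversity panels", {
  # all-singleton population of 14
  gm14 <- gm_clonal_structure(rep(1L, 14))
  s14 <- clonal_statistics(gm14, assign_mlg(gm14), "P")
  expect_equal(s14$Go, 14)
  expect_equal(s14$G, 1)
  expect_equal(s14$R, 1)
  expect_equal(s14$simpson_1mD, 1)
  expect_equal(s14$mode_label, "fully_sexual")
  # N = 13 with group sizes {1 x 7, 2 x 3}
  gm13 <- gm_clonal_structure(c(rep(1L, 7), rep(2L, 3)))
  s13 <- clonal_statistics(gm13, assign_mlg(gm13), "P")
  expect_equal(s13$Go, 169 / 19)
  expect_equal(s13$R, 0.75)
  expect_equal(s13$simpson_1mD, (13 / 12) * (1 - 19 / 169))
  expect_equal(round(s13$simpson_1mD, 2), 0.96)
  # 19 singletons: Shannon log10
  gm19 <- gm_clonal_structure(rep(1L, 19))
  s19 <- clonal_statistics(gm19, assign_mlg(gm19), "P")
  expect_equal(s19$shannon_H, log10(19))
  expect_error(clonal_statistics(gm14[1, ], assign_mlg(gm14[1, ]), "P"),
               "at least 2")
})

test_that("genotypic diversity identities hold on random partitions", {
  set.seed(8)
  for (rep in 1:10) {
    sizes <- sample(1:4, sample(2:8, 1), replace = TRUE)
    gm <- gm_clonal_structure(sizes)
    s <- clonal_statistics(gm, assign_mlg(gm), "P")
    expect_gte(s$Go, 1); expect_lte(s$Go, s$N + 1e-9)
    all_singletons <- all(sizes == 1)
    expect_equal(abs(s$Go - s$N) < 1e-9, all_singletons)
    expect_equal(abs(s$simpson_1mD - 1) < 1e-9, all_singletons)
    expect_equal(s$G, s$Go / s$N)
    expect_equal(s$R, (s$N_MLG - 1) / (s$N - 1))
  }
})

test_that("diversity-evenness regression recovers exact and null relationships", {
  df <- data.frame(E_D = c(0.2, 0.5, 0.8), G = c(0.4, 1.0, 1.6))
  res <- suppressWarnings(diversity_evenness_regression(df))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  expect_error(diversity_evenness_regression(
    data.frame(E_D = c(1, 1, 1), G = c(0.5, 0.7, 0.9))), "zero variance")
  # permutation null: mean R-squared ~ 1/(n-1) for n = 9 points
  set.seed(12)
  x <- stats::runif(9); y <- stats::runif(9)
  r2 <- vapply(1:300, function(i)
    diversity_evenness_regression(
      data.frame(E_D = x, G = y[sample.int(9)]))$r_squared, numeric(1))
  expect_lt(abs(mean(r2) - 1 / 8), 0.04)
})
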