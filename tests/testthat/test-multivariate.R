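test_that("allele count table expands genotypes and mean-imputes missing loci", {
  calls <- rbind(c(100L, 100L), c(100L, 102L), c(NA, NA))
  gm <- build_gm(calls, rep("P", 3))
  tab <- build_count_table(gm)
  expect_equal(unname(tab$counts[1, ]), c(2, 0))
  expect_equal(unname(tab$counts[2, ]), c(1, 1))
  expect_equal(unname(tab$counts[3, ]), c(1.5, 0.5))  # column means
  expect_true(all(tab$imputed[3, ]))
  # per-locus row sums are 0 or 2 before imputation
  expect_equal(unname(rowSums(tab$counts[1:2, ])), c(2, 2))
})

test_that("PCA preserves total variance and maps duplicates together", {
  sim <- simulate_dataset(sim_config(n_demes = 2L, deme_sizes = 10L,
                                     target_F = 0.3, missing_rate = 0,
                                     seed = 5L))
  gm <- sim$genotypes
  tab <- build_count_table(gm)
  p <- pca_genotypes(tab)
  ctr <- scale(tab$counts, center = TRUE, scale = FALSE)
  expect_equal(sum(p$eigenvalues), sum(ctr^2) / (nrow(ctr) - 1),
               tolerance = 1e-9)
  # duplicated individuals get identical scores
  dup_idx <- c(1, 1, 2:10)
  gm2 <- genotype_matrix(gm$alleles[dup_idx, , , drop = FALSE],
                         c(gm$individuals[1], "dup", gm$individuals[2:10]),
                         gm$populations[dup_idx], gm$loci)
  p2 <- pca_genotypes(build_count_table(gm2))
  expect_equal(p2$scores[1, ], p2$scores[2, ], tolerance = 1e-9)
  expect_error(pca_genotypes(tab, n_axes = 500), "rank")
})

test_that("PCA separates two differentiated demes on the first axis", {
  cfg <- sim_config(n_demes = 2L, deme_sizes = 25L, n_loci = 8L,
                    target_F = 0.3, clonality_c = 0, missing_rate = 0,
                    seed = 9L)
  sim <- simulate_dataset(cfg)
  p <- pca_genotypes(build_count_table(sim$genotypes))
  s1 <- p$scores[sim$genotypes$populations == "deme_1", 1]
  s2 <- p$scores[sim$genotypes$populations == "deme_2", 1]
  gap <- abs(mean(s1) - mean(s2))
  expect_gt(gap, 2 * max(stats::sd(s1), stats::sd(s2)))
})

test_that("DAPC separates disjoint clusters and reduces to plain LDA at full rank", {
  gm <- build_gm(rbind(matrix(rep(c(100L, 100L, 200L, 202L), 5), 5,
                              byrow = TRUE),
                       matrix(rep(c(104L, 104L, 210L, 212L), 5), 5,
                              byrow = TRUE)),
                 rep(c("A", "B"), each = 5))
  # add mild within-group noise so covariances are non-degenerate
  set.seed(2)
  noise <- sample(c(0L, 2L), 40, TRUE)
  gm$alleles[, 1, ] <- gm$alleles[, 1, ] + array(noise, dim = c(10, 2, 2))[, 1:2, 1]
  tab <- build_count_table(gm)
  d <- dapc(tab, gm$populations)
  expect_equal(d$reassignment_proportion, 1)
  expect_error(dapc(tab, c("A", rep("B", 9))), "at least 2")
  # with all PC axes retained, assignments equal plain LDA on the PC scores
  p <- pca_genotypes(tab)
  full <- suppressWarnings(dapc(tab, gm$populations,
                                n_pca = ncol(p$scores)))
  direct <- suppressWarnings(MASS::lda(p$scores,
                                       grouping = gm$populations))
  expect_equal(as.character(full$assignment),
               as.character(stats::predict(direct)$class))
})

test_that("cross-validated DAPC reassignment is near chance on panmictic data", {
  sim <- make_fixture("panmictic", seed = 6L)
  set.seed(7)
  groups <- sample(rep(c("g1", "g2", "g3"), each = 20))
  tab <- build_count_table(sim$genotypes)
  acc <- dapc_xval(tab, groups, n_pca = 10, folds = 5, seed = 8)
  expect_gt(acc, 0.05)
  expect_lt(acc, 0.62)
})

test_that("Nei distances match the direct formula and cap at fixed differences", {
  expect_equal(as.numeric(nei_distance(
    build_gm(rbind(c(100L, 102L), c(100L, 102L),
                   c(100L, 102L), c(100L, 102L)),
             c("A", "A", "B", "B")), "A", "B")), 0)
  fixed <- build_gm(rbind(c(100L, 100L), c(100L, 100L),
                          c(104L, 104L), c(104L, 104L)),
                    c("A", "A", "B", "B"))
  dfix <- nei_distance(fixed, "A", "B")
  expect_true(isTRUE(attr(dfix, "capped")))
  # hand 2-locus example vs the direct formula
  gm <- build_gm(rbind(c(100L, 100L), c(100L, 102L),
                       c(100L, 102L), c(102L, 102L)),
                 c("A", "A", "B", "B"))
  # pop A freqs (0.75, 0.25), pop B (0.25, 0.75); single locus
  I <- (0.75 * 0.25 + 0.25 * 0.75) /
    sqrt((0.75^2 + 0.25^2) * (0.25^2 + 0.75^2))
  expect_equal(as.numeric(nei_distance(gm, "A", "B")), -log(I))
  # 1978 unbiased variant shrinks the self-identities
  d78 <- nei_distance(gm, "A", "B", variant = "1978")
  expect_false(isTRUE(all.equal(as.numeric(d78),
                                as.numeric(nei_distance(gm, "A", "B")))))
})

test_that("minimum spanning network equals the brute-force MST and keeps ties", {
  m3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- minimum_spanning_network(m3)
  expect_equal(sort(net$weight), c(1, 2))
  # equilateral triangle: all three tied edges retained
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  dimnames(tri) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(nrow(minimum_spanning_network(tri)), 3L)
  # random matrices with distinct weights: exact MST recovery
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
    w <- w + t(w)
    dimnames(w) <- list(letters[1:n], letters[1:n])
    net <- minimum_spanning_network(w)
    bf <- bruteforce_mst(w)
    expect_equal(nrow(net), n - 1L)
    expect_equal(sum(net$weight), bf$weight, tolerance = 1e-12)
    got <- sort(paste(pmin(net$from, net$to), pmax(net$from, net$to)))
    want <- sort(paste(letters[pmin(bf$edges[, 1], bf$edges[, 2])],
                       letters[pmax(bf$edges[, 1], bf$edges[, 2])]))
    expect_equal(got, want)
  }
})

test_that("DAPC corroborates admixture clustering on the three-deme fixture", {
  sim <- make_fixture("three_demes", seed = 3L)
  gm <- sim$genotypes
  r <- run_admixture(gm, K = 3, burnin = 1000, iters = 6000, seed = 2)
  adm <- assign_clusters(r$Q, threshold = 0)
  d <- dapc(build_count_table(gm), gm$populations)
  expect_gte(adjusted_rand(unname(adm), as.character(d$assignment)), 0.8)
})
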