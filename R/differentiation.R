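# Weir-Cockerham (1984) variance components for one locus across r
# populations. Returns c(a = ..., bc = a+b+c summed over alleles); zero for
# loci monomorphic across the included populations.
wc_locus_components <- function(alle, pop_index, n_pops) {
  # alle: n x 2 matrix of allele calls (NA = missing)
  ok <- !is.na(alle[, 1])
  alle <- alle[ok, , drop = FALSE]
  pop_index <- pop_index[ok]
  ni <- tabulate(pop_index, nbins = n_pops)
  use <- which(ni >= 1L)
  r <- length(use)
  if (r < 2L) return(c(a = 0, abc = 0))
  ni <- ni[use]
  alleles <- sort(unique(as.vector(alle)))
  if (length(alleles) < 2L) return(c(a = 0, abc = 0))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  a_sum <- 0; abc_sum <- 0
  for (al in alleles) {
    p_i <- vapply(seq_along(use), function(k) {
      rows <- pop_index == use[k]
      (sum(alle[rows, 1] == al) + sum(alle[rows, 2] == al)) / (2 * ni[k])
    }, numeric(1))
    h_i <- vapply(seq_along(use), function(k) {
      rows <- pop_index == use[k]
      mean((alle[rows, 1] == al) != (alle[rows, 2] == al))
    }, numeric(1))
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  c(a = a_sum, abc = abc_sum)
}

# internal: multilocus theta across the populations present in `matrix`
wc_theta <- function(matrix) {
  pops <- pop_levels(matrix)
  pop_index <- match(matrix$populations, pops)
  comp <- vapply(seq_len(n_loci(matrix)), function(l)
    wc_locus_components(matrix$alleles[, l, ], pop_index, length(pops)),
    numeric(2))
  a <- sum(comp[1, ]); abc <- sum(comp[2, ])
  if (abc == 0) return(NA_real_)
  a / abc
}

#' Pairwise multilocus Weir-Cockerham theta (FST)
#'
#' The 1984 variance-components estimator: `theta = sum(a) / sum(a + b + c)`
#' with components summed over alleles and loci. Missing calls are excluded
#' per locus; loci monomorphic across the pair contribute nothing. Negative
#' estimates are reported as computed (not truncated at zero).
#'
#' @param matrix A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @return Multilocus theta (numeric scalar).
#' @export
pairwise_theta <- function(matrix, popA, popB) {
  keep <- matrix$populations %in% c(popA, popB)
  sub <- matrix[which(keep), ]
  for (p in c(popA, popB)) {
    scored <- rowSums(!is_missing_call(pop_subset(sub, p)))
    if (sum(scored > 0) < 2L)
      stop("population ", p, " has fewer than 2 scored individuals")
  }
  th <- wc_theta(sub)
  if (is.na(th))
    stop("no shared polymorphic locus between ", popA, " and ", popB)
  th
}

#' Permutation test for pairwise theta
#'
#' Permutes individuals between the two populations (keeping sample sizes)
#' and compares permuted theta values with the observed one:
#' `p = (1 + #[theta* >= theta_obs]) / (n_perm + 1)`.
#'
#' @inheritParams pairwise_theta
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with `theta`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(matrix, popA, popB, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  keep <- which(matrix$populations %in% c(popA, popB))
  if (length(keep) < 4L) stop("combined sample size below 4")
  sub <- matrix[keep, ]
  obs <- pairwise_theta(sub, popA, popB)
  set.seed(seed)
  labels <- sub$populations
  hits <- 0L
  for (r in seq_len(n_perm)) {
    perm <- sub
    perm$populations <- labels[sample.int(length(labels))]
    th <- suppressWarnings(tryCatch(wc_theta(perm), error = function(e) NA))
    if (!is.na(th) && th >= obs) hits <- hits + 1L
  }
  list(theta = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Keep one representative per MLG per population
#'
#' Builds the "per-genotype" (clone-censored) dataset: for each clone group
#' and each population in which it has members, only the first-sampled
#' member is kept.
#'
#' @param matrix A [genotype_matrix()].
#' @param partition A `clone_partition` from [assign_mlg()] or
#'   [collapse_mll()].
#' @return A [genotype_matrix()] with clonal replicates removed.
#' @export
to_per_genotype <- function(matrix, partition) {
  keep <- character()
  for (g in partition$groups) {
    idx <- match(g, matrix$individuals)
    pops <- matrix$populations[idx]
    for (p in unique(pops))
      keep <- c(keep, g[pops == p][which.min(idx[pops == p])])
  }
  keep_idx <- sort(match(keep, matrix$individuals))
  matrix[keep_idx, ]
}

#' Pairwise FST matrix with permutation p-values
#'
#' @param matrix A [genotype_matrix()] with at least two populations.
#' @param n_perm Permutations per pair (0 skips the test).
#' @param seed Integer RNG seed.
#' @param dataset_mode Label recorded in the result (`"per_individual"` or
#'   `"per_genotype"`); purely descriptive.
#' @return An object of class `fst_result`: `labels`, symmetric `theta`
#'   matrix (diagonal `NA`), `p_perm` matrix, `n_perm`, `dataset_mode`.
#' @export
fst_matrix <- function(matrix, n_perm = 1000L, seed = 1L,
                       dataset_mode = "per_individual") {
  pops <- pop_levels(matrix)
  k <- length(pops)
  if (k < 2L) stop("at least two populations required")
  theta <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (n_perm > 0L) {
      res <- permutation_test(matrix, pops[i], pops[j], n_perm = n_perm,
                              seed = seed + 1000L * i + j)
      theta[i, j] <- theta[j, i] <- res$theta
      pv[i, j] <- pv[j, i] <- res$p_value
    } else {
      theta[i, j] <- theta[j, i] <- pairwise_theta(matrix, pops[i], pops[j])
    }
  }
  structure(list(labels = pops, theta = theta, p_perm = pv, n_perm = n_perm,
                 dataset_mode = dataset_mode),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result (", x$dataset_mode, ", ", x$n_perm,
      " permutations)\ntheta:\n", sep = "")
  print(round(x$theta, 4))
  if (x$n_perm > 0L) {
    cat("permutation p-values:\n")
    print(round(x$p_perm, 4))
  }
  invisible(x)
}

#' Regional FST after pooling populations
#'
#' Pools individuals by region according to `region_mapping` and computes the
#' pairwise theta matrix between regions.
#'
#' @param matrix A [genotype_matrix()].
#' @param region_mapping Named character vector: population label -> region.
#' @inheritParams fst_matrix
#' @return An `fst_result` over regions.
#' @export
regional_theta <- function(matrix, region_mapping, n_perm = 1000L,
                           seed = 1L, dataset_mode = "per_individual") {
  pops <- pop_levels(matrix)
  if (!all(pops %in% names(region_mapping)))
    stop("region_mapping must cover every population")
  if (any(!nzchar(region_mapping)) ||
      length(unique(region_mapping[pops])) < 2L)
    stop("at least two non-empty regions required")
  pooled <- matrix
  pooled$populations <- unname(region_mapping[matrix$populations])
  fst_matrix(pooled, n_perm = n_perm, seed = seed,
             dataset_mode = dataset_mode)
}
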