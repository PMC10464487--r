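#' Probability of identity for codominant markers
#'
#' For each locus with allele frequencies `p`, the probability that two
#' independent (sexually produced) individuals share the same genotype is
#' `sum(p^4) + sum_{i<j} (2 p_i p_j)^2`; across loci the values multiply.
#' A low combined P_ID means identical multilocus genotypes are credible
#' clones rather than chance matches.
#'
#' @param freqs A list of per-locus allele frequency vectors (each summing to
#'   1), e.g. the `freq` component of [allele_frequencies()].
#' @return A list with `per_locus` (named numeric) and `combined` (product).
#' @export
probability_of_identity <- function(freqs) {
  if (length(freqs) == 0L) stop("no loci supplied")
  per_locus <- vapply(seq_along(freqs), function(l) {
    p <- freqs[[l]]
    if (length(p) == 0L || any(is.na(p))) stop("empty locus at position ", l)
    p <- p / sum(p)
    het <- outer(p, p)
    sum(p^4) + sum((2 * het[upper.tri(het)])^2)
  }, numeric(1))
  names(per_locus) <- names(freqs)
  list(per_locus = per_locus, combined = prod(per_locus))
}

# internal: do individuals i and j carry the same MLG under a policy?
# calls: n x L x 2 order-normalized array
mlg_match_matrix <- function(calls, policy, min_loci) {
  n <- dim(calls)[1]
  miss <- is.na(calls[, , 1, drop = FALSE])[, , 1, drop = TRUE]
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = n)
  complete <- rowSums(miss) == 0L
  match <- matrix(FALSE, n, n)
  a1 <- calls[, , 1, drop = TRUE]; a2 <- calls[, , 2, drop = TRUE]
  if (is.null(dim(a1))) { a1 <- matrix(a1, nrow = n); a2 <- matrix(a2, nrow = n) }
  for (i in seq_len(n)) {
    if (i == n) break
    for (j in (i + 1L):n) {
      ov <- !miss[i, ] & !miss[j, ]
      n_ov <- sum(ov)
      eq <- n_ov > 0L &&
        all(a1[i, ov] == a1[j, ov]) && all(a2[i, ov] == a2[j, ov])
      m <- if (policy == "strict") complete[i] && complete[j] && eq
           else eq && n_ov >= min_loci
      match[i, j] <- match[j, i] <- isTRUE(m)
    }
  }
  match
}

# internal: connected components of a logical adjacency matrix
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(adj[v, ] & is.na(comp))
      if (length(nb)) stack <- c(stack, nb)
    }
  }
  comp
}

new_clone_partition <- function(level, groups, unassigned = character()) {
  representative <- vapply(groups, `[`, character(1), 1L)
  structure(list(level = level, groups = groups,
                 representative = representative, unassigned = unassigned),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("clone_partition (", x$level, "): ", length(x$groups), " groups over ",
      sum(sizes), " individuals\n", sep = "")
  if (length(x$unassigned))
    cat("unassigned (missing at all loci):",
        paste(x$unassigned, collapse = ", "), "\n")
  cat("group sizes:", paste(sort(sizes, decreasing = TRUE), collapse = " "),
      "\n")
  invisible(x)
}

#' Assign individuals to multilocus genotypes (MLGs)
#'
#' Two individuals share an MLG when their calls are equal at every locus
#' where both are scored. Under the default `"observed"` policy the match
#' additionally requires the scored overlap to cover at least `min_loci`
#' loci; under `"strict"` both individuals must be complete (no missing
#' data). Because observed-overlap matching is not transitive, groups are the
#' connected components of the pairwise match graph (single linkage).
#'
#' @param matrix A [genotype_matrix()].
#' @param missing_policy `"observed"` (default) or `"strict"`.
#' @param min_loci Minimum scored overlap for a match under `"observed"`.
#' @return A `clone_partition` at level `"MLG"`. Individuals missing at every
#'   locus are excluded and reported in the `unassigned` component.
#' @export
assign_mlg <- function(matrix, missing_policy = c("observed", "strict"),
                       min_loci = 4L) {
  missing_policy <- match.arg(missing_policy)
  if (n_loci(matrix) < 1L) stop("at least one locus required")
  miss <- is_missing_call(matrix)
  all_missing <- rowSums(!miss) == 0L
  unassigned <- matrix$individuals[all_missing]
  keep <- which(!all_missing)
  calls <- matrix$alleles[keep, , , drop = FALSE]
  ids <- matrix$individuals[keep]
  adj <- mlg_match_matrix(calls, missing_policy, min_loci)
  comp <- graph_components(adj)
  groups <- split(ids, comp)
  ord <- order(vapply(groups, function(g) match(g[1], ids), integer(1)))
  groups <- groups[ord]
  names(groups) <- sprintf("MLG_%03d", seq_along(groups))
  new_clone_partition("MLG", groups, unassigned)
}

# internal: stepwise-mutation distance (in motif steps) between two genotypes
# at one locus; the smaller of the two allele pairings; NA if either missing
smm_locus_steps <- function(g1, g2, motif) {
  if (any(is.na(g1)) || any(is.na(g2))) return(NA_real_)
  d1 <- abs(g1[1] - g2[1]) + abs(g1[2] - g2[2])
  d2 <- abs(g1[1] - g2[2]) + abs(g1[2] - g2[1])
  min(d1, d2) / motif
}

#' Stepwise-mutation distance between two multilocus genotypes
#'
#' Sum over loci of the minimum total allele-size difference (over the two
#' possible pairings of alleles) divided by the locus motif length. Loci
#' missing in either genotype contribute 0. Non-integer step counts (size
#' differences that are not a motif multiple) are rounded to the nearest
#' step with a warning.
#'
#' @param matrix A [genotype_matrix()].
#' @param i,j Individual identifiers or indices.
#' @return Distance in mutational steps (numeric).
#' @export
smm_distance <- function(matrix, i, j) {
  if (is.character(i)) i <- match(i, matrix$individuals)
  if (is.character(j)) j <- match(j, matrix$individuals)
  steps <- vapply(seq_len(n_loci(matrix)), function(l)
    smm_locus_steps(matrix$alleles[i, l, ], matrix$alleles[j, l, ],
                    matrix$loci$motif_length[l]), numeric(1))
  steps[is.na(steps)] <- 0
  if (any(abs(steps - round(steps)) > 1e-9)) {
    warning("size difference not a motif multiple; rounded to nearest step")
    steps <- round(steps)
  }
  sum(steps)
}

#' Collapse MLGs into multilocus lineages (MLLs)
#'
#' Accounts for somatic mutation and scoring error by merging MLGs whose
#' representatives lie within `threshold_steps` mutational steps under the
#' stepwise mutation model (one-step mutations, distances summed over loci,
#' the smaller of the two allele pairings per locus). Merging is by single
#' linkage: chains of pairwise-close MLGs join one lineage.
#'
#' @param partition A `clone_partition` at level `"MLG"` from [assign_mlg()].
#' @param matrix The [genotype_matrix()] the partition was built from.
#' @param threshold_steps Maximum mutational distance merged (default 4).
#' @return A `clone_partition` at level `"MLL"`.
#' @export
collapse_mll <- function(partition, matrix, threshold_steps = 4) {
  reps <- partition$representative
  k <- length(reps)
  adj <- matrix(FALSE, k, k)
  if (k > 1L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      d <- smm_distance(matrix, reps[a], reps[b])
      adj[a, b] <- adj[b, a] <- d <= threshold_steps
    }
  }
  comp <- graph_components(adj)
  merged <- lapply(split(seq_len(k), comp), function(ix)
    unlist(partition$groups[ix], use.names = FALSE))
  ord <- order(vapply(merged, function(g) match(g[1], matrix$individuals),
                      integer(1)))
  merged <- merged[ord]
  names(merged) <- sprintf("MLL_%03d", seq_along(merged))
  new_clone_partition("MLL", merged, partition$unassigned)
}

# internal: fast MLG count used by the randomization test
count_mlg <- function(calls, policy, min_loci) {
  max(graph_components(mlg_match_matrix(calls, policy, min_loci)))
}

#' Randomization test for sexual reproduction
#'
#' Tests whether the observed clonal diversity (number of distinct MLGs) is
#' compatible with pure sexual reproduction by randomising alleles over
#' individuals independently within each locus (the missing-data pattern is
#' kept fixed) and recounting MLGs. The p-value uses the add-one convention
#' `p = (1 + #[N_MLG* <= N_MLG_obs]) / (n_rand + 1)`; a small p means the
#' observed clonality is unlikely under random mating.
#'
#' @param matrix A [genotype_matrix()].
#' @param population Population label to test.
#' @param n_rand Number of randomizations (>= 99).
#' @param seed Integer RNG seed.
#' @inheritParams assign_mlg
#' @return A list with `p_value`, `n_mlg_obs`, `null_n_mlg` (the randomized
#'   counts) and `n_rand`.
#' @export
sexual_null_test <- function(matrix, population, n_rand = 999L, seed = 1L,
                             missing_policy = "observed", min_loci = 4L) {
  if (n_rand < 99L) stop("n_rand must be at least 99")
  sub <- pop_subset(matrix, population)
  if (n_ind(sub) < 2L) stop("population of 1 individual: test undefined")
  set.seed(seed)
  calls <- sub$alleles
  obs <- count_mlg(calls, missing_policy, min_loci)
  L <- n_loci(sub)
  null_counts <- integer(n_rand)
  for (r in seq_len(n_rand)) {
    perm <- calls
    for (l in seq_len(L)) {
      slot <- perm[, l, ]
      ok <- !is.na(slot)
      vals <- slot[ok]
      slot[ok] <- vals[sample.int(length(vals))]
      # re-normalize pair order after shuffling
      lo <- pmin(slot[, 1], slot[, 2]); hi <- pmax(slot[, 1], slot[, 2])
      perm[, l, 1] <- lo; perm[, l, 2] <- hi
    }
    null_counts[r] <- count_mlg(perm, missing_policy, min_loci)
  }
  p <- (1 + sum(null_counts <= obs)) / (n_rand + 1)
  list(p_value = p, n_mlg_obs = obs, null_n_mlg = null_counts,
       n_rand = n_rand)
}

#' Clonal-structure statistics for one population
#'
#' Computes the genotypic diversity panel: with `N` individuals partitioned
#' into MLG/MLL groups of sizes `n_i` and `g_i = n_i / N`:
#' Stoddart-Taylor observed genotypic diversity `Go = 1 / sum(g_i^2)`, its
#' expectation under full sexuality `Ge = N`, genotypic diversity
#' `G = Go / Ge`, clonal richness `R = (N_MLG - 1) / (N - 1)`, evenness
#' `E_D = Go / N_MLG`, the unbiased Simpson index
#' `1 - D = (N / (N - 1)) * (1 - sum(g_i^2))` and the Shannon-Wiener index
#' in log base 10. A reproductive-mode label is attached from configurable
#' `G` thresholds.
#'
#' @param matrix A [genotype_matrix()].
#' @param partition A `clone_partition` covering the population's members.
#' @param population Population label.
#' @param mode_thresholds Named numeric: lower `G` bounds for the
#'   `predominantly_sexual` and `mostly_sexual` labels.
#' @param shannon_correction If `TRUE`, adds the first-order small-sample
#'   bias correction `(N_MLG - 1) / (2 N ln 10)` to the Shannon index
#'   (default off).
#' @return An object of class `clonal_stats` (a list with fields `N`,
#'   `N_MLG`, `R`, `Go`, `Ge`, `G`, `E_D`, `simpson_1mD`, `shannon_H`,
#'   `mode_label`, `population`, `level`).
#' @export
clonal_statistics <- function(matrix, partition, population,
                              mode_thresholds = c(predominantly = 0.65,
                                                  mostly = 0.5),
                              shannon_correction = FALSE) {
  members <- unlist(partition$groups, use.names = FALSE)
  in_pop <- matrix$individuals[matrix$populations == population]
  sizes <- vapply(partition$groups, function(g) sum(g %in% in_pop), integer(1))
  sizes <- sizes[sizes > 0L]
  N <- sum(sizes)
  if (N < 2L) stop("population must have at least 2 partitioned individuals")
  g <- sizes / N
  n_mlg <- length(sizes)
  Go <- 1 / sum(g^2)
  Ge <- N
  G <- Go / Ge
  R <- (n_mlg - 1) / (N - 1)
  E_D <- Go / n_mlg
  simpson <- (N / (N - 1)) * (1 - sum(g^2))
  H <- -sum(g * log10(g))
  if (shannon_correction) H <- H + (n_mlg - 1) / (2 * N * log(10))
  label <- if (G >= 1 - 1e-9) "fully_sexual"
    else if (G >= mode_thresholds[["predominantly"]]) "predominantly_sexual"
    else if (G >= mode_thresholds[["mostly"]]) "mostly_sexual"
    else "mixed_clonal"
  structure(list(population = population, level = partition$level, N = N,
                 N_MLG = n_mlg, R = R, Go = Go, Ge = Ge, G = G, E_D = E_D,
                 simpson_1mD = simpson, shannon_H = H,
                 evenness_go_nmlg = E_D, mode_label = label),
            class = "clonal_stats")
}

#' @export
print.clonal_stats <- function(x, ...) {
  cat(sprintf(
    "clonal_stats [%s, %s]: N=%d N_MLG=%d R=%.2f Go=%.1f G=%.2f E_D=%.2f 1-D=%.2f H'=%.2f (%s)\n",
    x$population, x$level, x$N, x$N_MLG, x$R, x$Go, x$G, x$E_D,
    x$simpson_1mD, x$shannon_H, x$mode_label))
  invisible(x)
}

#' Clonal statistics for every population
#'
#' @param matrix A [genotype_matrix()].
#' @param partition A `clone_partition`, by default [assign_mlg()] on
#'   `matrix`.
#' @param ... Passed to [clonal_statistics()].
#' @return A data.frame with one row per population, mirroring the usual
#'   summary-table layout (N, N_MLG, R, Go, Ge, G, 1-D, E_D, H').
#' @export
clonal_stats_table <- function(matrix, partition = assign_mlg(matrix), ...) {
  rows <- lapply(pop_levels(matrix), function(p) {
    s <- clonal_statistics(matrix, partition, p, ...)
    data.frame(population = p, N = s$N, N_MLG = s$N_MLG, R = s$R, Go = s$Go,
               Ge = s$Ge, G = s$G, simpson_1mD = s$simpson_1mD, E_D = s$E_D,
               shannon_H = s$shannon_H, mode_label = s$mode_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression of genotypic diversity on genotypic evenness
#'
#' Ordinary least squares of `G` on `Go / N_MLG` across populations; the
#' relationship separates predominantly sexual populations (both near 1)
#' from clonally inflated ones. Reports the slope, intercept, R-squared and
#' the F-test p-value on (1, n-2) degrees of freedom.
#'
#' @param stats A data.frame from [clonal_stats_table()] (or a list of
#'   `clonal_stats` objects), or any data.frame with columns `G` and `E_D`.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n` and
#'   the fitted `model`.
#' @export
diversity_evenness_regression <- function(stats) {
  if (is.list(stats) && !is.data.frame(stats) &&
      inherits(stats[[1]], "clonal_stats")) {
    stats <- data.frame(G = vapply(stats, `[[`, numeric(1), "G"),
                        E_D = vapply(stats, `[[`, numeric(1), "E_D"))
  }
  if (nrow(stats) < 3L) stop("at least 3 populations required")
  x <- stats$E_D; y <- stats$G
  if (stats::var(x) == 0) stop("zero variance in evenness: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = unname(p), n = nrow(stats),
       model = fit)
}
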