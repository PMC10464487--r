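#' Bayesian admixture-model clustering (Gibbs sampler)
#'
#' Fits the no-linkage admixture model: each allele copy of individual `i`
#' originates from one of `K` clusters with probability `Q[i, k]`, and a copy
#' from cluster `k` at locus `l` carries allele `a` with probability
#' `P[k, l, a]`. The Gibbs sweep alternates (i) sampling each copy's cluster
#' of origin, (ii) `P | Z ~ Dirichlet(lambda + counts)`, (iii)
#' `Q[i] | Z ~ Dirichlet(alpha + copy counts)`, with a single shared `alpha`
#' updated by a Metropolis random walk on the log scale (proposal sd 0.05).
#' Allele frequencies are independent across clusters. Missing calls are
#' skipped. The estimated log probability of data is the standard
#' harmonic-adjustment estimator `mean(l) - var(l) / 2` over the post-burn-in
#' log-likelihood trace.
#'
#' An optional simplified location prior (`locprior`) augments the symmetric
#' `alpha` for individual `i` by `locprior_r` times its population's current
#' cluster assignment proportions.
#'
#' @param matrix A [genotype_matrix()].
#' @param K Number of clusters (>= 1, at most the number of individuals).
#' @param burnin Burn-in sweeps discarded.
#' @param iters Total sweeps; must exceed `burnin`.
#' @param alpha_init Initial admixture parameter.
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param locprior Use the location-informed prior (off by default).
#' @param locprior_r Strength of the location prior.
#' @param update_alpha Update `alpha` by Metropolis (default `TRUE`).
#' @param seed Integer RNG seed; runs are bit-reproducible given the seed and
#'   iteration schedule.
#' @return An object of class `admixture_run`: `K`, `Q` (individuals x K
#'   posterior-mean memberships), `P` (per-locus cluster allele-frequency
#'   matrices), `alpha`, `lnPD`, `loglik` trace, and run metadata.
#' @export
run_admixture <- function(matrix, K, burnin = 2000L, iters = 10000L,
                          alpha_init = 1.0, lambda = 1.0, locprior = FALSE,
                          locprior_r = 1.0, update_alpha = TRUE, seed = 1L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > n_ind(matrix)) stop("K exceeds the number of individuals")
  if (iters <= burnin) stop("iters must exceed burnin")
  L <- n_loci(matrix)
  allele_sets <- lapply(seq_len(L), function(l) {
    sort(unique(as.vector(matrix$alleles[, l, ])))
  })
  n_alleles <- lengths(allele_sets)
  if (any(n_alleles == 0L)) stop("locus with no scored calls")
  geno <- base::matrix(-1L, n_ind(matrix), 2L * L)
  for (l in seq_len(L)) {
    for (c in 1:2) {
      v <- match(matrix$alleles[, l, c], allele_sets[[l]]) - 1L
      v[is.na(v)] <- -1L
      geno[, 2L * (l - 1L) + c] <- v
    }
  }
  pops <- pop_levels(matrix)
  pop_index <- match(matrix$populations, pops) - 1L
  set.seed(seed)
  res <- .admixture_gibbs(geno, as.integer(n_alleles), K,
                          as.integer(burnin), as.integer(iters),
                          alpha_init, lambda, isTRUE(locprior),
                          as.integer(pop_index), length(pops),
                          locprior_r, 0.05, isTRUE(update_alpha))
  ll <- res$loglik
  lnPD <- mean(ll) - stats::var(ll) / 2
  Q <- res$Q
  dimnames(Q) <- list(matrix$individuals, paste0("cluster_", seq_len(K)))
  P <- res$P
  names(P) <- matrix$loci$name
  for (l in seq_len(L))
    dimnames(P[[l]]) <- list(paste0("cluster_", seq_len(K)),
                             allele_sets[[l]])
  structure(list(K = K, Q = Q, P = P, alpha = mean(res$alpha_trace),
                 lnPD = lnPD, loglik = ll, seed = seed, burnin = burnin,
                 iters = iters, locprior_used = isTRUE(locprior)),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: K=%d, %d individuals, lnPD=%.2f, alpha=%.3f%s\n",
              x$K, nrow(x$Q), x$lnPD, x$alpha,
              if (x$locprior_used) " (location prior)" else ""))
  invisible(x)
}

#' Replicated admixture runs over a range of K
#'
#' @inheritParams run_admixture
#' @param k_range Integer vector of K values (e.g. `1:6`).
#' @param n_reps Replicates per K (distinct seeds derived from `seed`).
#' @param ... Passed to [run_admixture()].
#' @return A list of `admixture_run` objects (input for
#'   [evanno_delta_k()]).
#' @export
admixture_scan <- function(matrix, k_range = 1:6, n_reps = 3L, seed = 1L,
                           ...) {
  runs <- list()
  for (K in k_range) {
    for (r in seq_len(n_reps)) {
      runs[[length(runs) + 1L]] <-
        run_admixture(matrix, K, seed = seed + 97L * K + r, ...)
    }
  }
  runs
}

#' Evanno delta-K model selection
#'
#' For each K with both neighbors present, computes the second-order rate of
#' change of the mean estimated log probability of data,
#' `L''(K) = |L(K+1) - 2 L(K) + L(K-1)|`, normalized by the replicate
#' standard deviation: `deltaK = L''(K) / sd(lnPD at K)`. The optimal K is
#' the argmax over defined values. The full table is returned so secondary
#' peaks can be inspected rather than only the argmax.
#'
#' @param runs A list of `admixture_run` objects (several replicates per K).
#' @return An object of class `delta_k_table`: a data.frame with columns
#'   `K`, `n_reps`, `mean_lnPD`, `sd_lnPD`, `delta_k`, plus attribute
#'   `optimal_K`.
#' @export
evanno_delta_k <- function(runs) {
  Ks <- vapply(runs, `[[`, integer(1), "K")
  ln <- vapply(runs, `[[`, numeric(1), "lnPD")
  uK <- sort(unique(Ks))
  if (length(uK) < 3L) stop("at least 3 consecutive K values required")
  if (any(diff(uK) != 1L)) stop("K values must be consecutive")
  if (any(tabulate(factor(Ks, levels = uK)) < 2L))
    stop("at least 2 replicates per K required")
  tab <- data.frame(K = uK,
                    n_reps = as.integer(table(factor(Ks, levels = uK))),
                    mean_lnPD = tapply(ln, factor(Ks, levels = uK), mean),
                    sd_lnPD = tapply(ln, factor(Ks, levels = uK), stats::sd))
  rownames(tab) <- NULL
  tab$delta_k <- NA_real_
  for (i in seq_along(uK)) {
    if (i == 1L || i == length(uK)) next
    lpp <- abs(tab$mean_lnPD[i + 1] - 2 * tab$mean_lnPD[i] +
               tab$mean_lnPD[i - 1])
    if (tab$sd_lnPD[i] > 0) tab$delta_k[i] <- lpp / tab$sd_lnPD[i]
    else warning("sd(lnPD) = 0 at K = ", uK[i], ": delta-K undefined there")
  }
  opt <- if (all(is.na(tab$delta_k))) NA_integer_
         else tab$K[which.max(tab$delta_k)]
  structure(tab, class = c("delta_k_table", "data.frame"), optimal_K = opt)
}

#' @export
print.delta_k_table <- function(x, ...) {
  cat("Evanno delta-K table (optimal K =", attr(x, "optimal_K"), ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Threshold cluster assignment from a Q matrix
#'
#' @param Q Membership matrix (individuals x K, rows summing to 1), e.g. the
#'   `Q` of an `admixture_run`.
#' @param threshold Minimum membership for assignment; individuals whose
#'   maximum membership does not exceed it are `NA` (unassigned).
#' @return Integer vector of cluster indices (`NA` = unassigned), named by
#'   individual.
#' @export
assign_clusters <- function(Q, threshold = 0.75) {
  idx <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), idx)]
  idx[mx <= threshold] <- NA_integer_
  stats::setNames(idx, rownames(Q))
}

# internal: greedy column matching maximizing summed correlation
greedy_column_match <- function(Qref, Q) {
  K <- ncol(Qref)
  cm <- suppressWarnings(stats::cor(Qref, Q))
  cm[!is.finite(cm)] <- 0
  perm <- integer(K)
  used_r <- logical(K); used_c <- logical(K)
  for (step in seq_len(K)) {
    cm2 <- cm
    cm2[used_r, ] <- -Inf; cm2[, used_c] <- -Inf
    ij <- arrayInd(which.max(cm2), dim(cm2))
    perm[ij[1]] <- ij[2]
    used_r[ij[1]] <- TRUE; used_c[ij[2]] <- TRUE
  }
  perm
}

#' Align replicate runs across label switching
#'
#' Cluster labels are arbitrary across replicate MCMC runs. Columns of each
#' run's Q matrix are permuted, by greedy correlation matching against the
#' first run, so that matched clusters line up. The chosen permutation never
#' yields a lower summed column correlation than the identity.
#'
#' @param runs A list of `admixture_run` objects with identical K and
#'   individuals.
#' @return The list of runs with `Q` (and `P`) columns permuted; the applied
#'   permutations are attached as attribute `permutations`.
#' @export
align_replicates <- function(runs) {
  Ks <- vapply(runs, `[[`, integer(1), "K")
  if (length(unique(Ks)) != 1L) stop("runs must share the same K")
  ref <- runs[[1]]$Q
  perms <- vector("list", length(runs))
  perms[[1]] <- seq_len(Ks[1])
  for (r in seq_along(runs)[-1]) {
    perm <- greedy_column_match(ref, runs[[r]]$Q)
    obj_perm <- sum(diag(suppressWarnings(
      stats::cor(ref, runs[[r]]$Q[, perm, drop = FALSE]))), na.rm = TRUE)
    obj_id <- sum(diag(suppressWarnings(
      stats::cor(ref, runs[[r]]$Q))), na.rm = TRUE)
    if (obj_perm < obj_id) perm <- seq_len(Ks[1])
    runs[[r]]$Q <- runs[[r]]$Q[, perm, drop = FALSE]
    colnames(runs[[r]]$Q) <- colnames(ref)
    runs[[r]]$P <- lapply(runs[[r]]$P, function(pm) {
      out <- pm[perm, , drop = FALSE]
      rownames(out) <- rownames(pm)
      out
    })
    perms[[r]] <- perm
  }
  attr(runs, "permutations") <- perms
  runs
}
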