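# Builders and independent oracles shared across the suite.

# genotype_matrix from an n x (2L) matrix of allele sizes (columns a1,a2 per
# locus); NA = missing
build_gm <- function(calls, pops, motif = 2L, ids = NULL) {
  n <- nrow(calls); L <- ncol(calls) / 2
  arr <- array(NA_integer_, dim = c(n, L, 2L))
  for (l in seq_len(L)) {
    arr[, l, 1] <- calls[, 2 * l - 1]
    arr[, l, 2] <- calls[, 2 * l]
  }
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  genotype_matrix(arr, ids, pops,
                  locus_meta(sprintf("L%02d", seq_len(L)), motif))
}

# one population whose MLG structure has the given group sizes: members of a
# group share a genotype, groups are mutually distinct at every locus
gm_clonal_structure <- function(sizes, pop = "P", n_loci = 6L) {
  n <- sum(sizes)
  calls <- matrix(NA_integer_, n, 2L * n_loci)
  row <- 0L
  for (g in seq_along(sizes)) {
    geno <- rep(100L + 2L * g, 2L * n_loci)
    for (k in seq_len(sizes[g])) {
      row <- row + 1L
      calls[row, ] <- geno
    }
  }
  build_gm(calls, rep(pop, n))
}

# independent route to the Weir-Cockerham components: ANOVA mean squares on
# per-copy allele indicators (MSP / MSI / MSG), not the closed-form p-bar
# formulas used by the package
wc_anova_locus <- function(alle, pop) {
  ok <- !is.na(alle[, 1]); alle <- alle[ok, , drop = FALSE]; pop <- pop[ok]
  pops <- unique(pop); r <- length(pops)
  ni <- vapply(pops, function(p) sum(pop == p), numeric(1))
  nbar <- mean(ni); nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(as.vector(alle)))
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    x <- (alle == al) * 1
    xb_ind <- rowMeans(x)
    p_i <- vapply(pops, function(p) mean(xb_ind[pop == p]), numeric(1))
    pbar <- sum(ni * p_i) / sum(ni)
    MSP <- sum(2 * ni * (p_i - pbar)^2) / (r - 1)
    MSI <- sum(vapply(seq_along(pops), function(k)
      sum(2 * (xb_ind[pop == pops[k]] - p_i[k])^2), numeric(1))) /
      sum(ni - 1)
    MSG <- sum((x - xb_ind)^2) / sum(ni)
    a_tot <- a_tot + (MSP - MSI) / (2 * nc)
    b_tot <- b_tot + (MSI - MSG) / 2
    c_tot <- c_tot + MSG
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

wc_anova_theta <- function(gm) {
  comp <- rowSums(vapply(seq_len(n_loci(gm)), function(l)
    wc_anova_locus(gm$alleles[, l, ], gm$populations), numeric(3)))
  comp["a"] / sum(comp)
}

# P_ID oracle: enumerate all unordered genotypes under HWE and sum squared
# genotype probabilities (match probability of two independent draws)
pid_oracle_locus <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) for (j in i:k) {
    pr <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pr^2
  }
  tot
}

# exact HWE oracle by full enumeration of orderings of the pooled allele
# copies (each perfect matching appears equally often); feasible to 2n = 8
all_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

hwe_permutation_oracle <- function(a1, a2) {
  n <- length(a1)
  pool <- c(a1, a2)
  perms <- all_permutations(seq_along(pool))
  key <- function(x, y) paste(sort(paste(pmin(x, y), pmax(x, y))),
                              collapse = "|")
  obs_key <- key(a1, a2)
  obs_het <- sum(a1 != a2)
  keys <- character(nrow(perms)); hets <- integer(nrow(perms))
  for (r in seq_len(nrow(perms))) {
    g <- pool[perms[r, ]]
    x <- g[seq_len(n)]; y <- g[n + seq_len(n)]
    keys[r] <- key(x, y)
    hets[r] <- sum(x != y)
  }
  tab <- table(keys)
  probs <- as.numeric(tab) / nrow(perms)
  names(probs) <- names(tab)
  het_of <- tapply(hets, keys, function(h) h[1])
  p_obs <- probs[[obs_key]]
  list(p_two = sum(probs[probs <= p_obs + 1e-12]),
       p_deficit = sum(probs[het_of[names(probs)] <= obs_het]))
}

# brute-force minimum spanning tree over all edge subsets of size n-1
bruteforce_mst <- function(m) {
  n <- nrow(m)
  edges <- which(upper.tri(m), arr.ind = TRUE)
  best_w <- Inf; best <- NULL
  for (comb in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    adj <- matrix(FALSE, n, n)
    for (e in comb) {
      adj[edges[e, 1], edges[e, 2]] <- TRUE
      adj[edges[e, 2], edges[e, 1]] <- TRUE
    }
    # connectivity by repeated expansion
    seen <- c(1L); repeat {
      nb <- which(apply(adj[seen, , drop = FALSE], 2, any))
      new <- setdiff(nb, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    if (length(seen) < n) next
    w <- sum(m[edges[comb, , drop = FALSE]])
    if (w < best_w - 1e-12) { best_w <- w; best <- comb }
  }
  list(weight = best_w,
       edges = edges[best, , drop = FALSE])
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab)); sum_j <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_i * sum_j / n2
  (sum_ij - exp_idx) / ((sum_i + sum_j) / 2 - exp_idx)
}
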