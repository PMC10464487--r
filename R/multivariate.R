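#' Individuals x alleles count table
#'
#' Expands genotypes into per-(locus, allele) counts in {0, 1, 2}. Missing
#' loci are imputed with the column mean over non-missing individuals (the
#' standard pre-processing for PCA/DAPC on codominant data); imputed cells
#' are flagged in the `imputed` mask.
#'
#' @param matrix A [genotype_matrix()].
#' @param missing `"mean_impute"` (default) or `"zero"`.
#' @return An object of class `allele_count_table`: `counts` (numeric matrix,
#'   individuals x alleles), `imputed` (logical mask), `locus` (column ->
#'   locus map).
#' @export
build_count_table <- function(matrix, missing = c("mean_impute", "zero")) {
  missing <- match.arg(missing)
  n <- n_ind(matrix); L <- n_loci(matrix)
  cols <- list(); locus_of <- character()
  for (l in seq_len(L)) {
    alleles <- sort(unique(as.vector(matrix$alleles[, l, ])))
    for (al in alleles) {
      cnt <- (matrix$alleles[, l, 1] == al) + (matrix$alleles[, l, 2] == al)
      nm <- paste0(matrix$loci$name[l], ".", al)
      cols[[nm]] <- as.numeric(cnt)
      locus_of[nm] <- matrix$loci$name[l]
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- matrix$individuals
  imputed <- is.na(counts)
  if (any(imputed)) {
    for (j in seq_len(ncol(counts))) {
      na <- is.na(counts[, j])
      if (!any(na)) next
      counts[na, j] <- if (missing == "mean_impute")
        mean(counts[!na, j]) else 0
    }
  }
  structure(list(counts = counts, imputed = imputed, locus = locus_of),
            class = "allele_count_table")
}

#' Principal component analysis of the allele-count table
#'
#' Centered (not scaled) PCA via singular value decomposition.
#'
#' @param table An `allele_count_table` from [build_count_table()] (or a
#'   plain numeric matrix).
#' @param n_axes Number of axes to keep (default: all with positive
#'   variance).
#' @return A list with `scores`, `loadings`, `eigenvalues`,
#'   `explained_variance` (fractions) and `total_variance`.
#' @export
pca_genotypes <- function(table, n_axes = NULL) {
  m <- if (inherits(table, "allele_count_table")) table$counts else table
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- pr$sdev^2
  keep <- which(eig > 1e-12)
  if (!is.null(n_axes)) {
    if (n_axes > length(keep)) stop("n_axes exceeds the rank of the table")
    keep <- keep[seq_len(n_axes)]
  }
  list(scores = pr$x[, keep, drop = FALSE],
       loadings = pr$rotation[, keep, drop = FALSE],
       eigenvalues = eig[keep],
       explained_variance = eig[keep] / sum(eig),
       total_variance = sum(eig))
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the allele-count table to `n_pca` principal components, then fits
#' Fisher linear discriminants maximizing between-group over within-group
#' variance (via [MASS::lda()]). The proportion of individuals reassigned to
#' their own group by the discriminant functions is reported.
#'
#' @param table An `allele_count_table` or numeric matrix.
#' @param groups Factor-like group membership, one per individual; every
#'   group must have at least 2 members.
#' @param n_pca Number of retained PC axes; `NULL` keeps the smallest number
#'   explaining at least 90% of total variance.
#' @param n_da Number of discriminant axes (at most `n_groups - 1`).
#' @return A list with `coordinates` (individuals x discriminant axes),
#'   `centroids`, `assignment` (posterior-based group calls),
#'   `reassignment_proportion`, `n_pca`, `lda` (the fitted model) and
#'   `pca` (the reduction).
#' @export
dapc <- function(table, groups, n_pca = NULL, n_da = NULL) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  p <- pca_genotypes(table)
  if (is.null(n_pca)) {
    cum <- cumsum(p$explained_variance)
    n_pca <- which(cum >= 0.9)[1]
    if (is.na(n_pca)) n_pca <- length(p$eigenvalues)
  }
  n_pca <- min(n_pca, ncol(p$scores))
  X <- p$scores[, seq_len(n_pca), drop = FALSE]
  max_da <- nlevels(droplevels(groups)) - 1L
  if (is.null(n_da)) n_da <- max_da
  if (n_da > max_da) stop("n_da cannot exceed n_groups - 1")
  fit <- MASS::lda(X, grouping = groups)
  pred <- stats::predict(fit)
  coords <- pred$x[, seq_len(min(n_da, ncol(pred$x))), drop = FALSE]
  centroids <- apply(coords, 2, function(v) tapply(v, groups, mean))
  list(coordinates = coords, centroids = centroids,
       assignment = pred$class,
       reassignment_proportion = mean(pred$class == groups),
       n_pca = n_pca, lda = fit, pca = p)
}

#' Cross-validated DAPC reassignment accuracy
#'
#' Stratified k-fold cross-validation of the PCA + LDA pipeline: the model is
#' fit on the training folds and held-out individuals are assigned; the mean
#' proportion correctly reassigned estimates out-of-sample accuracy (useful
#' for choosing `n_pca` and for detecting overfitting to arbitrary groups).
#'
#' @inheritParams dapc
#' @param folds Number of folds.
#' @param seed Integer RNG seed for the fold split.
#' @return Mean held-out reassignment proportion.
#' @export
dapc_xval <- function(table, groups, n_pca = NULL, folds = 5L, seed = 1L) {
  m <- if (inherits(table, "allele_count_table")) table$counts else table
  groups <- as.factor(groups)
  set.seed(seed)
  fold_of <- integer(nrow(m))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  correct <- logical(nrow(m))
  for (f in seq_len(folds)) {
    train <- fold_of != f
    if (length(unique(groups[train])) < 2L) next
    p <- pca_genotypes(m[train, , drop = FALSE])
    k <- if (is.null(n_pca)) {
      w <- which(cumsum(p$explained_variance) >= 0.9)[1]
      if (is.na(w)) length(p$eigenvalues) else w
    } else min(n_pca, ncol(p$scores))
    fit <- MASS::lda(p$scores[, seq_len(k), drop = FALSE],
                     grouping = droplevels(groups[train]))
    ctr <- colMeans(m[train, , drop = FALSE])
    test_scores <- sweep(m[!train, , drop = FALSE], 2, ctr) %*%
      p$loadings[, seq_len(k), drop = FALSE]
    pred <- stats::predict(fit, test_scores)$class
    correct[!train] <- as.character(pred) == as.character(groups[!train])
  }
  mean(correct)
}

#' Nei genetic distance between two populations
#'
#' Nei's standard distance `D = -ln I` with the identity
#' `I = Jxy / sqrt(Jx * Jy)`, where `Jxy`, `Jx`, `Jy` are the sums of
#' `x * y`, `x^2` and `y^2` over alleles, aggregated over loci. The 1978
#' unbiased variant corrects `Jx` and `Jy` by `(2n J - 1) / (2n - 1)`.
#' Populations fixed for different alleles have `I = 0`; the infinite
#' distance is capped (flagged by attribute `capped`).
#'
#' @param matrix A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @param variant `"1972"` (standard, default) or `"1978"` (unbiased).
#' @param cap Cap for infinite distances.
#' @return Numeric distance (>= 0), with attribute `capped` if the identity
#'   was zero.
#' @export
nei_distance <- function(matrix, popA, popB, variant = c("1972", "1978"),
                         cap = 50) {
  variant <- match.arg(variant)
  fa <- suppressWarnings(allele_frequencies(matrix, popA))
  fb <- suppressWarnings(allele_frequencies(matrix, popB))
  shared <- intersect(names(fa$freq), names(fb$freq))
  if (length(shared) == 0L) stop("no shared scored loci")
  jxy <- 0; jx <- 0; jy <- 0
  for (nm in shared) {
    alleles <- union(names(fa$freq[[nm]]), names(fb$freq[[nm]]))
    x <- stats::setNames(numeric(length(alleles)), alleles)
    y <- x
    x[names(fa$freq[[nm]])] <- fa$freq[[nm]]
    y[names(fb$freq[[nm]])] <- fb$freq[[nm]]
    jxy <- jxy + sum(x * y)
    if (variant == "1978") {
      na <- fa$n_scored[[nm]]; nb <- fb$n_scored[[nm]]
      jx <- jx + (2 * na * sum(x^2) - 1) / (2 * na - 1)
      jy <- jy + (2 * nb * sum(y^2) - 1) / (2 * nb - 1)
    } else {
      jx <- jx + sum(x^2)
      jy <- jy + sum(y^2)
    }
  }
  I <- jxy / sqrt(jx * jy)
  if (I <= 0) {
    d <- cap
    attr(d, "capped") <- TRUE
    return(d)
  }
  max(0, -log(min(I, 1)))
}

#' Pairwise Nei distance matrix over populations
#'
#' @inheritParams nei_distance
#' @return Symmetric labeled matrix of distances.
#' @export
nei_distance_matrix <- function(matrix, variant = "1972", cap = 50) {
  pops <- pop_levels(matrix)
  k <- length(pops)
  d <- base::matrix(0, k, k, dimnames = list(pops, pops))
  if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- as.numeric(
      nei_distance(matrix, pops[i], pops[j], variant = variant, cap = cap))
  d
}

# internal union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Minimum spanning network from a distance matrix
#'
#' Kruskal's algorithm processed by distinct weight levels: within a level,
#' every edge joining two components (as they stood before the level) is
#' retained, so tied co-minimal edges all appear and the result is a network
#' rather than strictly a tree. With all-distinct weights it equals the
#' unique minimum spanning tree.
#'
#' @param distance_matrix Symmetric non-negative labeled matrix.
#' @return A data.frame edge list with columns `from`, `to`, `weight`.
#' @export
minimum_spanning_network <- function(distance_matrix) {
  m <- as.matrix(distance_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9 || any(m < 0))
    stop("distance matrix must be square, symmetric and non-negative")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)
  edges <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[edges]
  ord <- order(w)
  edges <- edges[ord, , drop = FALSE]; w <- w[ord]
  parent <- seq_len(n)
  out <- list()
  for (lev in unique(w)) {
    at <- which(w == lev)
    # evaluate all tied edges against the components before this level
    joins <- vapply(at, function(e)
      uf_find(parent, edges[e, 1]) != uf_find(parent, edges[e, 2]),
      logical(1))
    for (e in at[joins])
      out[[length(out) + 1L]] <- data.frame(
        from = labels[edges[e, 1]], to = labels[edges[e, 2]], weight = lev,
        stringsAsFactors = FALSE)
    for (e in at[joins]) {  # union after the whole level is evaluated
      ra <- uf_find(parent, edges[e, 1]); rb <- uf_find(parent, edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    if (length(unique(roots)) == 1L) break
  }
  do.call(rbind, out)
}
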