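#' Linearize FST for isolation-by-distance analysis
#'
#' The Rousset linearization `theta / (1 - theta)`, a monotone increasing
#' transform on `theta < 1`. Negative theta estimates pass through (flagged
#' with a warning) rather than being truncated.
#'
#' @param theta Numeric vector or matrix of FST values, all `< 1`.
#' @return Transformed values with the same shape.
#' @export
linearize_fst <- function(theta) {
  if (any(theta >= 1, na.rm = TRUE)) stop("theta must be < 1")
  if (any(theta < 0, na.rm = TRUE))
    warning("negative theta values passed through the linearization")
  theta / (1 - theta)
}

#' Great-circle distance (haversine)
#'
#' Fallback geographic distance when no over-water distance matrix is
#' supplied; Earth radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance in kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

#' Pairwise haversine distance matrix from site coordinates
#'
#' @param coords Data.frame with columns `site`, `lat`, `lon`.
#' @return Symmetric labeled matrix of distances in km.
#' @export
haversine_matrix <- function(coords) {
  k <- nrow(coords)
  m <- matrix(0, k, k, dimnames = list(coords$site, coords$site))
  if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- haversine_km(coords$lat[i], coords$lon[i],
                                       coords$lat[j], coords$lon[j])
  m
}

#' Mantel permutation test
#'
#' Pearson correlation of the off-diagonal elements of two labeled symmetric
#' matrices; the null distribution permutes rows and columns of `Y`
#' simultaneously. `p = (1 + #[r* >= r]) / (n_perm + 1)` (one-sided,
#' positive association).
#'
#' @param X,Y Symmetric matrices with identical labels.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @return A list with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(X, Y, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("matrices must have the same size")
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop("matrix labels do not match")
    Y <- Y[rownames(X), rownames(X)]
  }
  n <- nrow(X)
  if (n < 4L) stop("at least 4 populations required")
  lt <- lower.tri(X)
  if (stats::sd(Y[lt]) == 0 || stats::sd(X[lt]) == 0)
    stop("constant matrix: Mantel r undefined")
  r_obs <- stats::cor(X[lt], Y[lt])
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    r_star <- stats::cor(X[lt], Y[p, p][lt])
    if (r_star >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Isolation-by-distance analysis
#'
#' Regresses linearized FST (`theta / (1 - theta)`) on pairwise geographic
#' distance by ordinary least squares and attaches a Mantel permutation
#' test. Both the OLS F-test p and the Mantel p are reported, since either
#' convention appears in practice.
#'
#' @param fst_result An `fst_result` from [fst_matrix()] (or a labeled
#'   symmetric theta matrix).
#' @param dist_matrix Labeled symmetric geographic-distance matrix (km),
#'   e.g. from [read_distance_tsv()] or [haversine_matrix()].
#' @param n_perm Mantel permutations.
#' @param seed Integer RNG seed.
#' @return An object of class `ibd_result`: data.frame `pairs` (pop1, pop2,
#'   `distance_km`, `fst`, `linearized_fst`), `slope`, `intercept`,
#'   `r_squared`, `ols_p`, `mantel_r`, `mantel_p`, `n_perm`.
#' @export
ibd_analysis <- function(fst_result, dist_matrix, n_perm = 999L, seed = 1L) {
  theta <- if (inherits(fst_result, "fst_result")) fst_result$theta
           else as.matrix(fst_result)
  if (!setequal(rownames(theta), rownames(dist_matrix)))
    stop("FST and distance matrices must cover the same populations")
  dist_matrix <- dist_matrix[rownames(theta), rownames(theta)]
  lt <- which(lower.tri(theta), arr.ind = TRUE)
  pairs <- data.frame(pop1 = rownames(theta)[lt[, 2]],
                      pop2 = rownames(theta)[lt[, 1]],
                      distance_km = dist_matrix[lt],
                      fst = theta[lt], stringsAsFactors = FALSE)
  pairs$linearized_fst <- suppressWarnings(linearize_fst(pairs$fst))
  fit <- stats::lm(linearized_fst ~ distance_km, data = pairs)
  sm <- summary(fit)
  ols_p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE)
  lin <- suppressWarnings(linearize_fst(theta))
  diag(lin) <- 0
  mt <- mantel_test(dist_matrix, lin, n_perm = n_perm, seed = seed)
  structure(list(pairs = pairs, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, ols_p = unname(ols_p),
                 mantel_r = mt$r, mantel_p = mt$p_value, n_perm = n_perm,
                 model = fit),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "ibd_result: slope=%.3g, R2=%.3f, OLS p=%.4g, Mantel r=%.3f (p=%.4g, %d perms)\n",
    x$slope, x$r_squared, x$ols_p, x$mantel_r, x$mantel_p, x$n_perm))
  invisible(x)
}
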