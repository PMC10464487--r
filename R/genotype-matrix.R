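#' Locus metadata table
#'
#' Builds the per-locus metadata used throughout the package. Allele identity
#' is the integer fragment size in base pairs; repeat-step arithmetic (e.g.
#' stepwise-mutation distances) divides size differences by `motif_length`.
#'
#' @param name Character vector of unique locus names.
#' @param motif_length Integer vector (recycled) of base pairs per repeat unit,
#'   all >= 1. Dinucleotide loci have `motif_length = 2`, trinucleotide 3, etc.
#' @param size_min,size_max Optional numeric vectors giving the expected
#'   fragment size range in bp (informational).
#' @return A `data.frame` with columns `name`, `motif_length`, `size_min`,
#'   `size_max`.
#' @export
locus_meta <- function(name, motif_length = 2L, size_min = NA_real_,
                       size_max = NA_real_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("locus names must be unique")
  motif_length <- as.integer(rep_len(motif_length, length(name)))
  if (any(is.na(motif_length)) || any(motif_length < 1L))
    stop("motif_length must be an integer >= 1")
  data.frame(name = name, motif_length = motif_length,
             size_min = rep_len(as.numeric(size_min), length(name)),
             size_max = rep_len(as.numeric(size_max), length(name)),
             stringsAsFactors = FALSE)
}

#' Diploid codominant genotype matrix
#'
#' The central container: an individuals x loci table of unordered diploid
#' allele-size pairs with population labels and locus metadata. Allele calls
#' are positive integer fragment sizes (bp); a missing genotype has both
#' alleles `NA` (missingness is whole-genotype: half-coded calls are promoted
#' to missing by the readers).
#'
#' @param alleles Integer array of dimension `c(n_individuals, n_loci, 2)`.
#'   Pairs are order-normalized (low, high) by the constructor.
#' @param individuals Character vector of unique individual identifiers.
#' @param populations Character vector of non-empty population labels, one per
#'   individual.
#' @param loci Locus metadata as returned by [locus_meta()], one row per locus.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, individuals, populations, loci) {
  if (is.character(loci)) loci <- locus_meta(loci)
  alleles <- array(as.integer(alleles), dim = dim(alleles))
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("alleles must be an n x L x 2 array")
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  individuals <- as.character(individuals)
  populations <- as.character(populations)
  if (length(individuals) != n || length(populations) != n)
    stop("individuals/populations length must match rows of alleles")
  if (anyDuplicated(individuals)) stop("duplicate individual identifiers")
  if (any(is.na(populations)) || any(!nzchar(populations)))
    stop("population labels must be non-empty")
  if (nrow(loci) != L) stop("loci metadata rows must match number of loci")
  # whole-genotype missing: a half-call becomes fully missing
  a1 <- alleles[, , 1, drop = FALSE]; a2 <- alleles[, , 2, drop = FALSE]
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-coded call(s) promoted to MISSING")
    alleles[, , 1][half[, , 1]] <- NA_integer_
    alleles[, , 2][half[, , 1]] <- NA_integer_
  }
  ok <- !is.na(alleles)
  if (any(alleles[ok] <= 0L)) stop("non-missing allele sizes must be > 0")
  # order-normalize (low, high)
  lo <- pmin(alleles[, , 1], alleles[, , 2])
  hi <- pmax(alleles[, , 1], alleles[, , 2])
  alleles[, , 1] <- lo; alleles[, , 2] <- hi
  dimnames(alleles) <- list(individuals, loci$name, c("a1", "a2"))
  structure(list(alleles = alleles, individuals = individuals,
                 populations = populations, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_ind(x), "individuals x", n_loci(x), "loci,",
      length(unique(x$populations)), "population(s)\n")
  miss <- mean(is.na(x$alleles[, , 1])) * 100
  cat(sprintf("missing data: %.2f%%\n", miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  tab <- table(object$populations)
  cat("genotype_matrix with", n_ind(object), "individuals,", n_loci(object),
      "loci\nPopulations:\n")
  print(tab)
  print(missing_summary(object))
  invisible(object)
}

#' Number of individuals / loci
#' @param x A `genotype_matrix`.
#' @return An integer count.
#' @export
n_ind <- function(x) dim(x$alleles)[1]

#' @rdname n_ind
#' @export
n_loci <- function(x) dim(x$alleles)[2]

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x A `genotype_matrix`.
#' @param i Individual index (integer, logical or character).
#' @param j Locus index.
#' @param ... Unused.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, x$individuals)
  if (is.character(j)) j <- match(j, x$loci$name)
  genotype_matrix(x$alleles[i, j, , drop = FALSE], x$individuals[i],
                  x$populations[i], x$loci[j, , drop = FALSE])
}

#' Extract the individuals of one population
#' @param x A `genotype_matrix`.
#' @param population A population label present in `x`.
#' @return A `genotype_matrix` restricted to that population.
#' @export
pop_subset <- function(x, population) {
  keep <- x$populations == population
  if (!any(keep)) stop("no individuals in population '", population, "'")
  x[which(keep), ]
}

#' Population labels present in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of unique labels in order of first appearance.
#' @export
pop_levels <- function(x) unique(x$populations)

# internal: logical n x L matrix, TRUE where the call is missing
is_missing_call <- function(x) {
  m <- is.na(x$alleles[, , 1, drop = FALSE])
  dim(m) <- dim(m)[1:2]
  m
}
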