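#' Read a genepop genotype file
#'
#' Parses the classical genepop layout: a title line, locus names (one per
#' line or comma-separated), then `Pop` blocks of sample lines. Allele codes
#' are fixed width (2 or 3 digits per allele); the all-zero code is missing.
#' Both comma-terminated and plain whitespace sample names are accepted, and
#' `pop` is matched case-insensitively.
#'
#' @param path Path to a genepop `.gen`/`.txt` file.
#' @param digits Allele code width, 2 or 3. `NULL` (default) autodetects from
#'   the first genotype field.
#' @param pop_labels Either `"last"` (genepop convention: the block is labeled
#'   by its last sample's name) or `"index"` (`pop_1`, `pop_2`, ...).
#' @param loci Optional [locus_meta()] table overriding the default metadata
#'   (motif length 2) attached to the parsed loci.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, digits = NULL, pop_labels = c("last", "index"),
                         loci = NULL) {
  pop_labels <- match.arg(pop_labels)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a genepop file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a genepop file: no 'Pop' line found")
  header <- lines[2:(first_pop - 1L)]
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  if (L == 0L) stop("no locus names found before first 'Pop'")

  blocks <- split(seq_along(lines)[-seq_len(first_pop - 1L)],
                  cumsum(is_pop)[-seq_len(first_pop - 1L)])
  inds <- character(); pops <- character()
  allele_rows <- list()
  width <- NULL
  for (b in seq_along(blocks)) {
    idx <- setdiff(blocks[[b]], which(is_pop))
    if (length(idx) == 0L) stop("empty 'Pop' block in ", path)
    block_names <- character(length(idx))
    for (k in seq_along(idx)) {
      ln <- lines[idx[k]]
      if (grepl(",", ln)) {
        name <- trimws(sub(",.*$", "", ln))
        geno_part <- sub("^[^,]*,", "", ln)
        toks <- strsplit(trimws(geno_part), "\\s+")[[1]]
      } else {
        toks <- strsplit(trimws(ln), "\\s+")[[1]]
        name <- toks[1]; toks <- toks[-1]
      }
      toks <- toks[nzchar(toks)]
      if (length(toks) != L)
        stop("line ", idx[k], ": expected ", L, " genotype fields, found ",
             length(toks))
      if (!all(grepl("^[0-9]+$", toks)))
        stop("line ", idx[k], ": non-numeric genotype field")
      w <- unique(nchar(toks))
      if (length(w) != 1L)
        stop("line ", idx[k], ": mixed genotype field widths")
      if (w %% 2L != 0L)
        stop("line ", idx[k], ": odd-width allele field (width ", w, ")")
      if (is.null(width)) {
        width <- w %/% 2L
        if (!is.null(digits) && width != digits)
          stop("file uses ", width, "-digit alleles but digits=", digits,
               " was requested")
        if (!width %in% c(2L, 3L))
          stop("unsupported allele code width: ", width)
      } else if (w %/% 2L != width) {
        stop("line ", idx[k], ": inconsistent allele code width")
      }
      a1 <- as.integer(substr(toks, 1L, width))
      a2 <- as.integer(substr(toks, width + 1L, 2L * width))
      a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
      allele_rows[[length(allele_rows) + 1L]] <- cbind(a1, a2)
      block_names[k] <- name
    }
    lab <- if (pop_labels == "last") block_names[length(block_names)]
           else paste0("pop_", b)
    if (!nzchar(lab)) lab <- paste0("pop_", b)
    inds <- c(inds, block_names)
    pops <- c(pops, rep(lab, length(idx)))
  }
  n <- length(inds)
  arr <- array(NA_integer_, dim = c(n, L, 2L))
  for (i in seq_len(n)) arr[i, , ] <- allele_rows[[i]]
  if (anyDuplicated(inds))
    inds <- make.unique(inds, sep = "_")
  if (is.null(loci)) loci <- locus_meta(locus_names)
  else if (!identical(loci$name, locus_names))
    stop("supplied loci metadata does not match file locus names")
  genotype_matrix(arr, inds, pops, loci)
}

#' Write a genepop genotype file
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @param digits Allele code width (2 or 3); every allele size must fit.
#' @param title Title line (first line of the file).
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(matrix, path, digits = 3L,
                          title = "clonepop genotype export") {
  digits <- as.integer(digits)
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  maxa <- suppressWarnings(max(matrix$alleles, na.rm = TRUE))
  if (is.finite(maxa) && maxa > 10^digits - 1)
    stop("allele size ", maxa, " not representable with ", digits, " digits")
  pops <- pop_levels(matrix)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(matrix$loci$name, con)
  fmt <- paste0("%0", digits, "d")
  for (p in pops) {
    keep <- which(matrix$populations == p)
    if (length(keep) == 0L) stop("empty population: ", p)
    writeLines("Pop", con)
    for (i in keep) {
      a1 <- matrix$alleles[i, , 1]; a2 <- matrix$alleles[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      codes <- paste0(sprintf(fmt, a1), sprintf(fmt, a2))
      writeLines(paste0(matrix$individuals[i], " ,  ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a two-columns-per-locus CSV genotype table
#'
#' Expects a header `individual,population,<locus>.1,<locus>.2,...` with one
#' row per individual. Blank, `0` or `NA` cells are missing; a half-coded
#' genotype is promoted to fully missing with a warning.
#'
#' @param path CSV path.
#' @param loci Optional [locus_meta()] table (default motif length 2).
#' @return A [genotype_matrix()].
#' @export
read_csv_genotypes <- function(path, loci = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4L || !identical(tolower(names(df)[1:2]),
                                  c("individual", "population")))
    stop("header must start with 'individual,population'")
  acols <- names(df)[-(1:2)]
  if (length(acols) %% 2L != 0L) stop("odd number of allele columns")
  pre1 <- sub("\\.1$", "", acols[seq(1, length(acols), 2)])
  pre2 <- sub("\\.2$", "", acols[seq(2, length(acols), 2)])
  if (!identical(pre1, pre2) ||
      !all(grepl("\\.1$", acols[seq(1, length(acols), 2)])) ||
      !all(grepl("\\.2$", acols[seq(2, length(acols), 2)])))
    stop("allele columns must come in '<locus>.1','<locus>.2' pairs")
  L <- length(pre1); n <- nrow(df)
  arr <- array(NA_integer_, dim = c(n, L, 2L))
  for (l in seq_len(L)) {
    for (s in 1:2) {
      v <- df[[acols[2L * (l - 1L) + s]]]
      v <- suppressWarnings(as.integer(as.character(v)))
      v[!is.na(v) & v == 0L] <- NA_integer_
      arr[, l, s] <- v
    }
  }
  if (is.null(loci)) loci <- locus_meta(pre1)
  genotype_matrix(arr, df[[1]], df[[2]], loci)
}

#' Write the two-columns-per-locus CSV genotype table
#'
#' @param matrix A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_csv_genotypes <- function(matrix, path) {
  n <- n_ind(matrix); L <- n_loci(matrix)
  out <- data.frame(individual = matrix$individuals,
                    population = matrix$populations,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in seq_len(L)) {
    out[[paste0(matrix$loci$name[l], ".1")]] <- matrix$alleles[, l, 1]
    out[[paste0(matrix$loci$name[l], ".2")]] <- matrix$alleles[, l, 2]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "0")
  invisible(path)
}

#' Missing-data summary
#'
#' Percent missing calls per population, per locus and overall:
#' `%NA = 100 * missing calls / total calls` within each stratum.
#'
#' @param matrix A [genotype_matrix()].
#' @return A list with components `per_population`, `per_locus` (named numeric
#'   vectors, percent) and `overall`.
#' @export
missing_summary <- function(matrix) {
  miss <- is_missing_call(matrix)
  per_pop <- vapply(pop_levels(matrix), function(p)
    100 * mean(miss[matrix$populations == p, , drop = FALSE]), numeric(1))
  per_locus <- 100 * colMeans(miss)
  names(per_locus) <- matrix$loci$name
  if (any(per_locus >= 100))
    warning("locus with 100% missing data: ",
            paste(names(per_locus)[per_locus >= 100], collapse = ", "))
  list(per_population = per_pop, per_locus = per_locus,
       overall = 100 * mean(miss))
}

#' Read / write a labeled square distance matrix (TSV)
#'
#' The format is a tab-separated table with row and column labels; the matrix
#' must be square and symmetric (within floating tolerance).
#'
#' @param path TSV path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching labels")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  m
}

#' @rdname read_distance_tsv
#' @param m A symmetric labeled matrix.
#' @export
write_distance_tsv <- function(m, path) {
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
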