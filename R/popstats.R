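#' Per-locus allele frequencies for one population
#'
#' Frequencies are computed over non-missing calls only. A locus with zero
#' scored calls in the population is excluded with a warning.
#'
#' @param matrix A [genotype_matrix()].
#' @param population Population label.
#' @return A list with `freq` (list of named per-locus frequency vectors),
#'   `counts` (allele counts) and `n_scored` (scored individuals per locus).
#' @export
allele_frequencies <- function(matrix, population) {
  sub <- pop_subset(matrix, population)
  freq <- list(); counts <- list(); n_scored <- integer()
  for (l in seq_len(n_loci(sub))) {
    a <- c(sub$alleles[, l, 1], sub$alleles[, l, 2])
    a <- a[!is.na(a)]
    nm <- sub$loci$name[l]
    if (length(a) == 0L) {
      warning("locus ", nm, " has no scored calls in ", population,
              "; excluded")
      next
    }
    tab <- table(a)
    counts[[nm]] <- stats::setNames(as.integer(tab), names(tab))
    freq[[nm]] <- counts[[nm]] / sum(counts[[nm]])
    n_scored[nm] <- length(a) / 2
  }
  list(freq = freq, counts = counts, n_scored = n_scored)
}

#' Mean allelic richness and private alleles per population
#'
#' `Na` is the number of distinct alleles per locus; `Np` counts alleles
#' observed in exactly one population. Means are over loci with standard
#' errors `sd / sqrt(n_loci)`.
#'
#' @param matrix A [genotype_matrix()] with at least two populations.
#' @return A data.frame with one row per population: `Na_mean`, `Na_se`,
#'   `Np_mean`, `Np_se`.
#' @export
allelic_richness_and_private <- function(matrix) {
  pops <- pop_levels(matrix)
  if (length(pops) < 2L)
    stop("private alleles require at least two populations")
  L <- n_loci(matrix)
  # presence[[l]] : alleles x pops logical
  observed <- lapply(seq_len(L), function(l) {
    lapply(pops, function(p) {
      sub <- matrix$alleles[matrix$populations == p, l, , drop = FALSE]
      unique(as.integer(sub[!is.na(sub)]))
    })
  })
  rows <- lapply(seq_along(pops), function(pi) {
    na <- vapply(seq_len(L), function(l) length(observed[[l]][[pi]]),
                 numeric(1))
    np <- vapply(seq_len(L), function(l) {
      mine <- observed[[l]][[pi]]
      others <- unique(unlist(observed[[l]][-pi]))
      sum(!mine %in% others)
    }, numeric(1))
    data.frame(population = pops[pi],
               Na_mean = mean(na), Na_se = stats::sd(na) / sqrt(L),
               Np_mean = mean(np), Np_se = stats::sd(np) / sqrt(L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of heterozygous genotypes among scored calls,
#' averaged over loci. `He` is averaged over loci in both the biased
#' (`1 - sum(p^2)`) and Nei-unbiased (`2n / (2n - 1)` corrected) forms.
#'
#' @inheritParams allele_frequencies
#' @return A list with `Ho`, `He_biased`, `He_unbiased` and a `per_locus`
#'   data.frame.
#' @export
heterozygosity <- function(matrix, population) {
  sub <- pop_subset(matrix, population)
  af <- suppressWarnings(allele_frequencies(matrix, population))
  rows <- lapply(names(af$freq), function(nm) {
    l <- match(nm, sub$loci$name)
    a1 <- sub$alleles[, l, 1]; a2 <- sub$alleles[, l, 2]
    ok <- !is.na(a1)
    ho <- mean(a1[ok] != a2[ok])
    p <- af$freq[[nm]]
    he <- 1 - sum(p^2)
    n <- af$n_scored[[nm]]
    data.frame(locus = nm, n = n, Ho = ho, He_biased = he,
               He_unbiased = he * 2 * n / (2 * n - 1),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  list(Ho = mean(per_locus$Ho), He_biased = mean(per_locus$He_biased),
       He_unbiased = mean(per_locus$He_unbiased), per_locus = per_locus)
}

# internal: Weir-Cockerham within-population variance components for one
# locus in one population. Returns summed b (between individuals) and c
# (within individuals) components over alleles; f = 1 - sum(c)/sum(b + c).
wc_fis_components <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2L) return(c(b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(c(b = 0, c = 0))
  bsum <- 0; csum <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))  # heterozygous for allele al
    b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    bsum <- bsum + b
    csum <- csum + hbar / 2
  }
  c(b = bsum, c = csum)
}

#' Weir-Cockerham inbreeding coefficient with bootstrap CI
#'
#' Multilocus within-population `f` from Weir-Cockerham variance components
#' (between-individual and within-individual components summed over alleles
#' and loci): `f = 1 - sum(c) / sum(b + c)`. Negative values indicate
#' heterozygote excess. The 95% confidence interval is a percentile
#' bootstrap over loci.
#'
#' @inheritParams allele_frequencies
#' @param n_boot Bootstrap replicates (over loci).
#' @param seed Integer RNG seed.
#' @return A list with `fis`, `ci` (length-2, `NA` when fewer than 2
#'   polymorphic loci), and `per_locus` component sums. `fis` is `NA` for a
#'   monomorphic population.
#' @export
fis <- function(matrix, population, n_boot = 1000L, seed = 1L) {
  sub <- pop_subset(matrix, population)
  comp <- t(vapply(seq_len(n_loci(sub)), function(l)
    wc_fis_components(sub$alleles[, l, 1], sub$alleles[, l, 2]),
    numeric(2)))
  rownames(comp) <- sub$loci$name
  tot <- colSums(comp)
  f <- if (tot["b"] + tot["c"] <= 0) NA_real_
       else unname(1 - tot["c"] / (tot["b"] + tot["c"]))
  poly <- which(rowSums(comp) > 0)
  ci <- c(NA_real_, NA_real_)
  if (length(poly) >= 2L && n_boot > 0L) {
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      ix <- sample(seq_len(nrow(comp)), replace = TRUE)
      s <- colSums(comp[ix, , drop = FALSE])
      if (s["b"] + s["c"] <= 0) NA_real_ else 1 - s["c"] / (s["b"] + s["c"])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  list(fis = f, ci = ci, per_locus = comp, n_boot = n_boot)
}

# internal: log Levene probability of a genotype-count array given allele
# counts. geno: k x k upper-triangular count matrix (i <= j used), a: allele
# counts, n: individuals.
levene_log_prob <- function(geno, a, n) {
  H <- sum(geno[upper.tri(geno)])
  lfactorial(n) + sum(lfactorial(a)) + H * log(2) - lfactorial(2 * n) -
    sum(lfactorial(geno[upper.tri(geno, diag = TRUE)]))
}

# internal: enumerate all genotype-count arrays with allele-count margins a.
# Calls fn(geno) for each; stops with an error if more than max_tables.
enumerate_genotype_arrays <- function(a, fn, max_tables = 2e5) {
  k <- length(a)
  geno <- matrix(0L, k, k)
  count <- 0L
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  recurse <- function(idx, rem) {
    if (idx > nrow(pairs)) {
      if (all(rem == 0L)) {
        count <<- count + 1L
        if (count > max_tables) stop("enumeration_overflow", call. = FALSE)
        fn(geno)
      }
      return(invisible())
    }
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    last_in_row <- (j == k)
    if (i == j) {
      if (i == k) {  # final cell: forced
        if (rem[k] %% 2L == 0L) {
          geno[k, k] <<- rem[k] %/% 2L
          rem2 <- rem; rem2[k] <- 0L
          recurse(idx + 1L, rem2)
          geno[k, k] <<- 0L
        }
        return(invisible())
      }
      for (v in 0:(rem[i] %/% 2L)) {
        geno[i, i] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - 2L * v
        recurse(idx + 1L, rem2)
      }
      geno[i, i] <<- 0L
    } else if (last_in_row) {  # n_ik forced to absorb remainder of row i
      v <- rem[i]
      if (v <= rem[k]) {
        geno[i, k] <<- v
        rem2 <- rem; rem2[i] <- 0L; rem2[k] <- rem2[k] - v
        recurse(idx + 1L, rem2)
        geno[i, k] <<- 0L
      }
    } else {
      for (v in 0:min(rem[i], rem[j])) {
        geno[i, j] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v
        recurse(idx + 1L, rem2)
      }
      geno[i, j] <<- 0L
    }
    invisible()
  }
  recurse(1L, as.integer(a))
  count
}

#' Hardy-Weinberg exact test (Levene distribution)
#'
#' Conditions on the observed allele counts and evaluates the exact
#' distribution of genotype arrays. For small arrays all tables are
#' enumerated; otherwise a Monte-Carlo version permutes allele copies. The
#' two-sided p sums the probability of arrays no more probable than the
#' observed one; the one-sided heterozygote-deficit p uses the number of
#' heterozygotes as statistic (small p = fewer heterozygotes than expected).
#'
#' @inheritParams allele_frequencies
#' @param locus Locus name or index.
#' @param mode `"auto"` (enumerate when feasible), `"enumerate"` or `"mc"`.
#' @param max_tables Enumeration bound before falling back to Monte Carlo.
#' @param n_mc Monte-Carlo permutations.
#' @param seed Integer RNG seed (Monte Carlo only).
#' @return A list with `p_two_sided`, `p_deficit`, `method`, `n_het_obs`.
#'   A monomorphic locus returns p = 1 with a warning.
#' @export
hwe_exact <- function(matrix, population, locus,
                      mode = c("auto", "enumerate", "mc"),
                      max_tables = 2e5, n_mc = 2000L, seed = 1L) {
  mode <- match.arg(mode)
  sub <- pop_subset(matrix, population)
  if (is.character(locus)) locus <- match(locus, sub$loci$name)
  a1 <- sub$alleles[, locus, 1]; a2 <- sub$alleles[, locus, 2]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) {
    warning("monomorphic locus: p = 1 by convention")
    return(list(p_two_sided = 1, p_deficit = 1, method = "degenerate",
                n_het_obs = 0L))
  }
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  geno_obs <- matrix(0L, k, k)
  for (g in seq_len(n)) {
    i <- min(i1[g], i2[g]); j <- max(i1[g], i2[g])
    geno_obs[i, j] <- geno_obs[i, j] + 1L
  }
  acount <- tabulate(c(i1, i2), nbins = k)
  lp_obs <- levene_log_prob(geno_obs, acount, n)
  h_obs <- sum(geno_obs[upper.tri(geno_obs)])
  tol <- 1e-9

  run_enum <- function() {
    p_two <- 0; p_def <- 0; total <- 0
    enumerate_genotype_arrays(acount, function(geno) {
      lp <- levene_log_prob(geno, acount, n)
      pr <- exp(lp)
      total <<- total + pr
      if (lp <= lp_obs + tol) p_two <<- p_two + pr
      if (sum(geno[upper.tri(geno)]) <= h_obs) p_def <<- p_def + pr
    }, max_tables = max_tables)
    list(p_two_sided = min(1, p_two / total),
         p_deficit = min(1, p_def / total),
         method = "enumerate", n_het_obs = h_obs)
  }
  run_mc <- function() {
    set.seed(seed)
    pool <- c(i1, i2)
    hit_two <- 0L; hit_def <- 0L
    for (r in seq_len(n_mc)) {
      perm <- pool[sample.int(2L * n)]
      x <- perm[seq_len(n)]; y <- perm[n + seq_len(n)]
      geno <- matrix(0L, k, k)
      for (g in seq_len(n)) {
        i <- min(x[g], y[g]); j <- max(x[g], y[g])
        geno[i, j] <- geno[i, j] + 1L
      }
      lp <- levene_log_prob(geno, acount, n)
      if (lp <= lp_obs + tol) hit_two <- hit_two + 1L
      if (sum(geno[upper.tri(geno)]) <= h_obs) hit_def <- hit_def + 1L
    }
    list(p_two_sided = (1 + hit_two) / (n_mc + 1),
         p_deficit = (1 + hit_def) / (n_mc + 1),
         method = "mc", n_het_obs = h_obs)
  }
  if (mode == "mc") return(run_mc())
  res <- tryCatch(run_enum(), error = function(e) {
    if (conditionMessage(e) == "enumeration_overflow" && mode == "auto")
      NULL
    else if (conditionMessage(e) == "enumeration_overflow")
      stop("enumeration exceeds max_tables; use mode = 'mc'")
    else stop(e)
  })
  if (is.null(res)) res <- run_mc()
  res
}

#' Per-population HWE tests across loci with a global combination
#'
#' Runs [hwe_exact()] at every polymorphic locus and combines per-locus
#' p-values with Fisher's method (global two-sided and heterozygote-deficit
#' p). Benjamini-Hochberg adjusted per-locus p-values are also reported.
#'
#' @inheritParams hwe_exact
#' @return A list with `per_locus` (data.frame) and `global_p`,
#'   `global_p_deficit`.
#' @export
hwe_population <- function(matrix, population, mode = "auto",
                           n_mc = 2000L, seed = 1L) {
  sub <- pop_subset(matrix, population)
  rows <- lapply(seq_len(n_loci(sub)), function(l) {
    r <- suppressWarnings(hwe_exact(matrix, population, l, mode = mode,
                                    n_mc = n_mc, seed = seed + l))
    data.frame(locus = sub$loci$name[l], p = r$p_two_sided,
               p_deficit = r$p_deficit, method = r$method,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  per_locus$p_adj <- stats::p.adjust(per_locus$p, method = "BH")
  informative <- per_locus$method != "degenerate"
  fisher <- function(p) {
    if (!any(informative)) return(NA_real_)
    x <- -2 * sum(log(pmax(p[informative], 1e-300)))
    stats::pchisq(x, df = 2 * sum(informative), lower.tail = FALSE)
  }
  list(per_locus = per_locus, global_p = fisher(per_locus$p),
       global_p_deficit = fisher(per_locus$p_deficit))
}

#' Screen a locus for null alleles via homozygote excess
#'
#' Flags a locus when observed homozygosity significantly exceeds the
#' Hardy-Weinberg expectation (one-sided heterozygote-deficit exact/MC test)
#' and reports the Chakraborty-style null-allele frequency estimate
#' `r = (He - Ho) / (He + Ho)`.
#'
#' @inheritParams hwe_exact
#' @param alpha Significance level for the flag.
#' @return A list with `flagged`, `p_deficit`, `r_estimate`, `Ho`, `He`.
#' @export
null_allele_screen <- function(matrix, population, locus, alpha = 0.05,
                               mode = "auto", n_mc = 2000L, seed = 1L) {
  sub <- pop_subset(matrix, population)
  if (is.character(locus)) locus <- match(locus, sub$loci$name)
  het <- heterozygosity(matrix, population)
  nm <- sub$loci$name[locus]
  row <- het$per_locus[het$per_locus$locus == nm, ]
  ho <- row$Ho; he <- row$He_biased
  r <- if (he + ho > 0) (he - ho) / (he + ho) else 0
  test <- suppressWarnings(hwe_exact(matrix, population, locus, mode = mode,
                                     n_mc = n_mc, seed = seed))
  list(flagged = is.finite(test$p_deficit) && test$p_deficit < alpha,
       p_deficit = test$p_deficit, r_estimate = r, Ho = ho, He = he)
}

#' Summary statistics table for every population
#'
#' Assembles the usual per-population summary: sample size, allelic richness
#' and private alleles, heterozygosities, Weir-Cockerham FIS with bootstrap
#' CI, global HWE p and percent missing data.
#'
#' @param matrix A [genotype_matrix()].
#' @param n_boot Bootstrap replicates for the FIS interval.
#' @param seed Integer RNG seed.
#' @param hwe If `TRUE` (default), include the global HWE p-value.
#' @return A data.frame with one row per population.
#' @export
pop_stats_table <- function(matrix, n_boot = 1000L, seed = 1L, hwe = TRUE) {
  rich <- if (length(pop_levels(matrix)) >= 2L)
    allelic_richness_and_private(matrix) else NULL
  miss <- missing_summary(matrix)
  rows <- lapply(pop_levels(matrix), function(p) {
    het <- heterozygosity(matrix, p)
    f <- fis(matrix, p, n_boot = n_boot, seed = seed)
    out <- data.frame(population = p,
                      N = sum(matrix$populations == p),
                      He = het$He_biased, Ho = het$Ho, FIS = f$fis,
                      FIS_lo = f$ci[1], FIS_hi = f$ci[2],
                      pct_missing = unname(miss$per_population[p]),
                      stringsAsFactors = FALSE)
    if (hwe)
      out$hwe_global_p <- hwe_population(matrix, p, seed = seed)$global_p
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(rich)) out <- merge(out, rich, by = "population", sort = FALSE)
  out
}
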