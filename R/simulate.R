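#' Configuration for the multi-deme clonal microsatellite simulator
#'
#' Defaults emulate the sampled coral populations the package targets: nine
#' demes with the observed sample sizes, six microsatellite loci with di-,
#' tri- and tetranucleotide motifs, moderate differentiation, a ~10% clonal
#' fraction (the observed 196 distinct genotypes among 217 colonies) and the
#' observed ~24% missing-data rate.
#'
#' @param n_demes Number of demes.
#' @param deme_sizes Integer vector of individuals per deme (recycled), all
#'   >= 2.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Number of distinct allele sizes per locus.
#' @param ancestral_freq_concentration Dirichlet concentration for the
#'   ancestral allele frequencies (1 = uniform on the simplex).
#' @param target_F Differentiation parameter in `[0, 1)`. Island mode draws
#'   deme frequencies from `Dirichlet(ancestral * (1 - F) / F)` independently,
#'   so the expected Weir-Cockerham FST among demes is approximately
#'   `target_F`; stepping-stone mode applies the same Dirichlet drift per
#'   adjacent step along a line.
#' @param spatial_mode `"island"` or `"stepping_stone"`.
#' @param clonality_c Fraction of individuals per deme that are clonal copies
#'   of a founder.
#' @param somatic_step_prob Per-locus probability that a clonal copy mutates
#'   one allele by one motif step (stepwise mutation model).
#' @param missing_rate Per-call missing probability applied after corruption.
#' @param null_allele_freq Frequency of a non-amplifying (null) allele at
#'   `null_locus`; heterozygous carriers appear homozygous for the visible
#'   allele, null homozygotes become missing.
#' @param null_locus Index of the locus carrying the null allele.
#' @param motif_lengths Motif lengths per locus (recycled).
#' @param seed Integer RNG seed; identical configs give identical datasets.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_demes = 9L,
                       deme_sizes = c(13L, 14L, 11L, 22L, 18L, 19L, 13L, 51L, 56L),
                       n_loci = 6L,
                       alleles_per_locus = 8L,
                       ancestral_freq_concentration = 1,
                       target_F = 0.1,
                       spatial_mode = c("island", "stepping_stone"),
                       clonality_c = 0.1,
                       somatic_step_prob = 0,
                       missing_rate = 0.24,
                       null_allele_freq = 0,
                       null_locus = 1L,
                       motif_lengths = c(4L, 2L, 4L, 3L, 2L, 3L),
                       seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  cfg <- list(n_demes = as.integer(n_demes),
              deme_sizes = as.integer(rep_len(deme_sizes, n_demes)),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              ancestral_freq_concentration = ancestral_freq_concentration,
              target_F = target_F, spatial_mode = spatial_mode,
              clonality_c = clonality_c,
              somatic_step_prob = somatic_step_prob,
              missing_rate = missing_rate,
              null_allele_freq = null_allele_freq,
              null_locus = as.integer(null_locus),
              motif_lengths = as.integer(rep_len(motif_lengths, n_loci)),
              seed = as.integer(seed))
  stopifnot(cfg$n_demes >= 1L, all(cfg$deme_sizes >= 2L), cfg$n_loci >= 1L,
            cfg$alleles_per_locus >= 1L,
            cfg$ancestral_freq_concentration > 0,
            cfg$target_F >= 0, cfg$target_F < 1,
            cfg$clonality_c >= 0, cfg$clonality_c <= 1,
            cfg$somatic_step_prob >= 0, cfg$somatic_step_prob <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$null_allele_freq >= 0, cfg$null_allele_freq <= 1,
            cfg$null_locus >= 1L, cfg$null_locus <= cfg$n_loci)
  class(cfg) <- "sim_config"
  cfg
}

# internal Dirichlet sampler (rows = draws)
rdirichlet <- function(n, shape) {
  g <- matrix(stats::rgamma(n * length(shape), shape = rep(shape, each = n)),
              nrow = n)
  s <- rowSums(g)
  zero <- s <= 0
  if (any(zero)) {  # numerically degenerate draw: fall back to the mean
    g[zero, ] <- rep(shape / sum(shape), each = sum(zero))
    s[zero] <- 1
  }
  g / rowSums(g)
}

# allele size ladder for locus l: 100 + motif * (0 .. A-1), offset by locus
sim_allele_sizes <- function(config, l) {
  100L + 10L * l + config$motif_lengths[l] *
    (0:(config$alleles_per_locus - 1L))
}

.sample_freqs <- function(config) {
  A <- config$alleles_per_locus; d <- config$n_demes
  ancestral <- vector("list", config$n_loci)
  freq <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    p_bar <- as.numeric(rdirichlet(1, rep(config$ancestral_freq_concentration, A)))
    Fst <- config$target_F
    if (Fst == 0) {
      m <- matrix(rep(p_bar, each = d), nrow = d)
    } else if (config$spatial_mode == "island") {
      m <- rdirichlet(d, p_bar * (1 - Fst) / Fst)
    } else {  # stepping stone: Dirichlet drift per adjacent step
      m <- matrix(0, d, A)
      prev <- p_bar
      for (k in seq_len(d)) {
        prev <- as.numeric(rdirichlet(1, prev * (1 - Fst) / Fst))
        m[k, ] <- prev
      }
    }
    colnames(m) <- sim_allele_sizes(config, l)
    names(p_bar) <- colnames(m)
    ancestral[[l]] <- p_bar
    freq[[l]] <- m
  }
  list(ancestral = ancestral, freq = freq)
}

#' Draw per-deme per-locus allele frequencies under the F-model
#'
#' Ancestral frequencies are Dirichlet(`ancestral_freq_concentration`); deme
#' frequencies are Dirichlet(`ancestral * (1 - F) / F`) drawn independently
#' per deme (island) or chained along a line (stepping stone). `target_F = 0`
#' returns the ancestral frequencies for every deme exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `ancestral` (list of per-locus frequency vectors named
#'   by allele size) and `freq` (list of demes x alleles frequency matrices).
#' @export
sample_deme_frequencies <- function(config) {
  set.seed(config$seed)
  .sample_freqs(config)
}

#' Simulate a multi-deme diploid microsatellite dataset with known truth
#'
#' Within each deme, `ceiling((1 - c) * n)` founders are drawn as
#' Hardy-Weinberg genotypes from the deme allele frequencies; the remaining
#' individuals copy a uniformly chosen founder of the same deme (clonal
#' ramets of a genet), after which each locus of a copy mutates by one motif
#' step with probability `somatic_step_prob`. A designated locus can carry a
#' null allele: heterozygous carriers appear homozygous for the visible
#' allele and null homozygotes become missing. Finally each call is set
#' missing independently at `missing_rate`. Truth is recorded before
#' corruption.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_dataset` with `genotypes` (a
#'   [genotype_matrix()]), `truth` (a data.frame with `individual`, `deme`,
#'   `is_clone`, `parent`) and `frequencies` (the output of the frequency
#'   sampler), plus `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  fr <- .sample_freqs(config)
  L <- config$n_loci
  n_total <- sum(config$deme_sizes)
  arr <- array(NA_integer_, dim = c(n_total, L, 2L))
  inds <- character(n_total); pops <- character(n_total)
  is_clone <- logical(n_total); parent <- rep(NA_character_, n_total)
  row <- 0L
  NULL_ALLELE <- -1L
  for (d in seq_len(config$n_demes)) {
    n <- config$deme_sizes[d]
    nf <- max(1L, ceiling((1 - config$clonality_c) * n))
    nf <- min(nf, n)
    deme_lab <- paste0("deme_", d)
    ids <- sprintf("d%02d_i%03d", d, seq_len(n))
    true_geno <- array(NA_integer_, dim = c(n, L, 2L))
    for (f in seq_len(nf)) {
      for (l in seq_len(L)) {
        sizes <- as.integer(colnames(fr$freq[[l]]))
        p <- fr$freq[[l]][d, ]
        g <- sizes[sample.int(length(sizes), 2L, replace = TRUE, prob = p)]
        if (l == config$null_locus && config$null_allele_freq > 0) {
          nul <- stats::runif(2) < config$null_allele_freq
          g[nul] <- NULL_ALLELE
        }
        true_geno[f, l, ] <- g
      }
    }
    if (n > nf) {
      for (i in (nf + 1L):n) {
        par <- sample.int(nf, 1L)
        true_geno[i, , ] <- true_geno[par, , ]
        is_clone[row + i] <- TRUE
        parent[row + i] <- ids[par]
        if (config$somatic_step_prob > 0) {
          for (l in seq_len(L)) {
            if (stats::runif(1) < config$somatic_step_prob) {
              slot <- sample.int(2L, 1L)
              a <- true_geno[i, l, slot]
              if (a != NULL_ALLELE) {
                step <- config$motif_lengths[l] *
                  (if (stats::runif(1) < 0.5) -1L else 1L)
                true_geno[i, l, slot] <- a + step
              }
            }
          }
        }
      }
    }
    # visible genotypes: null corruption then random missingness
    vis <- true_geno
    for (i in seq_len(n)) {
      for (l in seq_len(L)) {
        g <- vis[i, l, ]
        if (any(g == NULL_ALLELE, na.rm = TRUE)) {
          visible <- g[g != NULL_ALLELE]
          if (length(visible) == 0L) g <- c(NA_integer_, NA_integer_)
          else g <- c(visible[1], visible[1])
          vis[i, l, ] <- g
        }
        if (config$missing_rate > 0 && stats::runif(1) < config$missing_rate)
          vis[i, l, ] <- NA_integer_
      }
    }
    arr[row + seq_len(n), , ] <- vis
    inds[row + seq_len(n)] <- ids
    pops[row + seq_len(n)] <- deme_lab
    row <- row + n
  }
  loci <- locus_meta(sprintf("loc%02d", seq_len(L)),
                     motif_length = config$motif_lengths)
  gm <- genotype_matrix(arr, inds, pops, loci)
  truth <- data.frame(individual = inds, deme = pops, is_clone = is_clone,
                      parent = parent, stringsAsFactors = FALSE)
  structure(list(genotypes = gm, truth = truth, frequencies = fr,
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", n_ind(x$genotypes), "individuals,",
      x$config$n_demes, "demes,", x$config$n_loci, "loci\n")
  cat(sprintf("clonal copies: %d (configured c = %.2f)\n",
              sum(x$truth$is_clone), x$config$clonality_c))
  invisible(x)
}
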