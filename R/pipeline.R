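#' Default parameters for the full analysis pipeline
#'
#' Desk-scale defaults: they keep a full dual-dataset run on a laptop-sized
#' dataset in the minutes range while remaining configurable up to
#' publication-scale settings (e.g. longer MCMC chains, more permutations).
#'
#' @param mlg_policy,min_loci MLG matching policy (see [assign_mlg()]).
#' @param mll_threshold Stepwise-mutation merge threshold (steps).
#' @param n_rand Randomizations for the sexual-reproduction test.
#' @param n_perm FST permutations per population pair.
#' @param k_range,n_reps,burnin,iters Admixture scan schedule.
#' @param locprior Use the location prior in the admixture runs.
#' @param assignment_threshold Membership threshold for cluster assignment.
#' @param n_mantel Mantel permutations for the IBD stage.
#' @param run_clustering,run_hwe Stage toggles.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(mlg_policy = "observed", min_loci = 4L,
                            mll_threshold = 4, n_rand = 999L,
                            n_perm = 1000L, k_range = 1:6, n_reps = 3L,
                            burnin = 2000L, iters = 10000L,
                            locprior = FALSE, assignment_threshold = 0.75,
                            n_mantel = 999L, run_clustering = TRUE,
                            run_hwe = TRUE, seed = 1L) {
  structure(list(mlg_policy = mlg_policy, min_loci = min_loci,
                 mll_threshold = mll_threshold, n_rand = n_rand,
                 n_perm = n_perm, k_range = k_range, n_reps = n_reps,
                 burnin = burnin, iters = iters, locprior = locprior,
                 assignment_threshold = assignment_threshold,
                 n_mantel = n_mantel, run_clustering = run_clustering,
                 run_hwe = run_hwe, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full clonal population-genetics pipeline
#'
#' Orchestrates io, clonality, per-population statistics, pairwise FST,
#' admixture clustering with delta-K selection, DAPC/MSN and (when a
#' distance matrix is supplied) isolation by distance — on the
#' per-individual dataset and on the per-genotype (clone-censored) dataset.
#' Clustering runs on the per-genotype dataset by default, since keeping one
#' clonemate per clone avoids biased estimates in clonal populations.
#'
#' @param input A [genotype_matrix()] or a path to a genepop/CSV file.
#' @param config A [pipeline_config()].
#' @param dist_matrix Optional labeled geographic-distance matrix (km).
#' @param dataset_modes Which datasets to analyze.
#' @param out_dir Optional directory to write TSV/JSON outputs into.
#' @return A list of class `pipeline_report` with one entry per dataset
#'   mode (each holding `clonal_stats`, `pop_stats`, `fst`, `delta_k`, `Q`,
#'   `cluster_assignment`, `dapc`, `msn`, `ibd`, `regression`) plus `log`
#'   (stage timings and seeds) and `partition`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         dist_matrix = NULL,
                         dataset_modes = c("per_individual", "per_genotype"),
                         out_dir = NULL) {
  dataset_modes <- match.arg(dataset_modes, several.ok = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, seconds = proc.time()[["elapsed"]] - t0,
      seed = config$seed, stringsAsFactors = FALSE)
    res
  }
  gm <- stage("io", {
    if (inherits(input, "genotype_matrix")) input
    else if (grepl("\\.csv$", input)) read_csv_genotypes(input)
    else read_genepop(input)
  })
  partition <- stage("clonality", assign_mlg(gm, config$mlg_policy,
                                             config$min_loci))
  datasets <- list()
  if ("per_individual" %in% dataset_modes) datasets$per_individual <- gm
  if ("per_genotype" %in% dataset_modes)
    datasets$per_genotype <- stage("clone_censor",
                                   to_per_genotype(gm, partition))
  report <- list(partition = partition)
  for (mode in names(datasets)) {
    dat <- datasets[[mode]]
    out <- list(dataset_mode = mode, n = n_ind(dat))
    out$clonal_stats <- stage(paste0(mode, ":clonal_stats"), {
      part <- assign_mlg(dat, config$mlg_policy, config$min_loci)
      clonal_stats_table(dat, part)
    })
    out$sexual_test <- stage(paste0(mode, ":sexual_test"), {
      ps <- vapply(pop_levels(dat), function(p) {
        if (sum(dat$populations == p) < 2L) return(NA_real_)
        sexual_null_test(dat, p, n_rand = config$n_rand,
                         seed = config$seed + 11L,
                         missing_policy = config$mlg_policy,
                         min_loci = config$min_loci)$p_value
      }, numeric(1))
      data.frame(population = pop_levels(dat), p_value = ps,
                 stringsAsFactors = FALSE)
    })
    out$regression <- stage(paste0(mode, ":regression"), {
      if (nrow(out$clonal_stats) >= 3L &&
          stats::var(out$clonal_stats$E_D) > 0)
        diversity_evenness_regression(out$clonal_stats)
      else NULL
    })
    out$pop_stats <- stage(paste0(mode, ":pop_stats"),
      pop_stats_table(dat, n_boot = 200L, seed = config$seed + 23L,
                      hwe = config$run_hwe))
    if (length(pop_levels(dat)) >= 2L) {
      out$fst <- stage(paste0(mode, ":fst"),
        fst_matrix(dat, n_perm = config$n_perm, seed = config$seed + 31L,
                   dataset_mode = mode))
      out$msn <- stage(paste0(mode, ":msn"),
        minimum_spanning_network(nei_distance_matrix(dat)))
    }
    if (config$run_clustering && (mode == "per_genotype" ||
                                  !"per_genotype" %in% names(datasets))) {
      runs <- stage(paste0(mode, ":admixture"),
        admixture_scan(dat, k_range = config$k_range,
                       n_reps = config$n_reps, seed = config$seed + 41L,
                       burnin = config$burnin, iters = config$iters,
                       locprior = config$locprior))
      out$delta_k <- stage(paste0(mode, ":delta_k"), evanno_delta_k(runs))
      bestK <- attr(out$delta_k, "optimal_K")
      best_runs <- align_replicates(
        runs[vapply(runs, `[[`, integer(1), "K") == bestK])
      Qs <- lapply(best_runs, `[[`, "Q")
      out$Q <- Reduce(`+`, Qs) / length(Qs)
      out$cluster_assignment <-
        assign_clusters(out$Q, config$assignment_threshold)
    }
    if (length(pop_levels(dat)) >= 3L) {
      out$dapc <- stage(paste0(mode, ":dapc"),
        dapc(build_count_table(dat), dat$populations))
    }
    if (!is.null(dist_matrix) && !is.null(out$fst) &&
        length(pop_levels(dat)) >= 4L) {
      out$ibd <- stage(paste0(mode, ":ibd"),
        ibd_analysis(out$fst, dist_matrix, n_perm = config$n_mantel,
                     seed = config$seed + 53L))
    }
    report[[mode]] <- out
  }
  report$log <- do.call(rbind, log)
  report$config <- config
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  modes <- intersect(c("per_individual", "per_genotype"), names(x))
  cat("pipeline_report:", paste(modes, collapse = " + "), "\n")
  for (m in modes)
    cat(sprintf("  %s: n=%d, stages: %s\n", m, x[[m]]$n,
                paste(setdiff(names(x[[m]]), c("dataset_mode", "n")),
                      collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits per-mode TSVs (summary-table-shaped clonal statistics, population
#' statistics, FST matrices, Q matrices, delta-K table) and a JSON stage
#' log.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in intersect(c("per_individual", "per_genotype"), names(report))) {
    out <- report[[m]]
    wtsv(out$clonal_stats, paste0(m, "_clonal_stats.tsv"))
    wtsv(out$pop_stats, paste0(m, "_pop_stats.tsv"))
    if (!is.null(out$fst))
      write_distance_tsv(out$fst$theta, file.path(out_dir,
                                                  paste0(m, "_fst.tsv")))
    if (!is.null(out$Q))
      wtsv(data.frame(individual = rownames(out$Q), out$Q,
                      check.names = FALSE), paste0(m, "_Q.tsv"))
    if (!is.null(out$delta_k))
      wtsv(as.data.frame(out$delta_k), paste0(m, "_delta_k.tsv"))
    if (!is.null(out$msn)) wtsv(out$msn, paste0(m, "_msn.tsv"))
  }
  jsonlite::write_json(
    list(log = report$log,
         config = unclass(report$config)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Deterministic miniature datasets for tests and examples
#'
#' Four simulator profiles with fixed configurations: `clonal` (two demes,
#' half the individuals clonal copies), `panmictic` (one undifferentiated
#' deme, fully sexual), `three_demes` (three demes at moderate
#' differentiation, used for cluster-number selection), `stepping_stone`
#' (eight demes in a line, used for isolation by distance).
#'
#' @param profile One of `"clonal"`, `"panmictic"`, `"three_demes"`,
#'   `"stepping_stone"`.
#' @param seed Integer seed (profiles regenerate identically per seed).
#' @return A `simulated_dataset` (see [simulate_dataset()]).
#' @export
make_fixture <- function(profile = c("clonal", "panmictic", "three_demes",
                                     "stepping_stone"),
                         seed = 101L) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    clonal = sim_config(n_demes = 2L, deme_sizes = 30L, n_loci = 6L,
                        alleles_per_locus = 8L, target_F = 0.1,
                        clonality_c = 0.5, missing_rate = 0, seed = seed),
    panmictic = sim_config(n_demes = 1L, deme_sizes = 60L, n_loci = 6L,
                           alleles_per_locus = 8L, target_F = 0,
                           clonality_c = 0, missing_rate = 0, seed = seed),
    three_demes = sim_config(n_demes = 3L, deme_sizes = 30L, n_loci = 8L,
                             alleles_per_locus = 8L, target_F = 0.2,
                             clonality_c = 0, missing_rate = 0, seed = seed),
    stepping_stone = sim_config(n_demes = 8L, deme_sizes = 20L, n_loci = 8L,
                                alleles_per_locus = 8L, target_F = 0.05,
                                spatial_mode = "stepping_stone",
                                clonality_c = 0, missing_rate = 0,
                                seed = seed))
  simulate_dataset(cfg)
}
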