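#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline. Defaults follow the
#' reference analysis: Pearson correlation similarity, gamma = 0.9,
#' N = 1000 consensus runs, 999 permutations, FDR q = 0.05, 10
#' reproducibility subsets.
#'
#' @param gamma Resolution parameter; ignored when `k_target` is set and
#'   tuning is requested.
#' @param k_target Optional target subtype count; when non-`NULL`,
#'   [tune_gamma()] picks gamma from `gamma_grid`.
#' @param gamma_grid Grid for tuning.
#' @param n_runs Consensus runs.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param alpha Euclidean-exp regularization factor or `"auto"`.
#' @param n_perm Permutations for tests.
#' @param q FDR level.
#' @param n_subsets Reproducibility subsets.
#' @param seed Integer seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(gamma = 0.9, k_target = NULL,
                       gamma_grid = seq(0.5, 1.5, by = 0.05),
                       n_runs = 1000, metric = c("correlation", "euclidean"),
                       alpha = "auto", n_perm = 999, q = 0.05,
                       n_subsets = 10, seed = 1L) {
  metric <- match.arg(metric)
  structure(list(gamma = gamma, k_target = k_target,
                 gamma_grid = gamma_grid, n_runs = n_runs, metric = metric,
                 alpha = alpha, n_perm = n_perm, q = q,
                 n_subsets = n_subsets, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full subtyping pipeline
#'
#' Chains z-scoring against the CN group, similarity construction, consensus
#' Louvain subtyping (with optional gamma tuning to a target subtype count)
#' and, when requested, validation statistics and ROI hallmark analysis.
#' When `out_dir` is given, writes `assignments.tsv` (subject_id, subtype,
#' vote_fraction), `hallmarks.tsv`, and `run_info.txt` with the resolved
#' configuration and diagnostics; reruns with the same cohort, config and
#' seed reproduce the outputs exactly.
#'
#' @param cohort A [cohort()] (or a directory path for [read_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param validate If `TRUE`, also run the similarity permutation test and
#'   the reproducibility statistic.
#' @param hallmarks If `TRUE` and the cohort has an ROI map, run the
#'   hallmark analysis.
#' @return List with `patterns`, `similarity`, `partition`, `gamma`, and
#'   (optionally) `perm_test`, `reproducibility`, `hallmarks`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         validate = FALSE, hallmarks = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"), inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4L)

  patterns <- compute_atrophy(cohort)
  sim <- if (config$metric == "correlation") correlation_similarity(patterns)
         else euclidean_similarity(patterns, alpha = config$alpha)

  if (!is.null(config$k_target)) {
    tuned <- tune_gamma(sim, k_target = config$k_target,
                        gamma_grid = config$gamma_grid,
                        n_runs = config$n_runs, seed = seeds[1])
    gamma <- tuned$gamma
    partition <- tuned$partition
  } else {
    gamma <- config$gamma
    partition <- consensus_vote(sim, gamma = gamma, n_runs = config$n_runs,
                                seed = seeds[1])
  }

  out <- list(patterns = patterns, similarity = sim, partition = partition,
              gamma = gamma, config = config)

  if (validate) {
    out$perm_test <- similarity_permutation_test(
      patterns, gamma = gamma, n_runs = max(5L, config$n_runs %/% 20L),
      n_perm = config$n_perm, seed = seeds[2])
    out$reproducibility <- reproducibility(
      cohort, gamma = gamma, n_runs = max(10L, config$n_runs %/% 10L),
      n_subsets = config$n_subsets, seed = seeds[3],
      metric = config$metric, reference = partition)
  }
  if (hallmarks && !is.null(cohort$roi_map)) {
    ad <- cohort$subjects$group == "AD"
    roi <- roi_means(cohort)
    roi_ad <- roi
    roi_ad$values <- roi$values[ad, , drop = FALSE]
    roi_ad$subject_ids <- roi$subject_ids[ad]
    roi_ad <- normalize_roi_rows(roi_ad, cohort)
    covs <- data.frame(age = cohort$subjects$age[ad],
                       sex = cohort$subjects$sex[ad],
                       education = cohort$subjects$education[ad])
    out$hallmarks <- select_hallmarks(roi_ad, partition, covs,
                                      n_perm = config$n_perm, q = config$q,
                                      seed = seeds[4])
  }

  if (!is.null(out_dir)) write_pipeline_outputs(out, cohort, out_dir)
  out
}

# normalize an roi_table whose rows are a subject subset
normalize_roi_rows <- function(roi, cohort) {
  cortex <- rowMeans(cohort$thickness[roi$subject_ids, cohort$mask,
                                      drop = FALSE])
  roi$values <- roi$values / cortex
  roi$normalized <- TRUE
  roi
}

write_pipeline_outputs <- function(res, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  part <- res$partition
  assign_tab <- data.frame(subject_id = names(part$labels),
                           subtype = part$labels,
                           vote_fraction = part$vote_fraction)
  write.table(assign_tab, file.path(out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$hallmarks))
    write.table(as.data.frame(res$hallmarks),
                file.path(out_dir, "hallmarks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  info <- c(
    sprintf("metric: %s", res$similarity$metric),
    sprintf("gamma: %g", res$gamma),
    sprintf("n_runs: %d", part$n_runs),
    sprintf("seed: %d", res$config$seed),
    sprintf("q_modularity: %.6f", part$q),
    sprintf("n_communities: %d", n_communities(part)),
    sprintf("community_sizes: %s",
            paste(table(part$labels), collapse = "/")),
    sprintf("clipped_negative_fraction: %.4f", part$clipped_fraction),
    sprintf("masked_locations: %d", sum(res$patterns$mask)),
    sprintf("dropped_locations: %s",
            if (length(res$patterns$reference$dropped))
              paste(res$patterns$reference$dropped, collapse = ",")
            else "none"),
    sprintf("mean_vote_fraction: %.4f", mean(part$vote_fraction)))
  if (!is.null(res$perm_test))
    info <- c(info, sprintf("similarity_perm_p: %.4g", res$perm_test$p))
  if (!is.null(res$reproducibility))
    info <- c(info, sprintf("reproducibility_pct: %.2f",
                            100 * res$reproducibility$overall))
  writeLines(info, file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}

#' Compare subtyping methods on one cohort
#'
#' Reruns the subtyping with the graph method (correlation and
#' exponential-Euclidean similarity) and the hierarchical comparators
#' (correlation and Euclidean distance), reporting for each the modularity
#' Q of its partition scored on the shared correlation similarity matrix,
#' the subtype count, and the leave-subset-out reproducibility.
#'
#' @param cohort A [cohort()].
#' @param k Cluster count for the hierarchical methods.
#' @param gamma Resolution for the graph methods and for Q scoring.
#' @param n_runs Consensus runs for the graph methods.
#' @param n_subsets Reproducibility subsets.
#' @param seed Integer seed.
#' @return Data frame: method, metric, n_subtypes, q, reproducibility_pct.
#' @export
compare_methods <- function(cohort, k = 3, gamma = 0.9, n_runs = 100,
                            n_subsets = 10, seed = 1L) {
  patterns <- compute_atrophy(cohort)
  sim_corr <- correlation_similarity(patterns)
  seeds <- derive_seeds(seed, 8L)

  spec <- list(
    list(method = "louvain", metric = "correlation"),
    list(method = "louvain", metric = "euclidean"),
    list(method = "hc", metric = "correlation"),
    list(method = "hc", metric = "euclidean"))

  rows <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    part <- if (s$method == "louvain") {
      simm <- if (s$metric == "correlation") sim_corr
              else euclidean_similarity(patterns)
      consensus_vote(simm, gamma = gamma, n_runs = n_runs, seed = seeds[i])
    } else {
      hierarchical_subtype(patterns, metric = s$metric, k = k, gamma = gamma)
    }
    q_shared <- modularity_q(sim_corr, part$labels, gamma)
    rep_res <- reproducibility(cohort, gamma = gamma, n_runs = n_runs,
                               n_subsets = n_subsets, seed = seeds[4 + i],
                               method = s$method, metric = s$metric, k = k,
                               reference = part)
    data.frame(method = s$method, metric = s$metric,
               n_subtypes = n_communities(part), q = q_shared,
               reproducibility_pct = 100 * rep_res$overall)
  })
  do.call(rbind, rows)
}
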