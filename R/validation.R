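new_perm_result <- function(observed, null_stats, n_perm, seed, exact = FALSE) {
  p <- if (exact) mean(null_stats >= observed)
       else (1 + sum(null_stats >= observed)) / (1 + n_perm)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p = p, n_perm = n_perm, seed = seed, exact = exact),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed = %.4f, p = %.4g (%s, %d permutations)\n",
              x$observed_stat, x$p,
              if (x$exact) "exact" else "add-one Monte Carlo", x$n_perm))
  invisible(x)
}

#' Permutation test of the similarity-matrix structure
#'
#' Tests whether the modular structure found in the patient similarity
#' matrix exceeds what arises from patients with no shared spatial atrophy
#' pattern. The observed statistic is the consensus modularity Q at the
#' given gamma. Each null draw independently shuffles every patient's
#' *standardized deviation from the cohort-average z profile* across masked
#' locations, restores the per-location mean and scale, rebuilds the
#' similarity matrix, and reruns the consensus. This residual-permutation
#' null preserves the per-location profile shared by all patients (the
#' average atrophy pattern and its dispersion, including any noise inherited
#' from the CN reference fit) while destroying patient-specific spatial
#' structure, so the test asks whether patients cluster into *distinct*
#' patterns beyond a common one. `scheme = "matrix-permute"` instead
#' permutes patients jointly within the observed similarity matrix
#' rows/columns and re-optimizes.
#'
#' @param patterns An [compute_atrophy()] result.
#' @param gamma Resolution parameter.
#' @param n_runs Louvain runs per consensus inside the test (kept small for
#'   tractability).
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed.
#' @param scheme `"location-shuffle"` (default) or `"matrix-permute"`.
#' @return A `perm_result` with `p = (1 + #\{null >= observed\}) /
#'   (1 + n_perm)`.
#' @export
similarity_permutation_test <- function(patterns, gamma = 0.9, n_runs = 10,
                                        n_perm = 99, seed = NULL,
                                        scheme = c("location-shuffle",
                                                   "matrix-permute")) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 19)
  z <- masked_z(patterns)
  sim <- correlation_similarity(patterns)
  # per-location profile shared by all patients: mean and scale across the
  # cohort; the null permutes each patient's standardized deviation from it
  cm <- colMeans(z)
  cs <- apply(z, 2L, sd)
  cs[cs == 0] <- 1
  zres <- sweep(sweep(z, 2L, cm), 2L, cs, `/`)

  seeds <- derive_seeds(seed, n_perm + 2L)
  observed <- consensus_vote(sim, gamma = gamma, n_runs = n_runs,
                             seed = seeds[n_perm + 1L])$q
  null_stats <- with_seed(seeds[n_perm + 2L], {
    vapply(seq_len(n_perm), function(b) {
      if (scheme == "location-shuffle") {
        rs <- t(apply(zres, 1L, sample))
        zb <- sweep(sweep(rs, 2L, cs, `*`), 2L, cm, `+`)
        wb <- cor(t(zb))
        diag(wb) <- 0
      } else {
        idx <- sample(nrow(z))
        wb <- sim$w[idx, idx]
      }
      consensus_vote(wb, gamma = gamma, n_runs = n_runs, seed = seeds[b])$q
    }, 0)
  })
  new_perm_result(observed, null_stats, n_perm, seed)
}

#' Leave-subset-out reproducibility of subtyping
#'
#' Measures how stable the subtype assignments are under random removal of
#' part of the patient sample. The full-cohort consensus partition is the
#' reference; patients are split into `n_subsets` random equal subsets, and
#' for each subset the whole pipeline (z-scoring against the full CN group,
#' similarity, consensus at the same gamma) is rerun on the remaining
#' patients. Each rerun is aligned to the reference by maximum-overlap
#' matching over the retained patients, and the per-subset fraction of
#' retained patients keeping their reference label is averaged.
#'
#' @param cohort A [cohort()].
#' @param gamma Resolution parameter.
#' @param n_runs Louvain runs per consensus (default 100 inside resampling).
#' @param n_subsets Number of removal subsets (default 10, i.e. 10% removed
#'   per rerun).
#' @param seed Integer seed.
#' @param method `"louvain"` (consensus) or `"hc"` (deterministic
#'   hierarchical comparator).
#' @param metric Similarity metric, `"correlation"` or `"euclidean"`.
#' @param k Cluster count for `method = "hc"`.
#' @param reference Optional precomputed full-data `subtype_partition` to
#'   use as the reference.
#' @return Object of class `"reproducibility_result"`: `overall` (fraction
#'   in `[0, 1]`), `per_subset`, `n_subsets`, `seed`, and the `reference`
#'   partition.
#' @export
reproducibility <- function(cohort, gamma = 0.9, n_runs = 100,
                            n_subsets = 10, seed = NULL,
                            method = c("louvain", "hc"),
                            metric = c("correlation", "euclidean"),
                            k = 3, reference = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  ids <- ad_ids(cohort)
  if (length(ids) < n_subsets)
    stopf("need at least %d AD subjects for %d subsets", n_subsets, n_subsets)

  ref <- fit_cn_reference(cohort)
  seeds <- derive_seeds(seed, n_subsets + 2L)

  cluster_fun <- function(co, s) {
    pat <- compute_atrophy(co, fit_cn_reference(co))
    if (method == "louvain") {
      sim <- if (metric == "correlation") correlation_similarity(pat)
             else euclidean_similarity(pat)
      consensus_vote(sim, gamma = gamma, n_runs = n_runs, seed = s)
    } else {
      hierarchical_subtype(pat, metric = metric, k = k, gamma = gamma)
    }
  }

  if (is.null(reference)) reference <- cluster_fun(cohort, seeds[n_subsets + 1L])
  ref_labels <- reference$labels

  subsets <- with_seed(seeds[n_subsets + 2L],
                       split(sample(ids), rep_len(seq_len(n_subsets),
                                                  length(ids))))
  per_subset <- vapply(seq_len(n_subsets), function(s) {
    drop <- subsets[[s]]
    keep_rows <- !(cohort$subjects$subject_id %in% drop)
    sub <- cohort(cohort$thickness[keep_rows, , drop = FALSE],
                  group = cohort$subjects$group[keep_rows],
                  age = cohort$subjects$age[keep_rows],
                  sex = cohort$subjects$sex[keep_rows],
                  education = cohort$subjects$education[keep_rows],
                  subject_ids = cohort$subjects$subject_id[keep_rows],
                  mask = cohort$mask, roi_map = cohort$roi_map)
    part <- cluster_fun(sub, seeds[s])
    retained <- names(part$labels)
    aligned <- match_labels(ref_labels[retained], part$labels)
    mean(aligned == ref_labels[retained])
  }, 0)

  structure(list(overall = mean(per_subset), per_subset = per_subset,
                 n_subsets = as.integer(n_subsets), seed = seed,
                 reference = reference),
            class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  cat(sprintf("<reproducibility> %.2f%% over %d subsets (range %.1f-%.1f%%)\n",
              100 * x$overall, x$n_subsets, 100 * min(x$per_subset),
              100 * max(x$per_subset)))
  invisible(x)
}

#' Cross-cohort consistency of matched subtypes
#'
#' Tests whether subtypes found in two cohorts correspond: each subtype's
#' signature is its members' mean z-score per masked location, the observed
#' statistic is the mean Pearson correlation between name-matched
#' signatures, and the null re-matches cohort B's subtypes at random. For K
#' subtypes only K! matchings exist, so for small K the exact permutation
#' distribution is enumerated (minimum attainable p = 1/K!).
#'
#' @param patterns_a,patterns_b [compute_atrophy()] results on a shared
#'   masked-location vocabulary.
#' @param labels_a,labels_b Subtype label per patient (the matching is
#'   given by equal label values/names).
#' @param n_perm Monte Carlo permutations when K! is large (> 720).
#' @param seed Integer seed (Monte Carlo case only).
#' @return A `perm_result`.
#' @export
inter_dataset_consistency <- function(patterns_a, labels_a,
                                      patterns_b, labels_b,
                                      n_perm = 999, seed = NULL) {
  za <- masked_z(patterns_a); zb <- masked_z(patterns_b)
  if (ncol(za) != ncol(zb))
    stopf("datasets have different masked-location counts (%d vs %d)",
          ncol(za), ncol(zb))
  ka <- sort(unique(as.character(labels_a)))
  kb <- sort(unique(as.character(labels_b)))
  if (!identical(ka, kb))
    stopf("subtype labels differ between datasets (%s vs %s)",
          paste(ka, collapse = ","), paste(kb, collapse = ","))
  K <- length(ka)

  sig <- function(z, labels) {
    t(vapply(ka, function(k) colMeans(z[labels == k, , drop = FALSE]),
             numeric(ncol(z))))
  }
  sa <- sig(za, as.character(labels_a))
  sb <- sig(zb, as.character(labels_b))
  stat <- function(perm) mean(vapply(seq_len(K), function(i)
    cor(sa[i, ], sb[perm[i], ]), 0))

  observed <- stat(seq_len(K))
  if (factorial(K) <= 720) {
    perms <- all_permutations(K)
    null_stats <- apply(perms, 1L, stat)
    new_perm_result(observed, null_stats, nrow(perms), seed, exact = TRUE)
  } else {
    null_stats <- with_seed(seed, vapply(seq_len(n_perm),
                                         function(b) stat(sample(K)), 0))
    new_perm_result(observed, null_stats, n_perm, seed)
  }
}
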