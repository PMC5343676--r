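new_similarity <- function(w, metric, subject_ids, alpha = NULL) {
  w <- (w + t(w)) / 2          # exact symmetry by construction
  diag(w) <- 0                 # no self-loops
  dimnames(w) <- list(subject_ids, subject_ids)
  structure(list(w = w, metric = metric, alpha = alpha,
                 subject_ids = subject_ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d subjects, metric=%s%s\n",
              nrow(x$w), x$metric,
              if (is.null(x$alpha)) "" else sprintf(" (alpha=%.4g)", x$alpha)))
  invisible(x)
}

#' Correlation similarity between atrophy patterns
#'
#' The similarity of two patients is the Pearson correlation of their
#' z-score atrophy patterns over the masked cortex. Correlation compares the
#' *shape* of cortical thinning, not its overall level: it is invariant to
#' any per-patient positive affine transform of the pattern, which is what
#' makes it robust to a global severity axis.
#'
#' @param patterns An [compute_atrophy()] result.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `similarity_matrix` (symmetric, zero diagonal, entries in
#'   `[-1, 1]`).
#' @export
correlation_similarity <- function(patterns, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  z <- masked_z(patterns)
  if (ncol(z) < 3) stopf("need >= 3 masked locations (got %d)", ncol(z))
  if (nrow(z) < 2) stopf("need >= 2 patients (got %d)", nrow(z))
  v <- apply(z, 1L, sd)
  if (any(v == 0))
    stopf("zero-variance atrophy pattern for subject(s): %s",
          paste(rownames(z)[v == 0], collapse = ", "))
  w <- cor(t(z), method = method)
  new_similarity(w, paste0("correlation-", method), rownames(z))
}

#' Exponential-Euclidean similarity between atrophy patterns
#'
#' Comparator metric: the Euclidean distance `d_jk` between masked z-score
#' patterns mapped through the monotonically decreasing transform
#' `w_jk = exp(-d_jk / alpha)`, with regularization factor `alpha`. Unlike
#' correlation, this metric is sensitive to overall atrophy severity.
#'
#' @param patterns An [compute_atrophy()] result.
#' @param alpha Positive scalar, or `"auto"` (default) for the median
#'   off-diagonal distance.
#' @return A `similarity_matrix` with entries in `(0, 1]`.
#' @export
euclidean_similarity <- function(patterns, alpha = "auto") {
  z <- masked_z(patterns)
  if (ncol(z) < 3) stopf("need >= 3 masked locations (got %d)", ncol(z))
  if (nrow(z) < 2) stopf("need >= 2 patients (got %d)", nrow(z))
  d <- as.matrix(dist(z))
  if (identical(alpha, "auto")) alpha <- stats::median(d[upper.tri(d)])
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stopf("`alpha` must be a positive scalar or \"auto\"")
  w <- exp(-d / alpha)
  new_similarity(w, "euclidean-exp", rownames(z), alpha = alpha)
}

# Extract the nonnegative weight matrix used for modularity: negative
# entries clipped at zero; the clipped fraction is recorded.
nonneg_graph <- function(sim) {
  w <- if (inherits(sim, "similarity_matrix")) sim$w else as.matrix(sim)
  clipped <- mean(w[upper.tri(w)] < 0)
  w[w < 0] <- 0
  attr(w, "clipped_fraction") <- clipped
  w
}
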