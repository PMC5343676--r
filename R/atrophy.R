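#' Fit the CN reference distribution
#'
#' Computes the per-location mean and standard deviation of cortical
#' thickness over the cognitively normal subjects. These define the z unit
#' against which patient atrophy is scored. The sd uses the sample (n-1)
#' denominator. Masked locations with zero CN variance cannot be scored and
#' are dropped from the mask with a warning.
#'
#' @param cohort A [cohort()] with at least 2 CN subjects.
#' @return Object of class `"cn_reference"`: `mu`, `sigma` (per location,
#'   mm), `n_cn`, the possibly reduced `mask`, and `dropped` (ids of
#'   zero-variance locations).
#' @export
fit_cn_reference <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cn <- cohort$thickness[cohort$subjects$group == "CN", , drop = FALSE]
  if (nrow(cn) < 2) stopf("need >= 2 CN subjects to fit a reference (got %d)",
                          nrow(cn))
  mu <- colMeans(cn)
  sigma <- apply(cn, 2L, sd)
  mask <- cohort$mask
  zero_var <- mask & sigma == 0
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance location(s) from the mask: %s",
                    sum(zero_var),
                    paste(utils::head(names(mu)[zero_var], 5L), collapse = ", ")),
            call. = FALSE)
    mask[zero_var] <- FALSE
  }
  structure(list(mu = mu, sigma = sigma, n_cn = nrow(cn), mask = mask,
                 dropped = names(mu)[zero_var]),
            class = "cn_reference")
}

#' Compute z-score atrophy patterns
#'
#' Standardizes each patient's thickness to the CN distribution:
#' `z_ij = (t_ij - mu_i) / sigma_i` per masked location i, giving the extent
#' of cortical atrophy (negative = thinning relative to controls). The
#' patient's concatenated z-scores over the masked cortex are their atrophy
#' pattern. Unmasked locations are set to `NA` and excluded downstream.
#'
#' @param cohort A [cohort()].
#' @param ref A [fit_cn_reference()] result for the same location set;
#'   fitted on `cohort` if missing.
#' @param group Which subjects to score (default `"AD"`; use `"all"` to
#'   score controls too, e.g. for calibration checks).
#' @return Object of class `"atrophy_patterns"`: `z` (subjects x locations),
#'   `mask`, `reference`, `subject_ids`.
#' @export
compute_atrophy <- function(cohort, ref = NULL, group = "AD") {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(ref)) ref <- fit_cn_reference(cohort)
  if (length(ref$mu) != ncol(cohort$thickness))
    stopf("reference has %d locations, cohort has %d",
          length(ref$mu), ncol(cohort$thickness))
  if (!identical(names(ref$mu), colnames(cohort$thickness)))
    stopf("reference location ids do not match the cohort")

  keep <- if (identical(group, "all")) rep(TRUE, nrow(cohort$thickness))
          else cohort$subjects$group %in% group
  t_mat <- cohort$thickness[keep, , drop = FALSE]
  z <- sweep(sweep(t_mat, 2L, ref$mu, `-`), 2L, ref$sigma, `/`)
  z[, !ref$mask] <- NA_real_
  structure(list(z = z, mask = ref$mask, reference = ref,
                 subject_ids = rownames(t_mat)),
            class = "atrophy_patterns")
}

#' @export
print.atrophy_patterns <- function(x, ...) {
  cat(sprintf("<atrophy_patterns> %d subjects x %d locations (%d masked)\n",
              nrow(x$z), ncol(x$z), sum(x$mask)))
  invisible(x)
}

# masked z matrix (subjects x masked locations)
masked_z <- function(patterns) {
  stopifnot(inherits(patterns, "atrophy_patterns"))
  patterns$z[, patterns$mask, drop = FALSE]
}
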