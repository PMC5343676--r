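#' Per-subject ROI mean thickness
#'
#' Averages thickness over each ROI's masked locations, per subject. ROIs
#' left empty by the mask are dropped with a warning.
#'
#' @param cohort A [cohort()] with `roi_map`.
#' @return Object of class `"roi_table"`: `values` (subjects x ROIs),
#'   `roi_labels`, `n_locations` per ROI, `normalized = FALSE`.
#' @export
roi_means <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$roi_map)) stopf("cohort has no roi_map")
  keep <- cohort$mask
  map <- cohort$roi_map[keep]
  labs <- unique(cohort$roi_map)
  empty <- setdiff(labs, unique(map))
  if (length(empty)) {
    warning(sprintf("dropping %d ROI(s) with no masked locations: %s",
                    length(empty), paste(empty, collapse = ", ")),
            call. = FALSE)
    labs <- setdiff(labs, empty)
  }
  t_mat <- cohort$thickness[, keep, drop = FALSE]
  sums <- t(rowsum(t(t_mat), map))           # subjects x ROIs (sorted labels)
  counts <- as.vector(table(map)[colnames(sums)])
  vals <- sweep(sums, 2L, counts, `/`)[, labs, drop = FALSE]
  structure(list(values = vals, roi_labels = labs,
                 n_locations = counts[match(labs, colnames(sums))],
                 normalized = FALSE, subject_ids = rownames(t_mat)),
            class = "roi_table")
}

#' Normalize ROI thickness by whole-cortex mean
#'
#' Divides each subject's ROI mean thickness by that subject's mean
#' thickness over the entire masked cortex (location-weighted). This removes
#' the global atrophy level and retains the spatial *pattern*, so subtype
#' comparisons reflect where a subtype is atrophied rather than how much
#' overall. Invariant to scaling a subject's whole thickness row.
#'
#' @param roi A [roi_means()] result (not already normalized).
#' @param cohort The cohort the ROI table came from.
#' @return A `roi_table` with `normalized = TRUE`.
#' @export
normalize_roi <- function(roi, cohort) {
  stopifnot(inherits(roi, "roi_table"))
  if (roi$normalized) stopf("roi table is already normalized")
  cortex <- rowMeans(cohort$thickness[roi$subject_ids, cohort$mask,
                                      drop = FALSE])
  if (any(cortex == 0)) stopf("zero whole-cortex mean thickness")
  roi$values <- roi$values / cortex
  roi$normalized <- TRUE
  roi
}

#' Permutation-based ANCOVA for a group effect
#'
#' Partial F-test for a group effect on `y` adjusted for covariates: the
#' full linear model (covariates + group) is compared to the reduced model
#' (covariates only). Significance comes from a permutation null rather than
#' the F distribution, by default the Freedman-Lane scheme: reduced-model
#' residuals are permuted, added back to the reduced-model fit, and the
#' partial F recomputed; `scheme = "raw"` permutes `y` directly.
#'
#' @param y Numeric response per subject (e.g. normalized ROI thickness).
#' @param group Factor-like group label per subject (>= 2 levels).
#' @param covariates Data frame of adjustment covariates (numeric columns
#'   used as-is; character/factor columns expanded to indicators).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param scheme `"freedman-lane"` (default) or `"raw"`.
#' @return List with `f` (observed partial F), `p` (add-one permutation p),
#'   `df` (numerator, denominator), `null_f`.
#' @export
permutation_ancova <- function(y, group, covariates, n_perm = 999,
                               seed = NULL,
                               scheme = c("freedman-lane", "raw")) {
  scheme <- match.arg(scheme)
  y <- as.numeric(y)
  n <- length(y)
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need >= 2 groups")

  xr <- covariate_matrix(covariates, n)
  xg <- stats::model.matrix(~group)[, -1L, drop = FALSE]
  xf <- cbind(xr, xg)
  if (n <= ncol(xf)) stopf("more model terms than subjects")

  qr_r <- qr(xr); qr_f <- qr(xf)
  if (qr_f$rank < ncol(xf)) stopf("rank-deficient design matrix")
  df1 <- ncol(xf) - ncol(xr)
  df2 <- n - ncol(xf)

  qrt <- qr.Q(qr_r); qft <- qr.Q(qr_f)
  rss <- function(Y, Q) colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  fstat <- function(Y) {
    rr <- rss(Y, qrt); rf <- rss(Y, qft)
    ((rr - rf) / df1) / (rf / df2)
  }

  f_obs <- fstat(matrix(y, ncol = 1))

  fitted_r <- qrt %*% crossprod(qrt, y)
  resid_r <- y - fitted_r
  null_f <- with_seed(seed, {
    perm_idx <- replicate(n_perm, sample.int(n))
    ystar <- if (scheme == "freedman-lane")
      matrix(fitted_r, n, n_perm) + matrix(resid_r[perm_idx], n, n_perm)
    else matrix(y[perm_idx], n, n_perm)
    fstat(ystar)
  })
  p <- (1 + sum(null_f >= f_obs)) / (1 + n_perm)
  list(f = f_obs, p = p, df = c(df1, df2), null_f = null_f)
}

# Build a numeric covariate design matrix with intercept.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stopf("covariates have %d rows for %d subjects",
                                   nrow(covariates), n)
  if (anyNA(covariates)) stopf("missing values in covariates")
  stats::model.matrix(~., data = covariates)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up FDR control: adjusted p-values via `p.adjust(method = "BH")`,
#' rejecting tests with adjusted p <= `q`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Data frame with `p`, `p_adj`, `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0)
    return(data.frame(p = numeric(0), p_adj = numeric(0),
                      reject = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adj = adj, reject = adj <= q)
}

#' Select cortical atrophy hallmarks per subtype
#'
#' For every ROI, runs a permutation ANCOVA of normalized ROI thickness
#' across subtypes (adjusted for the given covariates), controls the FDR
#' over ROIs by Benjamini-Hochberg, and assigns each surviving ROI to the
#' subtype with the lowest covariate-adjusted mean normalized thickness --
#' the subtype for which that region is a hallmark of atrophy.
#'
#' @param roi A normalized [roi_table] (see [normalize_roi()]).
#' @param labels Subtype label per subject in the ROI table (a
#'   `subtype_partition` or a vector).
#' @param covariates Data frame of adjustment covariates (one row per
#'   subject in the ROI table).
#' @param n_perm Permutations per ROI.
#' @param q FDR level.
#' @param seed Integer seed.
#' @param scheme Permutation scheme, see [permutation_ancova()].
#' @return Object of class `"hallmark_table"`: a data frame with per-ROI
#'   F, p, adjusted p, FDR decision, per-subtype adjusted means and the
#'   assigned subtype (`NA` unless the ROI survives FDR).
#' @export
select_hallmarks <- function(roi, labels, covariates, n_perm = 999,
                             q = 0.05, seed = NULL,
                             scheme = c("freedman-lane", "raw")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(roi, "roi_table"))
  if (!roi$normalized)
    stopf("hallmark analysis expects normalized ROI thickness; see normalize_roi()")
  if (inherits(labels, "subtype_partition")) {
    labels <- labels$labels[roi$subject_ids]
    if (anyNA(labels)) stopf("partition does not cover all subjects in the ROI table")
  }
  if (length(labels) != nrow(roi$values))
    stopf("%d labels for %d subjects", length(labels), nrow(roi$values))
  group <- factor(labels)

  seeds <- derive_seeds(seed, length(roi$roi_labels))

  tests <- lapply(seq_along(roi$roi_labels), function(i) {
    permutation_ancova(roi$values[, i], group, covariates,
                       n_perm = n_perm, seed = seeds[i], scheme = scheme)
  })
  pvals <- vapply(tests, `[[`, 0, "p")
  fvals <- vapply(tests, `[[`, 0, "f")
  dec <- fdr_bh(pvals, q)

  # covariate-adjusted subtype means: full-model prediction at mean covariates
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  adj_means <- t(vapply(seq_along(roi$roi_labels), function(i) {
    adjusted_group_means(roi$values[, i], group, cov_df)
  }, numeric(nlevels(group))))
  colnames(adj_means) <- paste0("mean_", levels(group))

  assigned <- ifelse(dec$reject,
                     levels(group)[apply(adj_means, 1L, which.min)],
                     NA_character_)

  out <- data.frame(roi = roi$roi_labels, f = fvals, p = pvals,
                    p_adj = dec$p_adj, reject = dec$reject,
                    subtype = assigned, stringsAsFactors = FALSE)
  out <- cbind(out, adj_means)
  structure(out, class = c("hallmark_table", "data.frame"),
            q = q, n_perm = n_perm)
}

# Group means adjusted to the covariate grand means via the full model.
adjusted_group_means <- function(y, group, cov_df) {
  if (is.null(cov_df) || ncol(cov_df) == 0) {
    return(tapply(y, group, mean)[levels(group)])
  }
  dat <- data.frame(y = y, group = group, cov_df)
  fit <- lm(y ~ ., data = dat)
  newdat <- data.frame(group = factor(levels(group), levels = levels(group)))
  for (nm in names(cov_df)) {
    v <- cov_df[[nm]]
    newdat[[nm]] <- if (is.numeric(v)) mean(v) else {
      # modal level for discrete covariates
      names(sort(table(v), decreasing = TRUE))[1L]
    }
  }
  predict(fit, newdata = newdat)
}

#' @export
print.hallmark_table <- function(x, ...) {
  cat(sprintf("<hallmark_table> %d ROIs, %d surviving FDR at q = %g\n",
              nrow(x), sum(x$reject), attr(x, "q")))
  hits <- x[x$reject, c("roi", "f", "p_adj", "subtype")]
  if (nrow(hits)) print.data.frame(hits, row.names = FALSE, digits = 4)
  invisible(x)
}
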