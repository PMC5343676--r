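#' Assemble a cohort of thickness measurements
#'
#' Bundles a subjects x locations cortical thickness matrix (mm) with the
#' subject metadata, the cortical mask and the location-to-ROI map used by
#' every downstream stage. Thickness rows are patients and controls alike;
#' the `group` column separates the cognitively normal (CN) reference group
#' from the patient (AD) group.
#'
#' @param thickness Numeric matrix, subjects x locations, in mm. Column
#'   names are location ids (generated if absent).
#' @param group Character/factor of `"CN"`/`"AD"` per subject.
#' @param age,education Numeric covariates per subject (years).
#' @param sex Character per subject, `"F"` or `"M"`.
#' @param subject_ids Character ids; default `rownames(thickness)` or
#'   `s1..sn`.
#' @param mask Logical per location, `TRUE` = cortical. Default all `TRUE`.
#' @param roi_map Optional character vector per location giving the ROI
#'   label of each location.
#' @param true_subtype Optional planted subtype label per subject (`NA` for
#'   CN); carried by synthetic cohorts.
#' @return An object of class `"cohort"`.
#' @seealso [generate_cohort()], [fit_cn_reference()], [read_cohort()]
#' @export
cohort <- function(thickness, group, age = NULL, sex = NULL,
                   education = NULL, subject_ids = NULL, mask = NULL,
                   roi_map = NULL, true_subtype = NULL) {
  thickness <- as.matrix(thickness)
  n <- nrow(thickness)
  p <- ncol(thickness)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(thickness)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  }
  if (anyDuplicated(subject_ids))
    stopf("duplicated subject ids: %s",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (is.null(colnames(thickness)))
    colnames(thickness) <- paste0("loc", seq_len(p))
  rownames(thickness) <- subject_ids

  group <- as.character(group)
  if (length(group) != n) stopf("`group` must have one entry per subject")
  bad <- setdiff(unique(group), c("CN", "AD"))
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))

  if (is.null(mask)) mask <- rep(TRUE, p)
  if (length(mask) != p) stopf("`mask` length %d != %d locations", length(mask), p)
  if (!is.null(roi_map)) {
    if (length(roi_map) != p)
      stopf("`roi_map` length %d != %d locations", length(roi_map), p)
    roi_map <- stats::setNames(as.character(roi_map), colnames(thickness))
  }

  if (anyNA(thickness)) stopf("thickness matrix contains missing values")
  if (any(thickness[, mask, drop = FALSE] <= 0))
    stopf("non-positive thickness at masked locations")

  meta <- data.frame(
    subject_id = subject_ids,
    group = group,
    age = if (is.null(age)) NA_real_ else as.numeric(age),
    sex = if (is.null(sex)) NA_character_ else as.character(sex),
    education = if (is.null(education)) NA_real_ else as.numeric(education),
    true_subtype = if (is.null(true_subtype)) NA_character_
                   else as.character(true_subtype),
    stringsAsFactors = FALSE
  )

  structure(
    list(thickness = thickness, subjects = meta,
         mask = as.logical(mask), roi_map = roi_map),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d CN / %d AD), %d locations (%d masked)%s\n",
    nrow(x$thickness), sum(x$subjects$group == "CN"),
    sum(x$subjects$group == "AD"), ncol(x$thickness), sum(x$mask),
    if (is.null(x$roi_map)) "" else
      sprintf(", %d ROIs", length(unique(x$roi_map)))))
  invisible(x)
}

n_cn <- function(cohort) sum(cohort$subjects$group == "CN")
n_ad <- function(cohort) sum(cohort$subjects$group == "AD")
ad_ids <- function(cohort) cohort$subjects$subject_id[cohort$subjects$group == "AD"]

#' Write a cohort to delimited text files
#'
#' Writes `thickness.tsv` (subject_id + one column per location),
#' `metadata.tsv` (subject_id, group, age, sex, education, true_subtype),
#' and, when present, `roi_map.tsv` (location_id, roi_label) and `mask.tsv`
#' (location_id, cortical).
#'
#' @param cohort A [cohort()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- data.frame(subject_id = rownames(cohort$thickness),
                   cohort$thickness, check.names = FALSE)
  write.table(th, file.path(dir, "thickness.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$subjects, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$roi_map)) {
    write.table(
      data.frame(location_id = colnames(cohort$thickness),
                 roi_label = unname(cohort$roi_map)),
      file.path(dir, "roi_map.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  write.table(
    data.frame(location_id = colnames(cohort$thickness),
               cortical = cohort$mask),
    file.path(dir, "mask.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]. Subject ids present in the thickness matrix
#' but absent from the metadata (or vice versa) are an error naming the
#' offenders.
#'
#' @param dir Directory containing `thickness.tsv` and `metadata.tsv`
#'   (plus optional `roi_map.tsv`, `mask.tsv`).
#' @return A [cohort()] object.
#' @export
read_cohort <- function(dir) {
  tf <- file.path(dir, "thickness.tsv")
  mf <- file.path(dir, "metadata.tsv")
  if (!file.exists(tf)) stopf("missing thickness file: %s", tf)
  if (!file.exists(mf)) stopf("missing metadata file: %s", mf)

  th <- read.delim(tf, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(th)[1L] != "subject_id")
    stopf("thickness.tsv must start with a subject_id column")
  ids <- as.character(th$subject_id)
  mat <- as.matrix(th[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric thickness values")
  rownames(mat) <- ids

  meta <- read.delim(mf, stringsAsFactors = FALSE)
  missing_meta <- setdiff(ids, meta$subject_id)
  missing_th <- setdiff(meta$subject_id, ids)
  if (length(missing_meta) || length(missing_th))
    stopf("subject ids do not match across files (missing in metadata: %s; missing in thickness: %s)",
          paste(missing_meta, collapse = ","), paste(missing_th, collapse = ","))
  meta <- meta[match(ids, meta$subject_id), ]

  roi_map <- NULL
  rf <- file.path(dir, "roi_map.tsv")
  if (file.exists(rf)) {
    rm_tab <- read.delim(rf, stringsAsFactors = FALSE)
    roi_map <- rm_tab$roi_label[match(colnames(mat), rm_tab$location_id)]
  }
  mask <- NULL
  kf <- file.path(dir, "mask.tsv")
  if (file.exists(kf)) {
    mk <- read.delim(kf, stringsAsFactors = FALSE)
    mask <- as.logical(mk$cortical[match(colnames(mat), mk$location_id)])
  }

  cohort(mat, group = meta$group, age = meta$age, sex = meta$sex,
         education = meta$education, subject_ids = ids, mask = mask,
         roi_map = roi_map,
         true_subtype = if ("true_subtype" %in% names(meta))
           meta$true_subtype else NULL)
}
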