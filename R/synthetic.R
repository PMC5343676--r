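#' Define a planted subtype template
#'
#' A template is the mean atrophy pattern of one planted subtype, expressed
#' in z units (CN standard deviations): a depth `z_shift` applied on the
#' ROIs in `roi_support` (focal template) or, when `roi_support` is empty,
#' uniformly across the whole cortex (diffuse template).
#'
#' @param name Subtype label, e.g. `"MT"`.
#' @param z_shift Mean atrophy depth in z units; must be finite and <= 0.
#' @param roi_support Character vector of ROI labels carrying the shift;
#'   `character(0)` for a diffuse template.
#' @return An object of class `"subtype_template"`.
#' @export
subtype_template <- function(name, z_shift, roi_support = character(0)) {
  if (!is.finite(z_shift) || z_shift > 0)
    stopf("`z_shift` must be finite and <= 0 (got %s)", format(z_shift))
  structure(list(name = as.character(name), z_shift = z_shift,
                 roi_support = as.character(roi_support)),
            class = "subtype_template")
}

#' Default planted subtype templates (MT / P / D)
#'
#' Three templates mirroring the anatomical subtypes reported for very mild
#' Alzheimer's disease: a medial temporal-predominant subtype (MT; deep
#' atrophy in entorhinal, parahippocampal, temporal pole and insular
#' cortices, both hemispheres), a parietal-predominant subtype (P; deep
#' atrophy in precuneus, supramarginal, inferior and superior parietal
#' cortices), and a diffuse subtype (D; shallow uniform atrophy). Focal
#' depths are -0.6 z and the diffuse depth -0.3 z, the extremes of the
#' subtype median-atrophy band.
#'
#' @return List of three [subtype_template()] objects named MT, P, D.
#' @export
default_templates <- function() {
  both <- function(rois) c(paste0("lh_", rois), paste0("rh_", rois))
  list(
    MT = subtype_template(
      "MT", -0.6,
      both(c("entorhinal", "parahippocampal", "temporalpole", "insula"))),
    P = subtype_template(
      "P", -0.6,
      both(c("precuneus", "supramarginal", "inferiorparietal",
             "superiorparietal"))),
    D = subtype_template("D", -0.3)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the scale and summary statistics of the cohort the
#' method was designed for: 225 patients and 320 controls, CN mean cortical
#' thickness about 2.36 mm, subtype proportions 82/79/64 of 225, and a
#' patient-level deviation of 0.2 z around the subtype template.
#'
#' @param n_cn,n_ad Number of CN / AD subjects.
#' @param subtype_proportions Numeric simplex over the templates (recycled
#'   names from the template list); must sum to 1.
#' @param n_loc_per_roi Locations simulated per ROI (ROI-block resolution).
#' @param rois ROI vocabulary; default the 68 hemisphere-prefixed
#'   Desikan-style labels.
#' @param cn_mu_range,cn_sigma_range Uniform ranges (mm) for per-location CN
#'   mean and sd.
#' @param noise_sd Per-location sd (z units) of a patient's deviation from
#'   their subtype template.
#' @param severity_confound_sd Sd (z units) of a per-patient global severity
#'   offset added uniformly across locations; 0 disables.
#' @param covariate_model List with `age_mean`, `age_sd`, `edu_mean`,
#'   `edu_sd`, `p_female`, `age_slope` (mm of thickness per year of age,
#'   applied to all subjects; 0 disables).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_cn = 320, n_ad = 225,
                          subtype_proportions = c(82, 79, 64) / 225,
                          n_loc_per_roi = 10,
                          rois = desikan_rois(),
                          cn_mu_range = c(2.11, 2.61),
                          cn_sigma_range = c(0.15, 0.35),
                          noise_sd = 0.2,
                          severity_confound_sd = 0,
                          covariate_model = list(
                            age_mean = 70, age_sd = 8,
                            edu_mean = 10, edu_sd = 5,
                            p_female = 0.6, age_slope = 0)) {
  stopifnot(n_cn >= 1, n_ad >= 1, n_loc_per_roi >= 1)
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stopf("subtype proportions must sum to 1")
  if (any(subtype_proportions < 0)) stopf("negative subtype proportion")
  if (any(cn_sigma_range <= 0)) stopf("cn_sigma_range must be positive")
  if (noise_sd < 0 || severity_confound_sd < 0)
    stopf("noise/severity sd must be nonnegative")
  structure(list(
    n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
    subtype_proportions = subtype_proportions,
    n_loc_per_roi = as.integer(n_loc_per_roi), rois = rois,
    cn_mu_range = cn_mu_range, cn_sigma_range = cn_sigma_range,
    noise_sd = noise_sd, severity_confound_sd = severity_confound_sd,
    covariate_model = covariate_model), class = "cohort_config")
}

# Largest-remainder apportionment of n subjects to proportions.
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic cohort with planted subtypes
#'
#' Simulates thickness as `t_ij = mu_i + sigma_i * x_ij` with per-location
#' CN mean `mu_i` and sd `sigma_i` drawn uniformly from the configured
#' ranges. For CN subjects `x_ij ~ N(0, 1)` (the CN group defines the z
#' unit); for a patient of subtype k, `x_ij ~ N(shift_k(i) + g_j,
#' noise_sd^2)` where `shift_k` is the template's z-shift map and `g_j ~
#' N(0, severity_confound_sd^2)` an optional global severity offset shared
#' by all locations of patient j. Covariates are matched across groups by
#' construction.
#'
#' @param config A [cohort_config()].
#' @param templates List of [subtype_template()] objects.
#' @param seed Integer seed; the same config + seed reproduces the cohort
#'   exactly.
#' @return List with `cohort` (a [cohort()] with `true_subtype` filled for
#'   AD subjects) and `truth` (data.frame subject_id, subtype; plus the
#'   templates and per-patient severity offsets as attributes).
#' @examples
#' sim <- generate_cohort(cohort_config(n_cn = 40, n_ad = 30,
#'                                      n_loc_per_roi = 1),
#'                        default_templates(), seed = 1)
#' sim$cohort
#' @export
generate_cohort <- function(config, templates, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), length(templates) >= 1)
  if (length(config$subtype_proportions) != length(templates))
    stopf("%d proportions for %d templates",
          length(config$subtype_proportions), length(templates))
  tnames <- vapply(templates, `[[`, "", "name")
  for (tpl in templates) {
    bad <- setdiff(tpl$roi_support, config$rois)
    if (length(bad))
      stopf("template '%s' references ROI(s) absent from the ROI map: %s",
            tpl$name, paste(bad, collapse = ", "))
  }

  with_seed(seed, {
    p <- length(config$rois) * config$n_loc_per_roi
    roi_map <- rep(config$rois, each = config$n_loc_per_roi)
    loc_ids <- paste0(roi_map, "_v", seq_len(config$n_loc_per_roi))

    mu <- runif(p, config$cn_mu_range[1], config$cn_mu_range[2])
    sigma <- runif(p, config$cn_sigma_range[1], config$cn_sigma_range[2])

    # per-template z-shift map over locations
    shift <- sapply(templates, function(tpl) {
      if (length(tpl$roi_support) == 0) rep(tpl$z_shift, p)
      else ifelse(roi_map %in% tpl$roi_support, tpl$z_shift, 0)
    })

    counts <- apportion(config$n_ad, config$subtype_proportions)
    ad_subtype <- sample(rep(seq_along(templates), counts))

    n <- config$n_cn + config$n_ad
    x <- matrix(0, n, p)
    cn_rows <- seq_len(config$n_cn)
    ad_rows <- config$n_cn + seq_len(config$n_ad)
    x[cn_rows, ] <- rnorm(config$n_cn * p)
    g <- if (config$severity_confound_sd > 0)
      rnorm(config$n_ad, 0, config$severity_confound_sd) else
      rep(0, config$n_ad)
    x[ad_rows, ] <- t(shift[, ad_subtype]) + g +
      matrix(rnorm(config$n_ad * p, 0, config$noise_sd), config$n_ad, p)

    thickness <- sweep(sweep(x, 2L, sigma, `*`), 2L, mu, `+`)

    cm <- config$covariate_model
    age <- rnorm(n, cm$age_mean, cm$age_sd)
    education <- pmax(0, rnorm(n, cm$edu_mean, cm$edu_sd))
    sex <- ifelse(runif(n) < cm$p_female, "F", "M")
    if (cm$age_slope != 0)
      thickness <- thickness + (age - cm$age_mean) * cm$age_slope
    thickness[thickness <= 0] <- 1e-3  # floor far below plausible cortex

    ids <- c(sprintf("cn%03d", cn_rows), sprintf("ad%03d", seq_len(config$n_ad)))
    colnames(thickness) <- loc_ids
    true_subtype <- c(rep(NA_character_, config$n_cn), tnames[ad_subtype])

    co <- cohort(thickness,
                 group = rep(c("CN", "AD"), c(config$n_cn, config$n_ad)),
                 age = age, sex = sex, education = education,
                 subject_ids = ids, roi_map = roi_map,
                 true_subtype = true_subtype)
    truth <- data.frame(subject_id = ids[ad_rows],
                        subtype = tnames[ad_subtype],
                        stringsAsFactors = FALSE)
    attr(truth, "templates") <- templates
    attr(truth, "severity") <- g
    attr(truth, "mu") <- mu
    attr(truth, "sigma") <- sigma
    list(cohort = co, truth = truth)
  })
}
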