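test_that("ROI means average masked locations per region", {
  th <- rbind(c(2.0, 2.0, 3.0, 3.0),
              c(2.4, 2.4, 3.6, 3.6))
  co <- cohort(th, group = c("CN", "AD"),
               roi_map = c("r1", "r1", "r2", "r2"))
  rm_ <- roi_means(co)
  expect_equal(unname(rm_$values[1, ]), c(2.0, 3.0))
  expect_equal(unname(rm_$values[2, ]), c(2.4, 3.6))
  # constant field: every ROI mean equals the constant
  co2 <- cohort(matrix(2.5, 2, 4), group = c("CN", "AD"),
                roi_map = c("r1", "r1", "r2", "r2"))
  expect_true(all(roi_means(co2)$values == 2.5))
})

test_that("the 68-label map yields 68 ROI columns", {
  sim <- generate_cohort(cohort_config(n_cn = 3, n_ad = 3, n_loc_per_roi = 2),
                         default_templates(), seed = 2)
  expect_equal(ncol(roi_means(sim$cohort)$values), 68)
})

test_that("ROIs emptied by the mask are dropped with a warning", {
  th <- matrix(runif(8, 2, 3), 2, 4)
  co <- cohort(th, group = c("CN", "AD"),
               mask = c(TRUE, TRUE, FALSE, FALSE),
               roi_map = c("r1", "r1", "gone", "gone"))
  expect_warning(rm_ <- roi_means(co), "gone")
  expect_equal(rm_$roi_labels, "r1")
})

test_that("normalized ROI thickness divides by the whole-cortex mean", {
  th <- rbind(c(2.0, 2.0, 3.0, 3.0),
              c(2.0, 2.0, 3.0, 3.0))
  co <- cohort(th, group = c("CN", "AD"),
               roi_map = c("r1", "r1", "r2", "r2"))
  nr <- normalize_roi(roi_means(co), co)
  # cortex mean 2.5 -> 0.8 and 1.2, exact
  expect_equal(unname(nr$values[1, ]), c(0.8, 1.2), tolerance = 1e-12)
  expect_true(nr$normalized)
  expect_error(normalize_roi(nr, co), "already")
  # uniform thickness -> all normalized values 1
  co2 <- cohort(matrix(2.2, 2, 4), group = c("CN", "AD"),
                roi_map = c("r1", "r1", "r2", "r2"))
  expect_true(all(normalize_roi(roi_means(co2), co2)$values == 1))
})

test_that("normalization is invariant to per-subject global scaling", {
  set.seed(5)
  th <- matrix(runif(3 * 6, 2, 3), 3, 6)
  co1 <- cohort(th, group = c("CN", "AD", "AD"),
                roi_map = rep(c("r1", "r2", "r3"), each = 2))
  th2 <- th * c(1, 1.3, 0.7)   # per-subject global atrophy level
  co2 <- cohort(th2, group = c("CN", "AD", "AD"),
                roi_map = rep(c("r1", "r2", "r3"), each = 2))
  expect_equal(normalize_roi(roi_means(co1), co1)$values,
               normalize_roi(roi_means(co2), co2)$values,
               tolerance = 1e-12)
})

test_that("permutation-ANCOVA F equals the closed-form partial F", {
  set.seed(30)
  for (rep in 1:5) {
    n <- 60
    covs <- data.frame(age = rnorm(n, 70, 8), sex = sample(c("F", "M"), n, TRUE),
                       education = rnorm(n, 10, 5))
    grp <- factor(sample(c("MT", "P", "D"), n, TRUE))
    y <- rnorm(n) + 0.02 * covs$age + 0.3 * (grp == "P")
    res <- permutation_ancova(y, grp, covs, n_perm = 19, seed = 1)
    full <- lm(y ~ age + sex + education + grp, data = covs)
    red <- lm(y ~ age + sex + education, data = covs)
    f_ref <- anova(red, full)$F[2]
    expect_equal(res$f, f_ref, tolerance = 1e-10)
    expect_equal(res$df, c(2, n - 6))
  }
})

test_that("the observed F is invariant to subject order", {
  set.seed(31)
  n <- 40
  covs <- data.frame(age = rnorm(n), education = rnorm(n))
  grp <- sample(c("a", "b"), n, TRUE)
  y <- rnorm(n)
  f1 <- permutation_ancova(y, grp, covs, n_perm = 9, seed = 1)$f
  idx <- sample(n)
  f2 <- permutation_ancova(y[idx], grp[idx], covs[idx, ], n_perm = 9,
                           seed = 1)$f
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("a strong group effect attains the minimum permutation p", {
  set.seed(32)
  n <- 45
  covs <- data.frame(age = rnorm(n))
  grp <- rep(c("a", "b", "c"), each = 15)
  y <- rnorm(n, 0, 0.1) + c(a = 0, b = 2, c = 4)[grp]
  res <- permutation_ancova(y, grp, covs, n_perm = 999, seed = 2)
  expect_equal(res$p, 0.001)
})

test_that("permutation p tracks the parametric p under Gaussian errors", {
  set.seed(33)
  diffs <- replicate(30, {
    n <- 50
    covs <- data.frame(age = rnorm(n), education = rnorm(n))
    grp <- sample(c("a", "b", "c"), n, TRUE)
    y <- rnorm(n) + 0.5 * covs$age
    res <- permutation_ancova(y, grp, covs, n_perm = 199, seed = 7)
    p_param <- pf(res$f, res$df[1], res$df[2], lower.tail = FALSE)
    abs(res$p - p_param)
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("rank-deficient and undersized designs are rejected", {
  covs <- data.frame(age = 1:10, age2 = (1:10) * 2)  # collinear
  expect_error(permutation_ancova(rnorm(10), rep(c("a", "b"), 5), covs,
                                  n_perm = 9),
               "rank")
  expect_error(permutation_ancova(rnorm(4), c("a", "a", "b", "b"),
                                  data.frame(x = rnorm(4), y = rnorm(4),
                                             z = rnorm(4)),
                                  n_perm = 9),
               "terms|subjects")
})

test_that("Benjamini-Hochberg step-up matches the hand example", {
  d <- fdr_bh(c(0.001, 0.01, 0.02, 0.04, 0.9), q = 0.05)
  expect_equal(sum(d$reject), 4)
  expect_identical(d$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(fdr_bh(rep(1, 5))$reject), 0)
  expect_equal(sum(fdr_bh(rep(0, 5))$reject), 5)
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejections contain the Bonferroni rejections", {
  set.seed(34)
  for (rep in 1:20) {
    p <- runif(40)^2
    bh <- fdr_bh(p, q = 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh[bonf]))
  }
})

test_that("hallmark selection finds the planted focal regions", {
  cfg <- cohort_config(n_cn = 80, n_ad = 90, n_loc_per_roi = 2,
                       subtype_proportions = c(1, 1, 1) / 3)
  sim <- generate_cohort(cfg, default_templates(), seed = 40)
  co <- sim$cohort
  ad <- co$subjects$group == "AD"
  roi <- roi_means(co)
  roi$values <- roi$values[ad, , drop = FALSE]
  roi$subject_ids <- roi$subject_ids[ad]
  roi <- atrophynet:::normalize_roi_rows(roi, co)
  covs <- data.frame(age = co$subjects$age[ad], sex = co$subjects$sex[ad],
                     education = co$subjects$education[ad])
  ht <- select_hallmarks(roi, sim$truth$subtype, covs, n_perm = 499,
                         q = 0.05, seed = 41)
  mt_hits <- ht$roi[ht$reject & !is.na(ht$subtype) & ht$subtype == "MT"]
  p_hits <- ht$roi[ht$reject & !is.na(ht$subtype) & ht$subtype == "P"]
  expect_true(all(c("lh_entorhinal", "rh_entorhinal") %in% mt_hits))
  expect_true(all(c("lh_precuneus", "rh_precuneus") %in% p_hits))
  # no focal ROI assigned to the diffuse subtype
  mtp_support <- c(attr(sim$truth, "templates")$MT$roi_support,
                   attr(sim$truth, "templates")$P$roi_support)
  expect_false(any(ht$subtype[ht$roi %in% mtp_support] == "D", na.rm = TRUE))
  # decisions monotone in p
  ord <- order(ht$p)
  expect_true(all(diff(ht$reject[ord]) <= 0))
})

test_that("hallmark table is empty under a vanishing FDR level on null data", {
  cfg <- cohort_config(n_cn = 40, n_ad = 45, n_loc_per_roi = 1,
                       subtype_proportions = c(1, 1, 1) / 3)
  tpls <- list(subtype_template("a", 0), subtype_template("b", 0),
               subtype_template("c", 0))
  sim <- generate_cohort(cfg, tpls, seed = 42)
  co <- sim$cohort
  ad <- co$subjects$group == "AD"
  roi <- roi_means(co)
  roi$values <- roi$values[ad, , drop = FALSE]
  roi$subject_ids <- roi$subject_ids[ad]
  roi <- atrophynet:::normalize_roi_rows(roi, co)
  covs <- data.frame(age = co$subjects$age[ad])
  ht <- select_hallmarks(roi, sim$truth$subtype, covs, n_perm = 99,
                         q = 1e-9, seed = 43)
  expect_equal(sum(ht$reject), 0)
  expect_true(all(is.na(ht$subtype)))
})
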