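test_that("Mann-Whitney exact p matches enumeration and hand values", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)          # 2/20 arrangements per tail
  expect_equal(r$method, "exact")

  ## identical groups
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5))$p_value, 1)

  ## enumeration oracle across random tie-free samples
  set.seed(41)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.5)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 enum_mwu_p(x, y), tolerance = 1e-12)
  }
  ## with ties, the exact mode enumerates the tied arrangement
  x <- c(1, 2, 2); y <- c(2, 3)
  expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
               enum_mwu_p(x, y), tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank exact p matches enumeration and hand values", {
  r <- wilcoxon_signed_rank(1:5, 2:6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.0625)       # 2 * 2^-5 * 2 sign patterns per tail
  expect_equal(r$method, "exact")

  ## symmetric +/- differences of equal magnitudes: p = 1 by symmetry
  ipsi <- c(1, 2, 3, 4, 5, 6)
  contra <- ipsi - c(1, -1, 2, -2, 3, -3)
  expect_equal(wilcoxon_signed_rank(ipsi, contra)$p_value, 1)

  ## all differences zero
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)

  ## enumeration oracle, tie-free magnitudes
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n, 0.4)
    expect_equal(wilcoxon_signed_rank(a, b, mode = "exact")$p_value,
                 enum_wsr_p(a, b), tolerance = 1e-12)
  }
})

test_that("corrected asymptotic p-values track the exact null closely", {
  ## Mann-Whitney: every statistic, group sizes 5..7
  for (n1 in 5:7) for (n2 in n1:7) {
    x0 <- seq_len(n1)
    for (U in 0:(n1 * n2)) {
      pex <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                            1 - stats::pwilcox(U - 1, n1, n2)))
      ## build a tie-free sample realising this U
      pas <- microfa:::mwu_asymptotic(U, n1, n2, seq_len(n1 + n2), FALSE)
      expect_lt(abs(pex - pas), 0.005)
    }
  }
  ## Wilcoxon: every statistic, 6..12 pairs
  for (n in 6:12) {
    for (W in 0:(n * (n + 1) / 2)) {
      pex <- min(1, 2 * min(stats::psignrank(W, n),
                            1 - stats::psignrank(W - 1, n)))
      pas <- microfa:::wsr_asymptotic(W, n, seq_len(n), FALSE)
      expect_lt(abs(pex - pas), 0.01)
    }
  }
})

test_that("asymptotic mode handles ties through the variance correction", {
  set.seed(43)
  for (i in 1:10) {
    x <- sample(1:4, 12, replace = TRUE)
    y <- sample(2:5, 14, replace = TRUE)
    p <- mann_whitney_u(x, y, mode = "asymptotic")$p_value
    ## reference: base R's tie-corrected normal approximation
    pref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE)$p.value)
    expect_equal(p, pref, tolerance = 1e-8)
  }
})

test_that("Bonferroni thresholds match the two analysis families", {
  expect_equal(bonferroni_threshold(0.05, 16), 0.003125)
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.01, 1), 0.01)
  expect_error(bonferroni_threshold(1.2, 4))
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8)^3)$rho, -1)
  r <- spearman_rho(c(1, 2, 3), c(1, 1, 2))
  expect_equal(r$rho, 0.866, tolerance = 1e-3)
  ## symmetry
  set.seed(44)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(y, x)$rho)
  ## agreement with base R on tie-free data
  expect_equal(spearman_rho(x, y)$rho,
               unname(stats::cor(x, y, method = "spearman")))
  expect_warning(spearman_rho(rep(1, 5), 1:5), "zero rank variance")
})

test_that("ROC AUC equals the pairwise probability and the trapezoid area", {
  ## perfectly separated
  expect_equal(roc_auc(c(1, 2, 3, 7, 8, 9),
                       rep(c("control", "case"), each = 3),
                       "higher_is_case")$auc, 1)
  ## identical distributions
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3),
                       rep(c("control", "case"), each = 3),
                       "higher_is_case")$auc, 0.5)
  ## hand-computed with a tie
  expect_equal(roc_auc(c(2, 3, 1, 3), c("case", "case", "control", "control"),
                       "higher_is_case")$auc, 0.625)
  ## direction flip mirrors the AUC
  v <- c(1, 2, 3, 4); lab <- c("case", "case", "control", "control")
  expect_equal(roc_auc(v, lab, "lower_is_case")$auc,
               1 - roc_auc(v, lab, "higher_is_case")$auc)
  ## trapezoidal area equals the pairwise statistic
  set.seed(45)
  for (i in 1:10) {
    vals <- c(stats::rnorm(12, 1), stats::rnorm(9))
    labs <- rep(c("case", "control"), c(12, 9))
    roc <- roc_auc(vals, labs, "higher_is_case")
    cu <- roc$curve[order(1 - roc$curve$specificity, roc$curve$sensitivity), ]
    fpr <- 1 - cu$specificity
    area <- sum(diff(fpr) * (utils::head(cu$sensitivity, -1) +
                               utils::tail(cu$sensitivity, -1)) / 2)
    expect_equal(roc$auc, area, tolerance = 1e-9)
  }
  expect_error(roc_auc(1:3, rep("case", 3)), "two classes")
})

test_that("single-hemisphere selection follows the metric-specific rule", {
  tab <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    region = "CA4/DG",
    hemisphere = rep(c("left", "right"), 2),
    metric = "ufa",
    value = c(0.50, 0.47, 0.44, 0.49))
  sel <- select_single_hemisphere(tab, "CA4/DG", "ufa")
  expect_equal(sel$value, c(0.47, 0.44))
  expect_equal(sel$hemisphere, c("right", "left"))
  tab$metric <- "md"
  tab$value <- c(0.85, 0.90, 0.95, 0.93)
  sel_md <- select_single_hemisphere(tab, "CA4/DG", "md")
  expect_equal(sel_md$value, c(0.90, 0.95))
  ## ties resolve to the left hemisphere, value unchanged
  tab$metric <- "fa"
  tab$value <- c(0.2, 0.2, 0.3, 0.3)
  sel_fa <- select_single_hemisphere(tab, "CA4/DG", "fa")
  expect_equal(sel_fa$hemisphere, c("left", "left"))
  expect_equal(sel_fa$value, c(0.2, 0.3))
})

test_that("asymmetry indices match the percentage-difference formulas", {
  expect_equal(asymmetry_index(0.51, 0.48), 6.0606, tolerance = 1e-4)
  expect_equal(asymmetry_index(0.4, 0.4), 0)
  expect_equal(asymmetry_index(0.5, 0.3), -asymmetry_index(0.3, 0.5))
  ## scale invariance
  expect_equal(asymmetry_index(0.51 * 7, 0.48 * 7),
               asymmetry_index(0.51, 0.48))
  expect_warning(a <- asymmetry_index(0.2, -0.2), "non-positive")
  expect_true(is.na(a))

  expect_equal(absolute_asymmetry(0.49, 0.45), 8.5106, tolerance = 1e-4)
  expect_equal(absolute_asymmetry(0.45, 0.49), absolute_asymmetry(0.49, 0.45))
  expect_equal(absolute_asymmetry(0.3, 0.3), 0)
})

test_that("lateralization applies the direction rules and scores ties as misses", {
  tab <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    suspected_side = rep(c("left", "left", "right"), each = 2),
    region = "CA4/DG", metric = "ufa",
    hemisphere = rep(c("left", "right"), 3),
    value = c(0.44, 0.49,   # lower left: predicts left, correct
              0.50, 0.46,   # lower right: predicts right, incorrect
              0.48, 0.48))  # tie: indeterminate, incorrect
  lat <- lateralize(tab, "CA4/DG", "ufa")
  expect_equal(lat$predictions$predicted_side,
               c("left", "right", "indeterminate"))
  expect_equal(lat$accuracy, 1 / 3)
  ## MD uses the opposite rule
  tab$metric <- "md"
  tab$value <- c(1.1, 0.9, 0.9, 1.1, 1.0, 1.0)
  lat_md <- lateralize(tab, "CA4/DG", "md")
  expect_equal(lat_md$predictions$predicted_side,
               c("left", "right", "indeterminate"))
})
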