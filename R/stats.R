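## Rank-based tests with exact and corrected-asymptotic modes.
##
## The exact modes enumerate (or use the closed-form null distributions of)
## the permutation null; the asymptotic modes use a continuity-corrected
## normal approximation sharpened, for small tie-free samples, by an
## Edgeworth expansion in the null cumulants. Two-sided p-values are twice
## the smaller tail, capped at 1, matching the exact-enumeration convention.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference between two independent groups.
#' The statistic is `U = #\{(i, j): x_i > y_j\} + 0.5 #\{ties\}` (so `U = 0`
#' when every `x` is below every `y`). Mode `"exact"` uses the exact
#' permutation null (closed form without ties, full enumeration with ties);
#' `"asymptotic"` uses the tie-corrected normal approximation with continuity
#' correction, refined by an Edgeworth term for small tie-free samples;
#' `"auto"` picks exact when `n1 + n2 <= 12` (enumerating the tied null if needed).
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param alpha Significance threshold recorded in the result (use
#'   [bonferroni_threshold()] for corrected families).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n1`, `n2`,
#'   `method`, `alpha_corrected`, `significant`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value # exact 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    p <- 1
    method <- "degenerate"
  } else if (mode == "exact" || (mode == "auto" && n1 + n2 <= 12)) {
    p <- if (has_ties) mwu_exact_ties(x, y, U) else mwu_exact_noties(U, n1, n2)
    method <- "exact"
  } else {
    p <- mwu_asymptotic(U, n1, n2, pooled, has_ties)
    method <- "asymptotic"
  }
  stat_result("mann_whitney_u", U, p, n1, n2, method, alpha)
}

stat_result <- function(test, statistic, p, n1, n2, method, alpha) {
  tibble::tibble(test = test, statistic = statistic,
                 p_value = min(1, max(0, p)), n1 = n1, n2 = n2,
                 method = method, alpha_corrected = alpha,
                 significant = p < alpha)
}

mwu_exact_noties <- function(U, n1, n2) {
  ## U is integer-valued without ties; pwilcox is the exact null CDF
  U <- round(U)
  min(1, 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2)))
}

mwu_exact_ties <- function(x, y, U) {
  n1 <- length(x); n <- n1 + length(y)
  if (choose(n, n1) > 5e5) {
    stop("exact Mann-Whitney with ties is limited to choose(n, n1) <= 5e5 ",
         "arrangements; use mode = 'asymptotic'", call. = FALSE)
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  combs <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps)))
}

mwu_asymptotic <- function(U, n1, n2, pooled, has_ties) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (v <= 0) return(1)
  if (!has_ties && n <= 30) {
    u_sup <- 0:(n1 * n2)
    pr <- stats::dwilcox(u_sup, n1, n2)
    p2_edgeworth(U, u_sup, pr)
  } else {
    p2_normal(U, mu, sqrt(v))
  }
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test of `ipsi` versus `contra`. Zero differences are
#' dropped; the statistic `W` is the sum of the ranks of the positive
#' differences `ipsi - contra` (so `W = 0` when `contra` exceeds `ipsi` in
#' every pair). Mode `"exact"` uses the exact sign-flip null (closed form
#' without tied magnitudes, enumeration of the `2^n` sign patterns with
#' ties); `"asymptotic"` is the tie-corrected, continuity-corrected normal
#' approximation with an Edgeworth refinement for small tie-free samples;
#' `"auto"` picks exact when `n <= 15`.
#'
#' @param ipsi,contra Paired numeric vectors of equal length.
#' @inheritParams mann_whitney_u
#' @return One-row tibble as in [mann_whitney_u()] (`n1 = n2` = pairs kept).
#' @examples
#' wilcoxon_signed_rank(1:5, 2:6)$p_value # exact 0.0625
#' @export
wilcoxon_signed_rank <- function(ipsi, contra,
                                 mode = c("auto", "exact", "asymptotic"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(ipsi) == length(contra))
  keep <- !is.na(ipsi) & !is.na(contra)
  d <- (ipsi - contra)[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result("wilcoxon_signed_rank", 0, 1, 0, 0, "degenerate", alpha))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  ## auto mode enumerates whenever n <= 15: the 2^n sign patterns are cheap
  ## and enumeration handles tied magnitudes exactly
  if (mode == "exact" || (mode == "auto" && n <= 15)) {
    p <- if (has_ties) wsr_exact_ties(r, d, W) else wsr_exact_noties(W, n)
    method <- "exact"
  } else {
    p <- wsr_asymptotic(W, n, r, has_ties)
    method <- "asymptotic"
  }
  stat_result("wilcoxon_signed_rank", W, p, n, n, method, alpha)
}

wsr_exact_noties <- function(W, n) {
  W <- round(W)
  min(1, 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n)))
}

wsr_exact_ties <- function(r, d, W) {
  n <- length(d)
  if (n > 20) {
    stop("exact signed-rank with tied magnitudes is limited to n <= 20; ",
         "use mode = 'asymptotic'", call. = FALSE)
  }
  ## enumerate all 2^n sign assignments of the ranked magnitudes
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= W + eps), mean(w_all >= W - eps)))
}

wsr_asymptotic <- function(W, n, r, has_ties) {
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (v <= 0) return(1)
  if (!has_ties && n <= 30) {
    w_sup <- 0:(n * (n + 1) / 2)
    pr <- stats::dsignrank(w_sup, n)
    p2_edgeworth(W, w_sup, pr)
  } else {
    p2_normal(W, mu, sqrt(v))
  }
}

## two-sided continuity-corrected normal p
p2_normal <- function(t, mu, sig) {
  plo <- stats::pnorm((t + 0.5 - mu) / sig)
  pup <- 1 - stats::pnorm((t - 0.5 - mu) / sig)
  min(1, 2 * min(plo, pup))
}

## two-sided p from an Edgeworth expansion matched to the exact null moments
## (symmetric lattice null: only even-order terms enter)
p2_edgeworth <- function(t, support, pr) {
  mu <- sum(support * pr)
  m <- function(k) sum((support - mu)^k * pr)
  v <- m(2); sig <- sqrt(v)
  g2 <- m(4) / v^2 - 3
  l6 <- (m(6) - 15 * m(4) * v - 10 * m(3)^2 + 30 * v^3) / v^3
  F <- function(x) {
    he3 <- x^3 - 3 * x
    he5 <- x^5 - 10 * x^3 + 15 * x
    he7 <- x^7 - 21 * x^5 + 105 * x^3 - 105 * x
    stats::pnorm(x) - stats::dnorm(x) *
      (g2 / 24 * he3 + l6 / 720 * he5 + g2^2 / 1152 * he7)
  }
  plo <- F((t + 0.5 - mu) / sig)
  pup <- 1 - F((t - 0.5 - mu) / sig)
  min(1, max(0, 2 * min(plo, pup)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise starting threshold in (0, 1).
#' @param m Number of comparisons in the family (>= 1). The hippocampal
#'   analysis uses m = 16 (4 regions x 4 metrics) for subregions and m = 4
#'   (4 metrics) for the full hippocampus.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 16) # 0.003125
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties), with a
#' two-sided p-value from the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return One-row tibble: `rho`, `p_value`, `n`. `rho` is `NA` (with a
#'   warning) when either variable has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined",
            call. = FALSE)
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' ROC curve and AUC for case/control separation
#'
#' Orients the metric so that larger oriented scores indicate disease
#' (`direction = "lower_is_case"` negates the values, the expected direction
#' for anisotropy and volume; `"higher_is_case"` fits diffusivity), then
#' computes the exact pairwise AUC
#' `P(score_case > score_control) + 0.5 P(equal)` over all case-control
#' pairs, together with the threshold-sweep curve (whose trapezoidal area
#' equals the pairwise statistic).
#'
#' @param values Per-subject metric values.
#' @param labels Vector with two classes; `"case"`/`"control"` or a factor
#'   whose first level is taken as control.
#' @param direction `"lower_is_case"` or `"higher_is_case"`.
#' @return Object of class `roc_curve`: list with `curve` (tibble
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `direction`,
#'   `n_case`, `n_control`.
#' @export
roc_auc <- function(values, labels,
                    direction = c("lower_is_case", "higher_is_case")) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  is_case <- roc_case_indicator(labels)
  if (!any(is_case) || all(is_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  score <- if (direction == "lower_is_case") -values else values
  sc <- score[is_case]; sn <- score[!is_case]
  auc <- (sum(vapply(sc, function(s) sum(s > sn) + 0.5 * sum(s == sn),
                     numeric(1)))) / (length(sc) * length(sn))
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(sc >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(sn < t), numeric(1))
  )
  structure(list(curve = curve, auc = auc, direction = direction,
                 n_case = length(sc), n_control = length(sn)),
            class = "roc_curve")
}

roc_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(as.character(labels))
  if (length(lv) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if ("case" %in% tolower(lv)) {
    tolower(as.character(labels)) == "case"
  } else if ("TLE" %in% lv) {
    as.character(labels) == "TLE"
  } else {
    as.character(labels) == lv[2]
  }
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC = %.3f (%s), %d cases / %d controls>\n",
              x$auc, x$direction, x$n_case, x$n_control))
  invisible(x)
}

#' Single-hemisphere measurement selection
#'
#' Picks, per subject, the hemisphere expected to be closer to pathology:
#' the lower of the two values for FA, microscopic FA and volume, the higher
#' for MD. Applied to patients and controls alike. Exact ties resolve to the
#' left hemisphere.
#'
#' @param table Long cohort tibble (columns `subject_id`, `region`,
#'   `hemisphere`, `metric`, `value`).
#' @param region,metric Cell to select.
#' @return Tibble `subject_id`, `value`, `hemisphere`; subjects missing a
#'   hemisphere are dropped with a message.
#' @export
select_single_hemisphere <- function(table, region, metric) {
  wide <- hemi_pairs(table, region, metric)
  use_max <- metric == "md"
  pick_right <- if (use_max) wide$right > wide$left else wide$right < wide$left
  tibble::tibble(
    subject_id = wide$subject_id,
    value = ifelse(pick_right, wide$right, wide$left),
    hemisphere = ifelse(pick_right, "right", "left")
  )
}

hemi_pairs <- function(table, region, metric) {
  sub <- table[table$region == region & table$metric == metric, ]
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "hemisphere", "value")],
    names_from = "hemisphere", values_from = "value")
  if (!all(c("left", "right") %in% names(wide))) {
    stop("both hemispheres required for region ", region, call. = FALSE)
  }
  miss <- !stats::complete.cases(wide[, c("left", "right")])
  if (any(miss)) {
    message(sum(miss), " subject(s) dropped: missing a hemisphere for ",
            region, "/", metric)
  }
  wide[!miss, ]
}

#' Signed and absolute asymmetry indices
#'
#' `asymmetry_index()` is the signed contra-minus-ipsi percentage difference
#' `a = (x_contra - x_ipsi) / (0.5 (x_contra + x_ipsi)) * 100`, positive when
#' the ipsilateral value is reduced. `absolute_asymmetry()` is the unsigned
#' variant `|x_min - x_max| / (0.5 (x_max + x_min)) * 100` used where no
#' ipsilateral/contralateral distinction exists (healthy controls),
#' maximising the asymmetry so comparisons against patients are conservative.
#' Both are undefined (NA, with a warning) when the two values sum to <= 0.
#'
#' @param x_contra,x_ipsi,x1,x2 Numeric vectors (recycled pairwise).
#' @return Numeric vector of percentages.
#' @examples
#' asymmetry_index(0.51, 0.48) # 6.06
#' absolute_asymmetry(0.49, 0.45) # 8.51
#' @export
asymmetry_index <- function(x_contra, x_ipsi) {
  s <- x_contra + x_ipsi
  bad <- !is.na(s) & s <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive sum: asymmetry undefined",
            call. = FALSE)
  }
  out <- (x_contra - x_ipsi) / (0.5 * s) * 100
  out[bad] <- NA_real_
  out
}

#' @rdname asymmetry_index
#' @export
absolute_asymmetry <- function(x1, x2) {
  abs(asymmetry_index(pmax(x1, x2), pmin(x1, x2)))
}

#' Metric-based lateralization of the suspected seizure focus
#'
#' Predicts the pathological side per subject as the hemisphere with the
#' lower value for microscopic FA, FA and volume, or the higher value for MD,
#' and scores the predictions against the EEG-suspected side. Exact ties are
#' "indeterminate" and scored as incorrect (conservative).
#'
#' @param table Long cohort tibble including `suspected_side` metadata;
#'   only subjects with `suspected_side` of `"left"` or `"right"` enter.
#' @param region,metric Cell to lateralize on.
#' @return List with `predictions` (tibble `subject_id`, `suspected_side`,
#'   `predicted_side`, `correct`) and `accuracy` (fraction correct).
#' @export
lateralize <- function(table, region, metric) {
  uni <- table[table$suspected_side %in% c("left", "right"), ]
  if (!nrow(uni)) stop("no suspected-unilateral subjects", call. = FALSE)
  side <- unique(uni[, c("subject_id", "suspected_side")])
  wide <- hemi_pairs(uni, region, metric)
  use_max <- metric == "md"
  toward <- if (use_max) wide$left > wide$right else wide$left < wide$right
  pred <- ifelse(wide$left == wide$right, "indeterminate",
                 ifelse(toward, "left", "right"))
  out <- dplyr::left_join(
    tibble::tibble(subject_id = wide$subject_id, predicted_side = pred),
    side, by = "subject_id")
  out$correct <- out$predicted_side == out$suspected_side
  list(predictions = out[, c("subject_id", "suspected_side",
                             "predicted_side", "correct")],
       accuracy = mean(out$correct))
}
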