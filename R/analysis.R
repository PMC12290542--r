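#' Full cohort-level analysis
#'
#' Runs the complete statistical layer over a long cohort table: Mann-Whitney
#' group comparisons of bilateral means for every metric in the full
#' hippocampus (Bonferroni family of 4) and in the four merged subregions
#' (family of 16); Spearman correlations among the full-hippocampus metrics
#' within each cohort; ROC curves (bilateral and single-hemisphere) for
#' regions flagged by a significant group difference; Wilcoxon signed-rank
#' ipsilateral-versus-contralateral tests with signed asymmetry-index
#' summaries in the suspected-unilateral patient subgroup (absolute
#' asymmetries, descriptively, in controls); and metric-based lateralization
#' accuracy.
#'
#' @param cohort Long tibble with columns `subject_id`, `group` (`"TLE"` /
#'   `"HC"`), `suspected_side` (`"left"`, `"right"`, `"bilateral"`,
#'   `"none"`), `mr_status` (`"MR-positive"`, `"MR-negative"`, `"unknown"`),
#'   `region`, `hemisphere`, `metric`, `value`.
#' @param alpha Starting significance threshold (default 0.05).
#' @param mode Test mode passed to the rank tests (`"auto"`, `"exact"`,
#'   `"asymptotic"`).
#' @param mr_negative_only If `TRUE`, restrict the patient rows to
#'   MR-negative subjects before all analyses (sensitivity re-analysis).
#' @return Object of class `mufa_analysis`: list of tibbles `group_stats`,
#'   `spearman`, `roc`, `asymmetry_stats`, `asymmetry_summary`,
#'   `lateralization`, plus `config`.
#' @export
run_full_analysis <- function(cohort, alpha = 0.05,
                              mode = c("auto", "exact", "asymptotic"),
                              mr_negative_only = FALSE) {
  mode <- match.arg(mode)
  required <- c("subject_id", "group", "suspected_side", "mr_status",
                "region", "hemisphere", "metric", "value")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (mr_negative_only) {
    cohort <- cohort[cohort$group != "TLE" |
                       cohort$mr_status == "MR-negative", ]
  }
  metrics <- c("volume", "md", "fa", "ufa")
  subregions <- region_names(include_full = FALSE)
  meta <- unique(cohort[, c("subject_id", "group", "suspected_side",
                            "mr_status")])
  bil <- bilateral_mean(cohort)
  bil <- dplyr::left_join(bil, meta, by = "subject_id")

  ## --- group comparisons, two Bonferroni families -----------------------
  group_cell <- function(region, metric, m) {
    cell <- bil[bil$region == region & bil$metric == metric, ]
    res <- mann_whitney_u(cell$value[cell$group == "TLE"],
                          cell$value[cell$group == "HC"],
                          mode = mode,
                          alpha = bonferroni_threshold(alpha, m))
    tibble::tibble(family = if (m == 4) "full" else "subregion",
                   region = region, metric = metric, res)
  }
  group_stats <- dplyr::bind_rows(
    purrr::map_dfr(metrics, function(mt)
      group_cell("FullHippocampus", mt, 4)),
    purrr::map_dfr(subregions, function(rg)
      purrr::map_dfr(metrics, function(mt) group_cell(rg, mt, 16)))
  )

  ## --- Spearman matrix on full-hippocampus metrics, per cohort ----------
  full_wide <- tidyr::pivot_wider(
    bil[bil$region == "FullHippocampus",
        c("subject_id", "group", "metric", "value")],
    names_from = "metric", values_from = "value")
  pairs <- utils::combn(metrics, 2)
  spearman <- purrr::map_dfr(unique(full_wide$group), function(g) {
    gw <- full_wide[full_wide$group == g, ]
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      tibble::tibble(group = g, var1 = pairs[1, k], var2 = pairs[2, k],
                     spearman_rho(gw[[pairs[1, k]]], gw[[pairs[2, k]]]))
    })
  })

  ## --- ROC for flagged regions, bilateral and single-hemisphere ---------
  flagged <- unique(group_stats$region[group_stats$significant])
  roc <- purrr::map_dfr(flagged, function(rg) {
    purrr::map_dfr(metrics, function(mt) {
      dirn <- roc_direction(mt)
      cellb <- bil[bil$region == rg & bil$metric == mt, ]
      rb <- roc_auc(cellb$value, cellb$group == "TLE", dirn)
      single <- select_single_hemisphere(cohort, rg, mt)
      single <- dplyr::left_join(single, meta, by = "subject_id")
      rs <- roc_auc(single$value, single$group == "TLE", dirn)
      tibble::tibble(region = rg, metric = mt, direction = dirn,
                     mode = c("bilateral", "single_hemisphere"),
                     auc = c(rb$auc, rs$auc))
    })
  })

  ## --- ipsi/contra asymmetry in the suspected-unilateral subgroup -------
  uni_ids <- meta$subject_id[meta$group == "TLE" &
                               meta$suspected_side %in% c("left", "right")]
  uni <- cohort[cohort$subject_id %in% uni_ids, ]
  uni$side_rel <- ifelse(uni$hemisphere ==
                           meta$suspected_side[match(uni$subject_id,
                                                     meta$subject_id)],
                         "ipsi", "contra")
  asym_cell <- function(region, metric, m) {
    wide <- tidyr::pivot_wider(
      uni[uni$region == region & uni$metric == metric,
          c("subject_id", "side_rel", "value")],
      names_from = "side_rel", values_from = "value")
    res <- wilcoxon_signed_rank(wide$ipsi, wide$contra, mode = mode,
                                alpha = bonferroni_threshold(alpha, m))
    a <- asymmetry_index(wide$contra, wide$ipsi)
    tibble::tibble(family = if (m == 4) "full" else "subregion",
                   region = region, metric = metric, res,
                   mean_asymmetry = mean(a, na.rm = TRUE),
                   sd_asymmetry = stats::sd(a, na.rm = TRUE))
  }
  asymmetry_stats <- if (length(uni_ids)) dplyr::bind_rows(
    purrr::map_dfr(metrics, function(mt)
      asym_cell("FullHippocampus", mt, 4)),
    purrr::map_dfr(subregions, function(rg)
      purrr::map_dfr(metrics, function(mt) asym_cell(rg, mt, 16)))
  ) else tibble::tibble()

  ## --- descriptive asymmetry summaries (patients signed, controls |a|) --
  hc <- cohort[cohort$group == "HC", ]
  hc_abs <- purrr::map_dfr(unique(hc$region), function(rg) {
    purrr::map_dfr(metrics, function(mt) {
      wide <- tidyr::pivot_wider(
        hc[hc$region == rg & hc$metric == mt,
           c("subject_id", "hemisphere", "value")],
        names_from = "hemisphere", values_from = "value")
      a <- absolute_asymmetry(wide$left, wide$right)
      tibble::tibble(group = "HC", region = rg, metric = mt,
                     index = "absolute",
                     mean_asymmetry = mean(a, na.rm = TRUE),
                     sd_asymmetry = stats::sd(a, na.rm = TRUE),
                     n = sum(!is.na(a)))
    })
  })
  tle_signed <- if (nrow(asymmetry_stats)) {
    tibble::tibble(group = "TLE", region = asymmetry_stats$region,
                   metric = asymmetry_stats$metric, index = "signed",
                   mean_asymmetry = asymmetry_stats$mean_asymmetry,
                   sd_asymmetry = asymmetry_stats$sd_asymmetry,
                   n = asymmetry_stats$n1)
  } else tibble::tibble()
  asymmetry_summary <- dplyr::bind_rows(tle_signed, hc_abs)

  ## --- lateralization accuracy ------------------------------------------
  lateralization <- if (length(uni_ids)) {
    purrr::map_dfr(region_names(), function(rg) {
      purrr::map_dfr(metrics, function(mt) {
        lat <- lateralize(cohort, rg, mt)
        tibble::tibble(region = rg, metric = mt,
                       n = nrow(lat$predictions),
                       n_correct = sum(lat$predictions$correct),
                       accuracy = lat$accuracy)
      })
    })
  } else tibble::tibble()

  structure(list(group_stats = group_stats, spearman = spearman, roc = roc,
                 asymmetry_stats = asymmetry_stats,
                 asymmetry_summary = asymmetry_summary,
                 lateralization = lateralization,
                 config = list(alpha = alpha, mode = mode,
                               mr_negative_only = mr_negative_only,
                               n_tle = sum(meta$group == "TLE"),
                               n_hc = sum(meta$group == "HC"),
                               n_unilateral = length(uni_ids))),
            class = "mufa_analysis")
}

## expected disease direction per metric: anisotropy and volume drop,
## diffusivity rises
roc_direction <- function(metric) {
  if (metric == "md") "higher_is_case" else "lower_is_case"
}

#' @export
print.mufa_analysis <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mufa_analysis: %d TLE / %d HC (%d unilateral)%s>\n",
              cfg$n_tle, cfg$n_hc, cfg$n_unilateral,
              if (cfg$mr_negative_only) ", MR-negative only" else ""))
  sig <- x$group_stats[x$group_stats$significant, c("region", "metric")]
  if (nrow(sig)) {
    cat("significant group differences:",
        paste(paste0(sig$region, "/", sig$metric), collapse = ", "), "\n")
  } else cat("no significant group differences\n")
  invisible(x)
}

#' Tidy and summarise analysis results
#'
#' `tidy()` returns the statistical tests as one long tibble (group
#' comparisons and ipsi/contra asymmetry tests); `glance()` returns a
#' one-row summary of the run.
#'
#' @param x A `mufa_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mufa_analysis <- function(x, ...) {
  dplyr::bind_rows(
    x$group_stats,
    if (nrow(x$asymmetry_stats))
      dplyr::select(x$asymmetry_stats, -dplyr::any_of(c("mean_asymmetry",
                                                        "sd_asymmetry")))
  )
}

#' @rdname tidy.mufa_analysis
#' @export
glance.mufa_analysis <- function(x, ...) {
  tibble::tibble(
    n_tle = x$config$n_tle, n_hc = x$config$n_hc,
    n_unilateral = x$config$n_unilateral,
    n_tests = nrow(tidy.mufa_analysis(x)),
    n_significant = sum(tidy.mufa_analysis(x)$significant),
    alpha = x$config$alpha, mode = x$config$mode
  )
}

#' Broom-style tidiers for voxel fits
#'
#' `tidy()` on a `dti_fit` or `cumulant_fit` returns the fitted parameters
#' as a term/estimate tibble; `glance()` returns the derived scalar metrics.
#'
#' @param x A `dti_fit` or `cumulant_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dti_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lnS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"),
    estimate = c(x$lnS0, x$tensor[1, 1], x$tensor[2, 2], x$tensor[3, 3],
                 x$tensor[1, 2], x$tensor[1, 3], x$tensor[2, 3])
  )
}

#' @rdname tidy.dti_fit
#' @export
glance.dti_fit <- function(x, ...) {
  tibble::tibble(md = x$md, fa = x$fa, valid = x$valid)
}

#' @rdname tidy.dti_fit
#' @export
tidy.cumulant_fit <- function(x, ...) {
  tibble::tibble(term = c("lnS0", "d", "a_lte", "a_ste"),
                 estimate = c(x$lnS0, x$d, x$a_lte, x$a_ste))
}

#' @rdname tidy.dti_fit
#' @export
glance.cumulant_fit <- function(x, ...) {
  tibble::tibble(d = x$d, k_lte = x$k_lte, k_ste = x$k_ste, ufa = x$ufa,
                 valid = x$valid)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
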