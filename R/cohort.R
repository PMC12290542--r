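#' Cohort specification for summary-level simulation
#'
#' Describes a two-group (TLE patients versus healthy controls) cohort at
#' the level of printed summary statistics: per (group, region, metric)
#' means and SDs of the bilateral-mean measurement, and, for the
#' suspected-unilateral patient subgroup, separate ipsilateral and
#' contralateral means and SDs. [sample_summary_cohort()] draws subject-level
#' tables from this description.
#'
#' Hemisphere pairs are drawn from a bivariate normal (Gaussian copula) with
#' correlation `hemi_correlation`. For cells specified as bilateral means,
#' the per-hemisphere marginal SD is inflated to `sd * sqrt(2 / (1 + rho))`
#' so that the (left + right)/2 average reproduces the specified SD exactly.
#' Unilateral cells use the ipsi/contra means and SDs as the marginals
#' directly.
#'
#' @param n_tle,n_hc Group sizes (>= 2).
#' @param n_unilateral Number of patients with suspected unilateral disease
#'   (<= `n_tle`); the remainder are suspected bilateral.
#' @param n_left Of the unilateral patients, how many are left-sided.
#' @param n_mr_negative_unilateral MR-negative count within the unilateral
#'   subgroup.
#' @param hemi_correlation Within-subject left-right correlation, between -1 and 1.
#' @param cells Tibble with columns `group`, `region`, `metric`, `mean`,
#'   `sd`, `source`.
#' @param unilateral_cells Tibble with columns `region`, `metric`,
#'   `mean_ipsi`, `sd_ipsi`, `mean_contra`, `sd_contra`, `source`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tle, n_hc, n_unilateral, n_left,
                        n_mr_negative_unilateral, hemi_correlation,
                        cells, unilateral_cells) {
  stopifnot(n_tle >= 2, n_hc >= 2, n_unilateral <= n_tle,
            n_left <= n_unilateral,
            n_mr_negative_unilateral <= n_unilateral)
  if (abs(hemi_correlation) > 1) {
    stop("hemi_correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (any(cells$sd < 0) || any(unilateral_cells$sd_ipsi < 0) ||
      any(unilateral_cells$sd_contra < 0)) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  structure(list(n_tle = n_tle, n_hc = n_hc, n_unilateral = n_unilateral,
                 n_left = n_left,
                 n_mr_negative_unilateral = n_mr_negative_unilateral,
                 hemi_correlation = hemi_correlation,
                 cells = cells, unilateral_cells = unilateral_cells),
            class = "cohort_spec")
}

#' Default cohort specification
#'
#' Pre-filled description of a drug-resistant TLE study cohort: 19 patients
#' (15 suspected unilateral, 10 left-sided, 9 of the unilateral subgroup
#' MR-negative) and 18 healthy controls. The microscopic-FA cells carry the
#' group summaries reported for such cohorts (full hippocampus 0.49 +/- 0.03
#' TLE vs 0.52 +/- 0.03 HC; CA4/DG 0.47 +/- 0.03 vs 0.51 +/- 0.03;
#' unilateral CA4/DG ipsi 0.45 +/- 0.04 vs contra 0.49 +/- 0.02; unilateral
#' full hippocampus ipsi 0.48 +/- 0.04 vs contra 0.51 +/- 0.02), marked
#' `source = "reported"`. All other cells (MD, FA, volume, remaining
#' regions) are plausible defaults consistent with hippocampal values at 3T
#' and with the qualitative disease direction (MD up, FA/volume/uFA down
#' ipsilaterally and in patients); they are marked `source = "assumed"` and
#' should not be read as reproduced results.
#'
#' The within-subject hemisphere correlation is not identifiable from the
#' printed marginals; the default of 0.5 is a package choice that
#' lateralization accuracy is, deliberately, left sensitive to.
#'
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function() {
  regions <- region_names()
  grid <- function(group, metric, mean, sd, region = regions) {
    tibble::tibble(group = group, region = region, metric = metric,
                   mean = mean, sd = sd, source = "assumed")
  }
  cells <- dplyr::bind_rows(
    ## volumes (mm^3, per structure) -- assumed magnitudes, TLE ~3% lower
    grid("HC", "volume", c(700, 1300, 450, 650, 3100) ,
         c(700, 1300, 450, 650, 3100) * 0.12),
    grid("TLE", "volume", c(700, 1300, 450, 650, 3100) * 0.97,
         c(700, 1300, 450, 650, 3100) * 0.13),
    ## MD (um^2/ms): elevated in patients
    grid("HC", "md", 0.95, 0.05),
    grid("TLE", "md", 1.00, 0.07),
    ## FA: hippocampal values fall in the 0.1-0.2 range
    grid("HC", "fa", 0.17, 0.03),
    grid("TLE", "fa", 0.16, 0.03),
    ## uFA: reported cells for CA4/DG and full hippocampus
    grid("HC", "ufa", 0.52, 0.03, c("SB", "CA1", "CA2/3")),
    grid("TLE", "ufa", 0.50, 0.03, c("SB", "CA1", "CA2/3")),
    tibble::tibble(group = c("HC", "TLE", "HC", "TLE"),
                   region = c("CA4/DG", "CA4/DG", "FullHippocampus",
                              "FullHippocampus"),
                   metric = "ufa",
                   mean = c(0.51, 0.47, 0.52, 0.49),
                   sd = c(0.03, 0.03, 0.03, 0.03),
                   source = "reported")
  )
  ugrid <- function(metric, mi, si, mc, sc, region = regions,
                    source = "assumed") {
    tibble::tibble(region = region, metric = metric, mean_ipsi = mi,
                   sd_ipsi = si, mean_contra = mc, sd_contra = sc,
                   source = source)
  }
  unilateral_cells <- dplyr::bind_rows(
    ugrid("volume", c(700, 1300, 450, 650, 3100) * 0.94,
          c(700, 1300, 450, 650, 3100) * 0.13,
          c(700, 1300, 450, 650, 3100) * 1.00,
          c(700, 1300, 450, 650, 3100) * 0.12),
    ugrid("md", 1.02, 0.07, 0.98, 0.06),
    ugrid("fa", 0.155, 0.03, 0.16, 0.03),
    ugrid("ufa", 0.49, 0.04, 0.51, 0.03, c("SB", "CA1", "CA2/3")),
    ugrid("ufa", c(0.45, 0.48), c(0.04, 0.04), c(0.49, 0.51),
          c(0.02, 0.02), c("CA4/DG", "FullHippocampus"),
          source = "reported")
  )
  cohort_spec(n_tle = 19, n_hc = 18, n_unilateral = 15, n_left = 10,
              n_mr_negative_unilateral = 9, hemi_correlation = 0.5,
              cells = cells, unilateral_cells = unilateral_cells)
}

#' Draw a subject-level cohort from a summary specification
#'
#' Samples per-subject, per-hemisphere values for every (region, metric)
#' cell of the specification. Suspected-unilateral patients draw correlated
#' ipsilateral/contralateral pairs from the unilateral cells (the ipsi value
#' is assigned to the suspected hemisphere); all other subjects draw
#' symmetric hemisphere pairs whose bilateral mean matches the group cell.
#' Values outside the physical range (anisotropies outside 0..1,
#' non-positive MD or volume) are redrawn; redraw events are reported.
#' Identical seeds give identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Long cohort tibble with columns `subject_id`, `group`,
#'   `suspected_side`, `mr_status`, `region`, `hemisphere`, `metric`,
#'   `value`.
#' @export
sample_summary_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  rho <- spec$hemi_correlation
  n_trunc <- 0L

  ## n correlated pairs (columns) with per-side means/SDs, redrawing any
  ## pair outside the metric's physical range
  draw_pairs <- function(n, m1, s1, m2, s2, metric) {
    lo <- if (metric %in% c("fa", "ufa")) 0 else 1e-12
    hi <- if (metric %in% c("fa", "ufa")) 1 else Inf
    v1 <- v2 <- numeric(n)
    todo <- seq_len(n)
    for (k in 1:100) {
      z1 <- stats::rnorm(length(todo))
      z2 <- stats::rnorm(length(todo))
      v1[todo] <- m1 + s1 * z1
      v2[todo] <- m2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
      bad <- v1[todo] < lo | v1[todo] > hi | v2[todo] < lo | v2[todo] > hi
      n_trunc <<- n_trunc + sum(bad)
      todo <- todo[bad]
      if (!length(todo)) return(rbind(v1, v2))
    }
    stop("could not draw values inside the physical range for metric ",
         metric, call. = FALSE)
  }

  ids_tle <- sprintf("TLE%02d", seq_len(spec$n_tle))
  ids_hc <- sprintf("HC%02d", seq_len(spec$n_hc))
  sides <- c(rep("left", spec$n_left),
             rep("right", spec$n_unilateral - spec$n_left),
             rep("bilateral", spec$n_tle - spec$n_unilateral))
  mr <- c(rep("MR-negative", spec$n_mr_negative_unilateral),
          rep("MR-positive", spec$n_unilateral -
                spec$n_mr_negative_unilateral),
          rep("MR-positive", spec$n_tle - spec$n_unilateral))

  subj_meta <- tibble::tibble(
    subject_id = c(ids_tle, ids_hc),
    group = c(rep("TLE", spec$n_tle), rep("HC", spec$n_hc)),
    suspected_side = c(sides, rep("none", spec$n_hc)),
    mr_status = c(mr, rep("unknown", spec$n_hc))
  )
  unilateral <- subj_meta$suspected_side %in% c("left", "right")
  sd_inflate <- sqrt(2 / (1 + rho))

  blocks <- list()
  ## symmetric subjects: bilateral-mean cells, per group
  for (g in unique(spec$cells$group)) {
    ids <- subj_meta$subject_id[subj_meta$group == g & !unilateral]
    if (!length(ids)) next
    cells <- spec$cells[spec$cells$group == g, ]
    blocks[[paste0("sym_", g)]] <- purrr::pmap_dfr(cells, function(...) {
      cell <- list(...)
      v <- draw_pairs(length(ids), cell$mean, cell$sd * sd_inflate,
                      cell$mean, cell$sd * sd_inflate, cell$metric)
      tibble::tibble(subject_id = rep(ids, 2),
                     region = cell$region, metric = cell$metric,
                     hemisphere = rep(c("left", "right"), each = length(ids)),
                     value = c(v[1, ], v[2, ]))
    })
  }
  ## unilateral patients: ipsi/contra cells mapped onto the suspected side
  uni_ids <- subj_meta$subject_id[unilateral]
  if (length(uni_ids)) {
    ipsi_left <- subj_meta$suspected_side[unilateral] == "left"
    blocks$uni <- purrr::pmap_dfr(spec$unilateral_cells, function(...) {
      cell <- list(...)
      v <- draw_pairs(length(uni_ids), cell$mean_ipsi, cell$sd_ipsi,
                      cell$mean_contra, cell$sd_contra, cell$metric)
      tibble::tibble(subject_id = rep(uni_ids, 2),
                     region = cell$region, metric = cell$metric,
                     hemisphere = rep(c("left", "right"), each = length(uni_ids)),
                     value = c(ifelse(ipsi_left, v[1, ], v[2, ]),
                               ifelse(ipsi_left, v[2, ], v[1, ])))
    })
  }
  out <- dplyr::left_join(dplyr::bind_rows(blocks), subj_meta,
                          by = "subject_id")
  if (n_trunc > 0) {
    message(n_trunc, " draw(s) outside the physical range were redrawn")
  }
  out[order(match(out$subject_id, subj_meta$subject_id)),
      c("subject_id", "group", "suspected_side", "mr_status",
        "region", "hemisphere", "metric", "value")]
}
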