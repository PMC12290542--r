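#' Axisymmetric micro-tensor matching target MD and microscopic FA
#'
#' Inverts the closed-form cumulant relations to find the axial and radial
#' diffusivity of a cylindrically symmetric micro-environment whose mean
#' diffusivity and microscopic FA equal the targets: the anisotropy variance
#' is `dmu2 = 0.4 md^2 / (1.5 / ufa^2 - 1)`, the axial-radial difference
#' `delta = sqrt(45 dmu2 / 4)`, and `radial = md - delta / 3`.
#'
#' @param md Target mean diffusivity (um^2/ms).
#' @param ufa Target microscopic FA in `[0, 1)`; 0 gives an isotropic tensor.
#' @return List with `axial` and `radial` (um^2/ms).
#' @export
micro_tensor_for <- function(md, ufa) {
  stopifnot(md > 0, ufa >= 0, ufa < 1)
  if (ufa == 0) return(list(axial = md, radial = md))
  dmu2 <- 0.4 * md^2 / (1.5 / ufa^2 - 1)
  delta <- sqrt(45 * dmu2 / 4)
  radial <- md - delta / 3
  if (radial < 0) {
    stop("target (md, ufa) not reachable with a prolate tensor", call. = FALSE)
  }
  list(axial = radial + delta, radial = radial)
}

#' Two-hemisphere hippocampus phantom specification
#'
#' Defines a small block phantom with mirrored left/right hippocampi, each
#' split into the six subfield labels (SB, CA1, CA2, CA3, CA4, DG) so the
#' merge rules are exercised. Every voxel of a merged region shares the
#' region's substrate recipe: identical axisymmetric micro-tensors whose
#' orientations follow `orientation_rule` (`"coherent"`, `"crossing-90"` or
#' `"dispersed"`, the last emulating the crossing/fanning fibres of
#' hippocampal grey matter), optionally mixed with an isotropic (CSF-like)
#' compartment. Pathology is a microscopic-anisotropy reduction: on the
#' affected side the radial diffusivity of the affected regions' micro-
#' tensors is scaled up until the ground-truth microscopic FA drops by
#' `ufa_reduction` (mimicking gliosis and axon loss, which also raises MD).
#'
#' @param voxel_size Isotropic voxel edge (mm).
#' @param region_md,region_ufa Named vectors (per merged region) of target
#'   mean diffusivity and microscopic FA.
#' @param orientation_rule `"dispersed"`, `"coherent"` or `"crossing-90"`.
#' @param n_orientations Orientation count for the dispersed rule.
#' @param iso_fraction,iso_diffusivity Optional isotropic compartment.
#' @param affected_side `"left"`, `"right"` or `"none"`.
#' @param affected_regions Merged regions carrying pathology.
#' @param ufa_reduction Ground-truth microscopic FA drop in affected regions.
#' @param s0 Baseline signal amplitude.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 1.8,
                         region_md = c(SB = 0.80, CA1 = 0.80,
                                       `CA2/3` = 0.80, `CA4/DG` = 0.80),
                         region_ufa = c(SB = 0.52, CA1 = 0.52,
                                        `CA2/3` = 0.52, `CA4/DG` = 0.51),
                         orientation_rule = "dispersed",
                         n_orientations = 60,
                         iso_fraction = 0, iso_diffusivity = 3.0,
                         affected_side = "left",
                         affected_regions = "CA4/DG",
                         ufa_reduction = 0.05,
                         s0 = 1) {
  orientation_rule <- match.arg(orientation_rule,
                                c("dispersed", "coherent", "crossing-90"))
  affected_side <- match.arg(affected_side, c("left", "right", "none"))
  regions <- region_names(include_full = FALSE)
  stopifnot(all(regions %in% names(region_md)),
            all(regions %in% names(region_ufa)),
            all(affected_regions %in% regions),
            iso_fraction >= 0, iso_fraction < 1,
            ufa_reduction >= 0, s0 > 0, voxel_size > 0)
  structure(list(voxel_size = voxel_size, region_md = region_md,
                 region_ufa = region_ufa,
                 orientation_rule = orientation_rule,
                 n_orientations = n_orientations,
                 iso_fraction = iso_fraction,
                 iso_diffusivity = iso_diffusivity,
                 affected_side = affected_side,
                 affected_regions = affected_regions,
                 ufa_reduction = ufa_reduction, s0 = s0),
            class = "phantom_spec")
}

## substrate for one region recipe; `radial_scale` > 1 applies pathology
region_substrate <- function(spec, region, radial_scale = 1) {
  mt <- micro_tensor_for(spec$region_md[[region]], spec$region_ufa[[region]])
  ax <- mt$axial
  rad <- mt$radial * radial_scale
  f_aniso <- 1 - spec$iso_fraction
  comps <- switch(
    spec$orientation_rule,
    coherent = list(diffusion_compartment(
      axisymmetric_tensor(ax, rad, c(1, 0, 0)), fraction = f_aniso)),
    `crossing-90` = list(
      diffusion_compartment(axisymmetric_tensor(ax, rad, c(1, 0, 0)),
                            fraction = f_aniso / 2),
      diffusion_compartment(axisymmetric_tensor(ax, rad, c(0, 1, 0)),
                            fraction = f_aniso / 2)),
    dispersed = {
      dirs <- fibonacci_directions(spec$n_orientations)
      lapply(seq_len(nrow(dirs)), function(i) {
        diffusion_compartment(axisymmetric_tensor(ax, rad, dirs[i, ]),
                              fraction = f_aniso / nrow(dirs))
      })
    })
  if (spec$iso_fraction > 0) {
    comps <- c(comps, list(diffusion_compartment(
      diag(spec$iso_diffusivity, 3), fraction = spec$iso_fraction)))
  }
  voxel_substrate(comps, s0 = spec$s0)
}

## radial scaling that lowers the region's ground-truth uFA by the target;
## the search stops at the isotropic point (radial = axial), beyond which
## the tensor turns oblate and anisotropy rises again
solve_radial_scale <- function(spec, region) {
  target <- substrate_truth(region_substrate(spec, region))$ufa -
    spec$ufa_reduction
  if (target <= 0) stop("ufa_reduction too large for region ", region,
                        call. = FALSE)
  mt <- micro_tensor_for(spec$region_md[[region]], spec$region_ufa[[region]])
  s_iso <- mt$axial / mt$radial
  f <- function(s) substrate_truth(region_substrate(spec, region, s))$ufa -
    target
  stats::uniroot(f, c(1, s_iso), tol = 1e-8)$root
}

#' Build a hippocampus phantom
#'
#' Lays out two mirrored hippocampus blocks on a 12 x 12 x 6 voxel grid,
#' assigns each merged region its substrate (with pathology applied on the
#' affected side) and computes the analytic ground-truth MD, FA and
#' microscopic FA maps from the closed-form cumulants.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `hippo_phantom`: list with `labels_left`,
#'   `labels_right` ([label_volume()]), `substrates` (named
#'   `side/region` list), `region_voxels` (same keys), `truth`
#'   (`scalar_maps`), `mask`, `grid`, `spec`.
#' @export
build_hippocampus_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- c(12L, 12L, 6L)
  codes <- hippunfold_labels()
  lab_l <- lab_r <- array(0L, grid)
  ## subfield slabs along y: SB, CA1 two rows each; CA2..DG one row each
  ybands <- list(SB = 3:4, CA1 = 5:6, CA2 = 7, CA3 = 8, CA4 = 9, DG = 10)
  for (nm in names(ybands)) {
    lab_l[2:5, ybands[[nm]], 2:5] <- codes[[nm]]
    lab_r[8:11, ybands[[nm]], 2:5] <- codes[[nm]]
  }
  vs <- rep(spec$voxel_size, 3)
  labels_left <- label_volume(lab_l, vs, "left")
  labels_right <- label_volume(lab_r, vs, "right")

  merged <- list(left = merge_labels(labels_left),
                 right = merge_labels(labels_right))
  regions <- region_names(include_full = FALSE)
  substrates <- list()
  region_voxels <- list()
  md <- fa <- ufa <- array(NA_real_, grid)
  mask <- array(FALSE, grid)
  for (side in c("left", "right")) {
    for (rg in regions) {
      scale <- if (side == spec$affected_side &&
                   rg %in% spec$affected_regions &&
                   spec$ufa_reduction > 0)
        solve_radial_scale(spec, rg) else 1
      sub <- region_substrate(spec, rg, scale)
      truth <- substrate_truth(sub)
      vox <- merged[[side]][[rg]]
      key <- paste(side, rg, sep = "/")
      substrates[[key]] <- sub
      region_voxels[[key]] <- vox
      md[vox] <- truth$md
      fa[vox] <- truth$fa
      ufa[vox] <- truth$ufa
      mask[vox] <- TRUE
    }
  }
  truth_maps <- structure(list(md = md, fa = fa, ufa = ufa, mask = mask,
                               voxel_size = vs, n_invalid = 0L),
                          class = "scalar_maps")
  structure(list(labels_left = labels_left, labels_right = labels_right,
                 substrates = substrates, region_voxels = region_voxels,
                 truth = truth_maps, mask = mask, grid = grid, spec = spec),
            class = "hippo_phantom")
}

#' @export
print.hippo_phantom <- function(x, ...) {
  cat(sprintf("<hippo_phantom: %s grid, %d tissue voxels, pathology %s/%s>\n",
              paste(x$grid, collapse = "x"), sum(x$mask),
              x$spec$affected_side,
              paste(x$spec$affected_regions, collapse = "+")))
  invisible(x)
}

#' Simulate the two-protocol acquisition of a phantom subject
#'
#' Generates noise-free signals for every tissue voxel of the phantom under
#' the DTI and microscopic-FA schemes (voxels of the same region share the
#' same noise-free signal, computed once), then applies Rician noise at the
#' requested SNR (`s0 / sigma` at b = 0; `snr = Inf` for noise-free data).
#'
#' @param phantom A [build_hippocampus_phantom()] result.
#' @param scheme_dti,scheme_ufa Acquisition schemes.
#' @param snr Signal-to-noise ratio at b = 0 (> 0, possibly `Inf`).
#' @param seed Integer seed for the noise streams (the two protocols use
#'   `seed` and `seed + 500000`).
#' @return List with `dwi_dti`, `dwi_ufa` ([dwi_dataset()]) and `mask`.
#' @export
simulate_subject_dataset <- function(phantom,
                                     scheme_dti = dti_scheme(),
                                     scheme_ufa = ufa_scheme(),
                                     snr = 50, seed = 1L) {
  stopifnot(inherits(phantom, "hippo_phantom"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0) {
    stop("snr must be positive (use Inf for noise-free data)", call. = FALSE)
  }
  grid <- phantom$grid
  sim_one <- function(scheme, sub_seed) {
    arr <- array(0, c(grid, nrow(scheme)))
    m <- matrix(arr, ncol = nrow(scheme))
    for (key in names(phantom$substrates)) {
      sig <- generate_signal(phantom$substrates[[key]], scheme)
      vox <- phantom$region_voxels[[key]]
      m[vox, ] <- matrix(sig, length(vox), length(sig), byrow = TRUE)
    }
    if (is.finite(snr)) {
      sigma <- phantom$spec$s0 / snr
      tissue <- which(phantom$mask)
      m[tissue, ] <- add_rician_noise(m[tissue, , drop = FALSE], sigma,
                                      seed = sub_seed)
    }
    dwi_dataset(array(m, c(grid, nrow(scheme))), scheme,
                rep(phantom$spec$voxel_size, 3))
  }
  list(dwi_dti = sim_one(scheme_dti, seed),
       dwi_ufa = sim_one(scheme_ufa, seed + 500000),
       mask = phantom$mask)
}

#' Simulate a suspected-unilateral phantom cohort through the full pipeline
#'
#' Runs simulate -> fit -> ROI aggregation for `n_subjects` phantom subjects
#' sharing one pathology specification (noise differs per subject), and
#' returns the long cohort table the statistics layer consumes. This is the
#' end-to-end harness used to check that a built-in ipsilateral
#' microscopic-FA reduction is recovered by the asymmetry analysis.
#'
#' @param n_subjects Number of patients.
#' @param spec A [phantom_spec()]; its `affected_side` sets every subject's
#'   suspected side.
#' @param snr Acquisition SNR.
#' @param seed Integer seed; subject `i` uses `seed + 1000 * i`.
#' @inheritParams simulate_subject_dataset
#' @param max_b DTI b-value cut-off (ms/um^2).
#' @return Long cohort tibble (columns as in [sample_summary_cohort()]).
#' @export
simulate_phantom_cohort <- function(n_subjects = 15, spec = phantom_spec(),
                                    snr = 50, seed = 1L,
                                    scheme_dti = dti_scheme(),
                                    scheme_ufa = ufa_scheme(),
                                    max_b = 1.0) {
  phantom <- build_hippocampus_phantom(spec)
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    ds <- simulate_subject_dataset(phantom, scheme_dti, scheme_ufa,
                                   snr = snr, seed = seed + 1000 * i)
    maps <- compute_maps(ds$dwi_dti, ds$dwi_ufa, ds$mask, max_b = max_b)
    tab <- subject_region_table(maps, phantom$labels_left,
                                phantom$labels_right,
                                subject_id = sprintf("P%02d", i))
    tab$group <- "TLE"
    tab$suspected_side <- spec$affected_side
    tab$mr_status <- "MR-negative"
    tab[, c("subject_id", "group", "suspected_side", "mr_status",
            "region", "hemisphere", "metric", "value", "n_voxels")]
  })
}
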