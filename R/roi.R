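#' Hippocampal subfield label volumes
#'
#' Wraps a 3D integer label image with its voxel size, hemisphere and the
#' code-to-name lookup. The default lookup follows the HippUnfold discrete
#' segmentation (dseg) convention shipped as a versioned fixture
#' (`inst/extdata/hippunfold_dseg_labels.tsv`): 1 = SB, 2 = CA1, 3 = CA2,
#' 4 = CA3, 5 = CA4, 6 = DG, 0 = background.
#'
#' @param labels 3D integer array of subfield codes.
#' @param voxel_size Length-3 voxel edge lengths in mm (> 0).
#' @param hemisphere `"left"` or `"right"`.
#' @param label_scheme Named integer vector mapping subfield name to code;
#'   default [hippunfold_labels()].
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, hemisphere,
                         label_scheme = hippunfold_labels()) {
  stopifnot(length(dim(labels)) == 3)
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  }
  structure(list(labels = labels, voxel_size = voxel_size,
                 hemisphere = hemisphere, label_scheme = label_scheme),
            class = "label_volume")
}

#' @rdname label_volume
#' @export
hippunfold_labels <- function() {
  path <- system.file("extdata", "hippunfold_dseg_labels.tsv",
                      package = "microfa", mustWork = TRUE)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(tb$code), tb$name)
}

#' Merged subfield region scheme
#'
#' The analysis regions are the ILAE-sclerosis-motivated merge of the six
#' subfields: SB and CA1 stay separate, CA2 and CA3 are pooled (their cell
#' loss is inconsistent across sclerosis subtypes), CA4 is pooled with the
#' adjacent DG, and the full hippocampus is the union of all six.
#'
#' @return Named list mapping region name to subfield names.
#' @export
region_scheme <- function() {
  list(SB = "SB", CA1 = "CA1", `CA2/3` = c("CA2", "CA3"),
       `CA4/DG` = c("CA4", "DG"),
       FullHippocampus = c("SB", "CA1", "CA2", "CA3", "CA4", "DG"))
}

#' Region names of the merged scheme
#' @param include_full Include the full hippocampus.
#' @return Character vector.
#' @export
region_names <- function(include_full = TRUE) {
  r <- names(region_scheme())
  if (include_full) r else setdiff(r, "FullHippocampus")
}

#' Merge subfield labels into analysis regions
#'
#' Pools the voxel index sets of the subfield codes into the merged regions
#' of [region_scheme()]. Nonzero codes absent from the label scheme trigger a
#' warning and are excluded (counted in the `n_unknown` attribute).
#'
#' @param volume A [label_volume()].
#' @param scheme Region scheme, default [region_scheme()].
#' @return Named list of integer voxel indices (into the flattened label
#'   array), one element per region, with attribute `n_unknown`.
#' @export
merge_labels <- function(volume, scheme = region_scheme()) {
  stopifnot(inherits(volume, "label_volume"))
  codes <- volume$label_scheme
  lab <- as.integer(volume$labels)
  known <- c(0L, unname(codes))
  unknown <- !(lab %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " voxel(s) with unknown label codes excluded: ",
            paste(unique(lab[unknown]), collapse = ", "), call. = FALSE)
  }
  out <- lapply(scheme, function(subfields) {
    which(lab %in% codes[subfields])
  })
  attr(out, "n_unknown") <- sum(unknown)
  out
}

#' Mean of a scalar map over a region
#'
#' Arithmetic mean over the region voxels that fall inside the map mask.
#' Voxels invalidated by the fits are excluded through the mask; the
#' difference between the region size and the contributing count is reported
#' so masked-out voxels are visible downstream.
#'
#' @param map 3D numeric array.
#' @param region_voxels Integer voxel indices.
#' @param mask Optional 3D logical array.
#' @return List with `mean`, `n_voxels` (contributing) and `n_region` (total
#'   region size); `mean` is `NA` when the intersection is empty.
#' @export
region_mean <- function(map, region_voxels, mask = NULL) {
  idx <- region_voxels
  if (!is.null(mask)) idx <- idx[mask[idx]]
  if (!length(idx)) {
    return(list(mean = NA_real_, n_voxels = 0L,
                n_region = length(region_voxels)))
  }
  list(mean = mean(map[idx]), n_voxels = length(idx),
       n_region = length(region_voxels))
}

#' Voxel-count volume of a region
#'
#' @param volume A [label_volume()] (supplies the voxel size).
#' @param region_voxels Integer voxel indices.
#' @return List with `n_voxels` and `volume_mm3` (count times voxel volume).
#' @export
region_volume <- function(volume, region_voxels) {
  n <- length(region_voxels)
  list(n_voxels = n, volume_mm3 = n * prod(volume$voxel_size))
}

#' Per-subject region/hemisphere metric table
#'
#' Computes, for one subject, the mean MD, FA and microscopic FA plus the
#' voxel-count volume of every merged region in each hemisphere, as a long
#' tibble (the unit the cohort statistics consume).
#'
#' @param maps A [compute_maps()] result (or any list with `md`, `fa`, `ufa`,
#'   `mask` arrays). Regions are assumed co-registered with the maps; volumes
#'   are counted on the label grid.
#' @param labels_left,labels_right [label_volume()] objects.
#' @param subject_id Subject identifier.
#' @return Tibble with columns `subject_id`, `region`, `hemisphere`,
#'   `metric` (`volume`, `md`, `fa`, `ufa`), `value`, `n_voxels`.
#' @export
subject_region_table <- function(maps, labels_left, labels_right,
                                 subject_id = "subj") {
  one_hemi <- function(labvol, hemi) {
    regions <- merge_labels(labvol)
    purrr::map_dfr(names(regions), function(rn) {
      idx <- regions[[rn]]
      vol <- region_volume(labvol, idx)
      mdm <- region_mean(maps$md, idx, maps$mask)
      fam <- region_mean(maps$fa, idx, maps$mask)
      ufm <- region_mean(maps$ufa, idx, maps$mask)
      tibble::tibble(
        subject_id = subject_id, region = rn, hemisphere = hemi,
        metric = c("volume", "md", "fa", "ufa"),
        value = c(vol$volume_mm3, mdm$mean, fam$mean, ufm$mean),
        n_voxels = c(vol$n_voxels, mdm$n_voxels, fam$n_voxels, ufm$n_voxels)
      )
    })
  }
  dplyr::bind_rows(one_hemi(labels_left, "left"),
                   one_hemi(labels_right, "right"))
}

#' Bilateral (two-hemisphere) means
#'
#' Averages the left and right values of each (subject, region, metric) cell:
#' `(left + right) / 2`. Cells missing a hemisphere yield `NA` and are
#' reported with a message.
#'
#' @param table Long tibble with columns `subject_id`, `region`,
#'   `hemisphere`, `metric`, `value`.
#' @return Tibble with columns `subject_id`, `region`, `metric`, `value`.
#' @export
bilateral_mean <- function(table) {
  wide <- tidyr::pivot_wider(
    dplyr::select(table, dplyr::all_of(c("subject_id", "region", "hemisphere",
                                         "metric", "value"))),
    names_from = "hemisphere", values_from = "value")
  if (!all(c("left", "right") %in% names(wide))) {
    wide$left <- if ("left" %in% names(wide)) wide$left else NA_real_
    wide$right <- if ("right" %in% names(wide)) wide$right else NA_real_
  }
  miss <- !stats::complete.cases(wide[, c("left", "right")])
  if (any(miss)) {
    message(sum(miss), " (subject, region, metric) cell(s) missing a hemisphere")
  }
  dplyr::transmute(wide, subject_id = .data$subject_id,
                   region = .data$region, metric = .data$metric,
                   value = (.data$left + .data$right) / 2)
}
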