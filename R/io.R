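## File-format boundary: NIfTI-1 volumes via RNifti, FSL-dialect bval/bvec,
## a plain-text .shape sidecar (one LTE/STE token per volume), and TSV
## tables. Units convert at this boundary only: b-values are s/mm^2 on disk
## and ms/um^2 in memory. Gradient directions are taken as given in the
## image coordinate frame of the accompanying NIfTI; no gradient-frame
## flipping heuristics are applied, so callers must pre-harmonize frames.

#' Read an acquisition scheme from FSL-dialect sidecars
#'
#' Parses `.bval` (one whitespace-separated row, s/mm^2), `.bvec` (three
#' rows of direction components) and `.shape` (one `LTE`/`STE` token per
#' volume). b-values are converted to ms/um^2 and clustered into shells
#' with a tolerance of `shell_tolerance_smm2` (default 50 s/mm^2).
#'
#' @param bval,bvec,shape File paths.
#' @param shell_tolerance_smm2 Shell clustering tolerance in s/mm^2.
#' @return An [acquisition_scheme()].
#' @export
read_gradient_scheme <- function(bval, bvec, shape,
                                 shell_tolerance_smm2 = 50) {
  b <- scan(bval, quiet = TRUE)
  g <- matrix(scan(bvec, quiet = TRUE), nrow = 3, byrow = TRUE)
  tok <- scan(shape, what = character(), quiet = TRUE)
  if (ncol(g) != length(b) || length(tok) != length(b)) {
    stop(sprintf(
      "sidecar volume counts disagree: %d b-values, %d directions, %d shape tokens",
      length(b), ncol(g), length(tok)), call. = FALSE)
  }
  if (!all(tok %in% c("LTE", "STE"))) {
    stop("unknown shape token(s): ",
         paste(setdiff(unique(tok), c("LTE", "STE")), collapse = ", "),
         call. = FALSE)
  }
  acquisition_scheme(b / 1000, tok, t(g),
                     shell_tolerance = shell_tolerance_smm2 / 1000)
}

#' @rdname read_gradient_scheme
#' @param scheme An [acquisition_scheme()] to write.
#' @param prefix Output path prefix; writes `<prefix>.bval`, `.bvec`,
#'   `.shape`.
#' @export
write_gradient_scheme <- function(scheme, prefix) {
  writeLines(paste(format(scheme$b * 1000, trim = TRUE, scientific = FALSE),
                   collapse = " "), paste0(prefix, ".bval"))
  g <- t(as.matrix(scheme[, c("gx", "gy", "gz")]))
  g[is.na(g)] <- 0
  writeLines(apply(g, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(prefix, ".bvec"))
  writeLines(paste(scheme$shape, collapse = " "), paste0(prefix, ".shape"))
  invisible(prefix)
}

nifti_with_voxels <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  img
}

#' Read and write 4D diffusion datasets
#'
#' `write_dwi_dataset()` writes `<prefix>.nii.gz` plus the three sidecars;
#' `read_dwi_dataset()` reads them back.
#'
#' @param ds A [dwi_dataset()].
#' @param prefix Path prefix (no extension).
#' @return The prefix (write) or a `dwi_dataset` (read).
#' @export
write_dwi_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "dwi_dataset"))
  RNifti::writeNifti(nifti_with_voxels(ds$data, c(ds$voxel_size, 1)),
                     paste0(prefix, ".nii.gz"))
  write_gradient_scheme(ds$scheme, prefix)
  invisible(prefix)
}

#' @rdname write_dwi_dataset
#' @export
read_dwi_dataset <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  scheme <- read_gradient_scheme(paste0(prefix, ".bval"),
                                 paste0(prefix, ".bvec"),
                                 paste0(prefix, ".shape"))
  dwi_dataset(unclass(img)[, , , , drop = FALSE], scheme,
              RNifti::pixdim(img)[1:3])
}

#' Read and write 3D volumes (labels, scalar maps)
#'
#' Thin NIfTI-1 wrappers preserving voxel size. Label images are rounded to
#' integer codes on read.
#'
#' @param arr 3D array.
#' @param path Output `.nii.gz` path.
#' @param voxel_size Length-3 mm.
#' @export
write_volume <- function(arr, path, voxel_size = c(1, 1, 1)) {
  RNifti::writeNifti(nifti_with_voxels(arr, voxel_size), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = unclass(img)[, , , drop = TRUE],
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @param hemisphere `"left"` or `"right"`.
#' @param label_scheme Code lookup, default [hippunfold_labels()].
#' @export
read_label_volume <- function(path, hemisphere,
                              label_scheme = hippunfold_labels()) {
  v <- read_volume(path)
  label_volume(array(as.integer(round(v$data)), dim(v$data)),
               v$voxel_size, hemisphere, label_scheme)
}

#' Write scalar maps to NIfTI
#'
#' Writes `md.nii.gz`, `fa.nii.gz`, `ufa.nii.gz` and `mask.nii.gz` into a
#' directory.
#'
#' @param maps A [compute_maps()] result.
#' @param dir Output directory (created if missing).
#' @export
write_scalar_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("md", "fa", "ufa")) {
    arr <- maps[[nm]]
    arr[is.na(arr)] <- 0
    write_volume(arr, file.path(dir, paste0(nm, ".nii.gz")),
                 maps$voxel_size)
  }
  write_volume(maps$mask + 0L, file.path(dir, "mask.nii.gz"),
               maps$voxel_size)
  invisible(dir)
}

#' @rdname write_scalar_maps
#' @export
read_scalar_maps <- function(dir) {
  rd <- function(nm) read_volume(file.path(dir, paste0(nm, ".nii.gz")))
  mask <- rd("mask")
  maps <- lapply(c(md = "md", fa = "fa", ufa = "ufa"), function(nm) {
    a <- rd(nm)$data
    a[mask$data == 0] <- NA_real_
    a
  })
  structure(c(maps, list(mask = mask$data > 0, voxel_size = mask$voxel_size,
                         n_invalid = NA_integer_)),
            class = "scalar_maps")
}

#' Cohort and result tables on disk
#'
#' TSV readers/writers with fixed, documented column orders. The cohort
#' table is long: one row per subject x region x hemisphere x metric plus
#' the subject metadata columns.
#'
#' @param cohort,path Table and file path.
#' @export
write_cohort_table <- function(cohort, path) {
  cols <- c("subject_id", "group", "suspected_side", "mr_status",
            "region", "hemisphere", "metric", "value")
  extra <- intersect("n_voxels", names(cohort))
  readr::write_tsv(cohort[, c(cols, extra)], path)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", group = "c", suspected_side = "c",
                    mr_status = "c", region = "c", hemisphere = "c",
                    metric = "c", value = "d", .default = "?"))
}

#' Write the result bundle of [run_full_analysis()]
#'
#' Writes `stats.tsv` (group and asymmetry tests), `asymmetry.tsv`,
#' `roc.tsv` and `lateralization.tsv` into a directory.
#'
#' @param analysis A `mufa_analysis` object.
#' @param dir Output directory.
#' @export
write_analysis_results <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(analysis), file.path(dir, "stats.tsv"))
  readr::write_tsv(analysis$asymmetry_summary,
                   file.path(dir, "asymmetry.tsv"))
  readr::write_tsv(analysis$roc, file.path(dir, "roc.tsv"))
  if (nrow(analysis$lateralization)) {
    readr::write_tsv(analysis$lateralization,
                     file.path(dir, "lateralization.tsv"))
  }
  invisible(dir)
}
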