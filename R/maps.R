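#' In-memory 4D diffusion-weighted dataset
#'
#' Couples a 4D signal array with the acquisition scheme describing its
#' volumes and the voxel size. This is the unit the voxelwise fitting stage
#' consumes; [read_dwi_dataset()] / [write_dwi_dataset()] move it to and from
#' NIfTI-1 plus FSL-dialect sidecars.
#'
#' @param data 4D numeric array, volumes along the 4th dimension.
#' @param scheme An [acquisition_scheme()] with one row per volume.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @return Object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(data, scheme, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != nrow(scheme)) {
    stop(sprintf("scheme has %d volumes but data has %d", nrow(scheme),
                 dim(data)[4]), call. = FALSE)
  }
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_dataset: %dx%dx%d grid, %d volumes, voxel %s mm>\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Voxelwise scalar maps from the two-protocol fit
#'
#' Applies [fit_dti_wlls()] (MD, FA; volumes with b above `max_b` excluded)
#' and the joint powder-average kurtosis fit (microscopic FA) to every voxel
#' inside the mask. The two datasets must be co-registered on a common grid;
#' registration is the caller's concern. Voxels where either fit is invalid
#' (non-positive signals or fitted diffusivity) are removed from the output
#' mask and counted.
#'
#' @param dwi_dti,dwi_ufa [dwi_dataset()] objects on the same grid.
#' @param mask 3D logical array (default: whole grid).
#' @param max_b DTI b-value cut-off in ms/um^2.
#' @return Object of class `scalar_maps`: list with 3D arrays `md`, `fa`,
#'   `ufa`, logical `mask`, `voxel_size` and `n_invalid`.
#' @export
compute_maps <- function(dwi_dti, dwi_ufa, mask = NULL, max_b = 1.0) {
  stopifnot(inherits(dwi_dti, "dwi_dataset"), inherits(dwi_ufa, "dwi_dataset"))
  grid <- dim(dwi_dti$data)[1:3]
  if (!identical(grid, dim(dwi_ufa$data)[1:3])) {
    stop("DTI and uFA datasets are not on a common grid", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!identical(dim(mask), grid)) {
    stop("mask grid does not match the data grid", call. = FALSE)
  }
  vox <- which(mask)
  md <- fa <- ufa <- array(NA_real_, grid)
  out_mask <- array(FALSE, grid)
  n_invalid <- 0L
  if (length(vox)) {
    nvol_dti <- dim(dwi_dti$data)[4]
    nvol_ufa <- dim(dwi_ufa$data)[4]
    sig_dti <- matrix(dwi_dti$data, ncol = nvol_dti)[vox, , drop = FALSE]
    sig_ufa <- matrix(dwi_ufa$data, ncol = nvol_ufa)[vox, , drop = FALSE]
    dti_fits <- fit_dti_wlls_many(sig_dti, dwi_dti$scheme, max_b)
    ufa_fits <- fit_powder_kurtosis_many(sig_ufa, dwi_ufa$scheme)
    ok <- dti_fits$valid & ufa_fits$valid
    n_invalid <- sum(!ok)
    if (n_invalid > 0) {
      message(n_invalid, " voxel(s) with invalid fits removed from mask")
    }
    md[vox] <- ifelse(ok, dti_fits$md, NA_real_)
    fa[vox] <- ifelse(ok, dti_fits$fa, NA_real_)
    ufa[vox] <- ifelse(ok, ufa_fits$ufa, NA_real_)
    out_mask[vox] <- ok
  }
  structure(list(md = md, fa = fa, ufa = ufa, mask = out_mask,
                 voxel_size = dwi_dti$voxel_size, n_invalid = n_invalid),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("<scalar_maps: %s grid, %d voxels in mask, %d invalid>\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask), x$n_invalid))
  invisible(x)
}

## vectorised two-pass WLLS DTI across voxels (rows of `signals`)
fit_dti_wlls_many <- function(signals, scheme, max_b = 1.0) {
  keep <- scheme$shape == "LTE" & scheme$b <= max_b
  X <- dti_design(scheme[keep, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient DTI design", call. = FALSE)
  }
  s <- signals[, keep, drop = FALSE]
  n <- nrow(s)
  md <- fa <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  ok_sig <- rowSums(!is.finite(s) | s <= 0) == 0
  for (v in which(ok_sig)) {
    y <- log(s[v, ])
    beta <- qr.coef(qr(X), y)
    w <- exp(X %*% beta)[, 1]^2
    fit <- dti_fit_from_beta(wls_solve(X, y, w))
    md[v] <- fit$md
    fa[v] <- fit$fa
    valid[v] <- fit$valid
  }
  list(md = md, fa = fa, valid = valid)
}

## vectorised joint powder kurtosis fit across voxels
fit_powder_kurtosis_many <- function(signals, scheme) {
  pa <- powder_average(signals, scheme)
  shells <- pa$shells
  b <- shells$b
  is_lte <- as.numeric(shells$shape == "LTE")
  X <- cbind(1, -b, b^2 * is_lte, b^2 * (1 - is_lte))
  ndir <- shells$n_directions
  n <- nrow(signals)
  d <- k_lte <- k_ste <- ufa <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  ms <- pa$mean_signal
  ok_sig <- rowSums(!is.finite(ms) | ms <= 0) == 0
  for (v in which(ok_sig)) {
    s <- ms[v, ]
    y <- log(s)
    beta <- wls_solve(X, y, ndir * s^2)
    w <- ndir * exp(X %*% beta)[, 1]^2
    beta <- wls_solve(X, y, w)
    if (!is.finite(beta[2]) || beta[2] <= 0) next
    d[v] <- beta[2]
    k_lte[v] <- 6 * beta[3] / beta[2]^2
    k_ste[v] <- 6 * beta[4] / beta[2]^2
    ufa[v] <- ufa_from_cumulants(d[v], k_lte[v], k_ste[v])
    valid[v] <- TRUE
  }
  list(d = d, k_lte = k_lte, k_ste = k_ste, ufa = ufa, valid = valid)
}
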