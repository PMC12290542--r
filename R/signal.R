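#' Multi-compartment Gaussian voxel substrates
#'
#' A voxel substrate is a mixture of non-exchanging Gaussian diffusion
#' compartments: each compartment contributes a signal fraction and a 3x3
#' symmetric positive-semidefinite diffusion tensor (um^2/ms). This is the
#' ground-truth forward model underlying the cumulant (kurtosis) signal
#' representation fitted by [fit_powder_kurtosis_joint()].
#'
#' `diffusion_compartment()` accepts either a full tensor or eigenvalues plus
#' an optional rotation; `axisymmetric_tensor()` is a convenience for
#' cylindrically symmetric micro-environments.
#'
#' @param tensor 3x3 symmetric psd matrix (um^2/ms), or `NULL` to build one
#'   from `eigenvalues`.
#' @param eigenvalues Length-3 non-negative vector; the tensor is
#'   `R diag(eigenvalues) R'`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param fraction Signal fraction in `[0, 1]`.
#' @return `diffusion_compartment()`: a list with `tensor` and `fraction`;
#'   `voxel_substrate()`: an object of class `voxel_substrate`.
#' @export
diffusion_compartment <- function(tensor = NULL, eigenvalues = NULL,
                                  rotation = diag(3), fraction = 1) {
  if (is.null(tensor)) {
    stopifnot(length(eigenvalues) == 3)
    if (any(eigenvalues < 0)) stop("eigenvalues must be >= 0", call. = FALSE)
    tensor <- rotation %*% diag(as.numeric(eigenvalues)) %*% t(rotation)
  }
  tensor <- (tensor + t(tensor)) / 2
  if (min(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop("diffusion tensor must be positive semi-definite", call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  list(tensor = tensor, fraction = fraction)
}

#' @rdname diffusion_compartment
#' @param axial,radial Axial and radial diffusivity (um^2/ms).
#' @param axis Unit symmetry axis.
#' @export
axisymmetric_tensor <- function(axial, radial, axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  diag(radial, 3) + (axial - radial) * tcrossprod(axis)
}

#' @rdname diffusion_compartment
#' @param compartments List of `diffusion_compartment()` objects; fractions
#'   must sum to 1 within 1e-9.
#' @param s0 Non-diffusion-weighted signal amplitude (> 0, arbitrary units).
#' @export
voxel_substrate <- function(compartments, s0 = 1) {
  if (!length(compartments)) stop("need at least one compartment", call. = FALSE)
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("compartment fractions must sum to 1 (got %.12g)", sum(fr)),
         call. = FALSE)
  }
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0) {
    stop("s0 must be a single positive number", call. = FALSE)
  }
  structure(list(compartments = compartments, s0 = s0),
            class = "voxel_substrate")
}

#' Noise-free diffusion-weighted signals from a substrate
#'
#' Evaluates the multi-Gaussian forward model
#' `S_j = s0 * sum_i f_i exp(-<B_j, D_i>)` for every volume of the scheme,
#' where `<B, D>` is the Frobenius inner product of the b-tensor and the
#' compartment diffusion tensor. For LTE this reduces to `b * u' D u`, for STE
#' to `b * MD`.
#'
#' @param substrate A [voxel_substrate()].
#' @param scheme An [acquisition_scheme()].
#' @return Numeric vector of strictly positive signals, one per volume.
#' @examples
#' sub <- voxel_substrate(list(diffusion_compartment(eigenvalues = c(1, 1, 1))))
#' sch <- acquisition_scheme(1, "STE")
#' generate_signal(sub, sch) # exp(-1)
#' @export
generate_signal <- function(substrate, scheme) {
  stopifnot(inherits(substrate, "voxel_substrate"))
  bd <- btensor_inner(substrate, scheme)
  as.vector(substrate$s0 * (exp(-bd) %*%
    vapply(substrate$compartments, `[[`, numeric(1), "fraction")))
}

## matrix of <B_j, D_i> with volumes in rows, compartments in columns
btensor_inner <- function(substrate, scheme) {
  n <- nrow(scheme)
  lte <- scheme$shape == "LTE" & scheme$b > 0
  ste <- scheme$shape == "STE"
  U <- as.matrix(scheme[, c("gx", "gy", "gz")])
  out <- matrix(0, n, length(substrate$compartments))
  for (i in seq_along(substrate$compartments)) {
    D <- substrate$compartments[[i]]$tensor
    if (any(lte)) {
      Ul <- U[lte, , drop = FALSE]
      out[lte, i] <- scheme$b[lte] * rowSums((Ul %*% D) * Ul)
    }
    if (any(ste)) out[ste, i] <- scheme$b[ste] * sum(diag(D)) / 3
  }
  out
}

#' Add Rician noise to magnitude signals
#'
#' Replaces each signal `S` by `sqrt((S + e1*sigma)^2 + (e2*sigma)^2)` with
#' `e1, e2` independent standard normal draws, the magnitude-MR noise model.
#' Randomness is seeded per volume through a counter scheme: volume `j` draws
#' from stream seed `(seed + 1000003 * j) mod (2^31 - 1)`, so appending
#' volumes to a dataset never perturbs the noise of earlier volumes.
#'
#' @param signals Numeric vector (one voxel) or matrix with voxels in rows
#'   and volumes in columns.
#' @param sigma Noise standard deviation (>= 0) of each Gaussian channel.
#' @param seed Integer seed.
#' @return Noised signals with the same shape as the input. `sigma = 0`
#'   returns the input exactly.
#' @export
add_rician_noise <- function(signals, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single number >= 0", call. = FALSE)
  }
  if (sigma == 0) return(signals)
  m <- if (is.matrix(signals)) signals else matrix(signals, nrow = 1)
  out <- m
  for (j in seq_len(ncol(m))) {
    sj <- (as.numeric(seed) + 1000003 * j) %% 2147483647
    set.seed(as.integer(sj))
    e1 <- stats::rnorm(nrow(m))
    e2 <- stats::rnorm(nrow(m))
    out[, j] <- sqrt((m[, j] + e1 * sigma)^2 + (e2 * sigma)^2)
  }
  if (is.matrix(signals)) out else as.vector(out)
}

#' Powder average of per-volume signals
#'
#' Arithmetic mean of the signals within each unique (b, shape) shell of the
#' scheme. Powder averaging removes orientational information, which is what
#' makes the joint LTE/STE kurtosis representation sensitive to microscopic
#' rather than voxel-scale anisotropy.
#'
#' @param signals Numeric vector, one value per scheme volume, or a matrix
#'   with voxels in rows and volumes in columns.
#' @param scheme An [acquisition_scheme()].
#' @return For vector input, a tibble of class `powder_signal` with columns
#'   `shell`, `b`, `shape`, `mean_signal`, `n_directions`. For matrix input a
#'   list with the shell table (`shells`) and a voxels x shells matrix
#'   (`mean_signal`).
#' @export
powder_average <- function(signals, scheme) {
  shells <- scheme_shells(scheme)
  idx <- lapply(shells$shell, function(s) which(scheme$shell == s))
  if (is.matrix(signals)) {
    if (ncol(signals) != nrow(scheme)) {
      stop("signals must have one column per scheme volume", call. = FALSE)
    }
    ms <- vapply(idx, function(i) rowMeans(signals[, i, drop = FALSE]),
                 numeric(nrow(signals)))
    ms <- matrix(ms, nrow = nrow(signals))
    return(list(shells = shells, mean_signal = ms))
  }
  if (length(signals) != nrow(scheme)) {
    stop("need one signal per scheme volume", call. = FALSE)
  }
  shells$mean_signal <- vapply(idx, function(i) mean(signals[i]), numeric(1))
  out <- shells[, c("shell", "b", "shape", "mean_signal", "n_directions")]
  class(out) <- c("powder_signal", class(out))
  out
}
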