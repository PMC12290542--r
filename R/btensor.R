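#' b-tensors for multidimensional diffusion encoding
#'
#' A b-tensor summarises one diffusion-weighted acquisition as a 3x3 symmetric
#' positive-semidefinite matrix whose trace is the b-value. Linear tensor
#' encoding (LTE) sensitises diffusion along a single axis (rank-1 tensor);
#' spherical tensor encoding (STE) sensitises all axes equally (isotropic
#' tensor). Units follow the diffusion-literature convention: b in ms/um^2
#' (so b = 2000 s/mm^2 is 2.0) and diffusivity in um^2/ms, keeping b*D of
#' order one.
#'
#' @param b b-value in ms/um^2; must be non-negative.
#' @param direction Unit 3-vector (LTE only). The norm must equal 1 within
#'   1e-6 unless `b = 0`, where the direction is irrelevant.
#' @return An object of class `btensor`: a list with elements `matrix` (3x3),
#'   `b`, `shape` (`"LTE"` or `"STE"`) and `direction` (`NA` for STE).
#' @examples
#' make_lte_btensor(1, c(1, 0, 0))$matrix
#' make_ste_btensor(2)$matrix # trace 2
#' @export
make_lte_btensor <- function(b, direction) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
    stop("b must be a single non-negative number", call. = FALSE)
  }
  direction <- as.numeric(direction)
  if (length(direction) != 3L) {
    stop("direction must be a 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (b > 0) {
    if (abs(nrm - 1) > 1e-6) {
      stop(sprintf("direction must be a unit vector (norm = %.8g)", nrm),
           call. = FALSE)
    }
    direction <- direction / nrm
  } else {
    direction <- c(NA_real_, NA_real_, NA_real_)
  }
  mat <- if (b > 0) b * tcrossprod(direction) else matrix(0, 3, 3)
  structure(list(matrix = mat, b = b, shape = "LTE", direction = direction),
            class = "btensor")
}

#' @rdname make_lte_btensor
#' @export
make_ste_btensor <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
    stop("b must be a single non-negative number", call. = FALSE)
  }
  structure(list(matrix = diag(b / 3, 3), b = b, shape = "STE",
                 direction = c(NA_real_, NA_real_, NA_real_)),
            class = "btensor")
}

#' Build an acquisition scheme
#'
#' An acquisition scheme is the ordered list of b-tensors matching the volumes
#' of a 4D diffusion dataset, stored as a tibble with one row per volume.
#' Volumes are grouped into shells by unique (b, shape) after clustering
#' b-values within `shell_tolerance`; b = 0 volumes are conventionally
#' assigned shape LTE (shape is irrelevant at b = 0).
#'
#' @param b Numeric vector of b-values in ms/um^2.
#' @param shape Character vector, `"LTE"` or `"STE"`, recycled to match `b`.
#' @param directions Matrix with one unit row per volume (or `NULL` when all
#'   volumes are STE or b = 0). Rows for STE or b = 0 volumes are ignored.
#' @param shell_tolerance b-values closer than this (ms/um^2) are merged into
#'   one shell; default 0.05 (= 50 s/mm^2).
#' @return A tibble of class `acq_scheme` with columns `volume`, `b`, `shape`,
#'   `gx`, `gy`, `gz`, `shell`.
#' @examples
#' acquisition_scheme(c(0, 1, 2), c("LTE", "LTE", "STE"),
#'                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
#' @export
acquisition_scheme <- function(b, shape, directions = NULL,
                               shell_tolerance = 0.05) {
  b <- as.numeric(b)
  if (any(is.na(b)) || any(b < 0)) stop("b-values must be >= 0", call. = FALSE)
  n <- length(b)
  shape <- rep_len(as.character(shape), n)
  if (!all(shape %in% c("LTE", "STE"))) {
    stop("shape tokens must be 'LTE' or 'STE'", call. = FALSE)
  }
  shape[b == 0] <- "LTE"
  if (is.null(directions)) {
    directions <- matrix(0, n, 3)
  }
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (nrow(directions) != n) {
    stop("directions must have one row per volume", call. = FALSE)
  }
  needs_dir <- shape == "LTE" & b > 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(needs_dir & abs(nrm - 1) > 1e-6)) {
    bad <- which(needs_dir & abs(nrm - 1) > 1e-6)[1]
    stop(sprintf("volume %d: LTE direction is not unit (norm = %.8g)",
                 bad, nrm[bad]), call. = FALSE)
  }
  directions[needs_dir, ] <- directions[needs_dir, , drop = FALSE] /
    nrm[needs_dir]
  directions[!needs_dir, ] <- NA_real_

  out <- tibble::tibble(
    volume = seq_len(n), b = b, shape = shape,
    gx = directions[, 1], gy = directions[, 2], gz = directions[, 3]
  )
  out$shell <- assign_shells(out$b, out$shape, shell_tolerance)
  ## snap b within a shell to the shell mean so clustered shells share one b
  out$b <- stats::ave(out$b, out$shell)
  class(out) <- c("acq_scheme", class(out))
  out
}

## single-linkage 1D clustering of b-values within tolerance, crossed w/ shape
assign_shells <- function(b, shape, tol) {
  ord <- order(b)
  grp <- integer(length(b))
  g <- 0L
  last <- -Inf
  for (i in ord) {
    if (b[i] - last > tol) g <- g + 1L
    grp[i] <- g
    last <- b[i]
  }
  key <- paste0(grp, "/", shape)
  match(key, unique(key[order(grp, shape != "LTE")]))
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat(sprintf("<acquisition scheme: %d volumes, %d shells>\n",
              nrow(x), length(unique(x$shell))))
  NextMethod()
}

#' Shell summary of an acquisition scheme
#'
#' @param scheme An [acquisition_scheme()].
#' @return Tibble with one row per shell: `shell`, `b`, `shape`,
#'   `n_directions`.
#' @export
scheme_shells <- function(scheme) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(scheme), .data$shell),
                   b = .data$b[1], shape = .data$shape[1],
                   n_directions = dplyr::n(), .groups = "drop")
}

#' List of b-tensors for each volume of a scheme
#'
#' @param scheme An [acquisition_scheme()].
#' @return List of [make_lte_btensor()] / [make_ste_btensor()] objects, one
#'   per volume.
#' @export
scheme_btensors <- function(scheme) {
  purrr::pmap(list(scheme$b, scheme$shape, scheme$gx, scheme$gy, scheme$gz),
              function(b, shape, gx, gy, gz) {
                if (shape == "STE") make_ste_btensor(b)
                else if (b == 0) make_lte_btensor(0, c(0, 0, 1))
                else make_lte_btensor(b, c(gx, gy, gz))
              })
}

#' Default acquisition schemes
#'
#' `dti_scheme()` mirrors a standard DTI protocol: 6 b = 0 volumes, 36 LTE
#' directions at b = 1 ms/um^2 and 60 LTE directions at b = 2 ms/um^2 (the
#' top shell is excluded from tensor fitting by default, see
#' [fit_dti_wlls()]). `ufa_scheme()` mirrors a compact microscopic-anisotropy
#' protocol: 8 LTE volumes at b = 2 plus 3, 6 and 16 STE volumes at
#' b = 0.1, 1 and 2 ms/um^2.
#'
#' @param b_max For `dti_scheme()`, drop shells above this b (ms/um^2);
#'   default keeps all.
#' @return An `acq_scheme` tibble.
#' @export
dti_scheme <- function(b_max = Inf) {
  d36 <- gradient_directions(36)
  d60 <- gradient_directions(60)
  b <- c(rep(0, 6), rep(1, 36), rep(2, 60))
  dirs <- rbind(matrix(0, 6, 3), d36, d60)
  keep <- b <= b_max
  acquisition_scheme(b[keep], "LTE", dirs[keep, , drop = FALSE])
}

#' @rdname dti_scheme
#' @export
ufa_scheme <- function() {
  d8 <- gradient_directions(8)
  b <- c(rep(2, 8), rep(0.1, 3), rep(1, 6), rep(2, 16))
  shape <- c(rep("LTE", 8), rep("STE", 25))
  dirs <- rbind(d8, matrix(0, 25, 3))
  acquisition_scheme(b, shape, dirs)
}

#' Small-b acquisition schemes for cumulant-regime estimation
#'
#' Shell layouts with max b-value `b_max` (ms/um^2), used where estimates must
#' approach the analytic cumulant limit: the quadratic (kurtosis) signal
#' representation is exact only as b -> 0, so noise-free oracle comparisons
#' against closed-form FA and microscopic FA use these schemes.
#' `small_b_ufa_scheme()` places LTE and STE shells at
#' `b_max * c(0.1, 0.5, 1)`; `small_b_dti_scheme()` uses 6 b = 0 volumes and
#' 36 LTE directions at `b_max`.
#'
#' @param b_max Maximum b-value in ms/um^2.
#' @param n_lte,n_ste Directions per LTE shell / averages per STE shell.
#' @return An `acq_scheme` tibble.
#' @export
small_b_ufa_scheme <- function(b_max = 0.5, n_lte = 60, n_ste = 6) {
  bs <- b_max * c(0.1, 0.5, 1)
  dl <- gradient_directions(n_lte)
  b <- c(rep(bs, each = n_lte), rep(bs, each = n_ste))
  shape <- c(rep("LTE", 3 * n_lte), rep("STE", 3 * n_ste))
  dirs <- rbind(do.call(rbind, rep(list(dl), 3)), matrix(0, 3 * n_ste, 3))
  acquisition_scheme(b, shape, dirs, shell_tolerance = b_max * 0.04)
}

#' @rdname small_b_ufa_scheme
#' @export
small_b_dti_scheme <- function(b_max = 0.2, n_lte = 36) {
  dl <- gradient_directions(n_lte)
  acquisition_scheme(c(rep(0, 6), rep(b_max, n_lte)), "LTE",
                     rbind(matrix(0, 6, 3), dl),
                     shell_tolerance = b_max / 2)
}
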