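#' Fractional anisotropy from tensor eigenvalues
#'
#' Standard closed form `FA = sqrt(3/2 * sum((l - lbar)^2) / sum(l^2))`.
#' Negative eigenvalues are clamped to zero before evaluation; an all-zero
#' (clamped) triple is undefined and returns `NaN`.
#'
#' @param l1,l2,l3 Tensor eigenvalues (um^2/ms).
#' @return FA in `[0, 1]` (or `NaN` for an all-zero tensor).
#' @examples
#' fa_from_eigenvalues(2, 0.5, 0.5) # 0.70711
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  l <- pmax(cbind(l1, l2, l3), 0)
  ss <- rowSums(l^2)
  lbar <- rowMeans(l)
  fa <- sqrt(1.5 * rowSums((l - lbar)^2) / ss)
  fa[ss == 0] <- NaN
  pmin(unname(fa), 1)
}

#' Diffusion tensor fit by weighted linear least squares
#'
#' Fits the log-linear DTI model `ln S = ln S0 - sum_ij b_ij D_ij` to the LTE
#' volumes with `b <= max_b`, using the standard two-pass weighted scheme:
#' pass 1 is ordinary least squares, pass 2 re-weights by the squared signal
#' predicted from pass 1. Restricting to a low-b subset keeps the Gaussian
#' (tensor) representation unbiased by non-Gaussian diffusion at high b; the
#' default cut-off is 1 ms/um^2 (= 1000 s/mm^2).
#'
#' @param signals Positive numeric vector, one per scheme volume.
#' @param scheme An [acquisition_scheme()].
#' @param max_b Exclude volumes with b above this value (ms/um^2).
#' @return Object of class `dti_fit`: list with `tensor` (3x3),
#'   `eigenvalues`, `md`, `fa`, `lnS0`, `valid`.
#' @export
fit_dti_wlls <- function(signals, scheme, max_b = 1.0) {
  keep <- scheme$shape == "LTE" & scheme$b <= max_b
  if (sum(keep) < 7) {
    stop("need at least 7 LTE volumes with b <= max_b", call. = FALSE)
  }
  s <- signals[keep]
  if (any(!is.finite(s)) || any(s <= 0)) {
    return(invalid_dti_fit())
  }
  X <- dti_design(scheme[keep, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient DTI design: directions do not span 6 independent components",
         call. = FALSE)
  }
  y <- log(s)
  beta <- qr.coef(qx, y)                       # pass 1: OLS
  w <- exp(X %*% beta)[, 1]^2                  # pass 2: predicted-signal^2
  beta <- wls_solve(X, y, w)
  dti_fit_from_beta(beta)
}

## rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]
dti_design <- function(scheme) {
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  g[scheme$b == 0, ] <- 0
  b <- scheme$b
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

wls_solve <- function(X, y, w) {
  Xw <- X * w
  solve(crossprod(Xw, X), crossprod(Xw, y))[, 1]
}

dti_fit_from_beta <- function(beta) {
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  evc <- pmax(ev, 0)
  fa <- fa_from_eigenvalues(evc[1], evc[2], evc[3])
  structure(list(tensor = D, eigenvalues = ev, md = mean(ev),
                 fa = fa, lnS0 = beta[1],
                 valid = is.finite(fa) && mean(ev) > 0),
            class = "dti_fit")
}

invalid_dti_fit <- function() {
  structure(list(tensor = matrix(NA_real_, 3, 3),
                 eigenvalues = rep(NA_real_, 3), md = NA_real_,
                 fa = NA_real_, lnS0 = NA_real_, valid = FALSE),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("<dti_fit: MD = %.4g um^2/ms, FA = %.4g%s>\n",
              x$md, x$fa, if (x$valid) "" else ", INVALID"))
  invisible(x)
}
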