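#' Analytic powder-average cumulants of a substrate
#'
#' Closed-form small-b cumulants of the powder-averaged LTE and STE signals
#' of a multi-compartment Gaussian substrate. Writing `d_i(u) = u' D_i u` for
#' the apparent diffusivity of compartment `i` along direction `u`, the
#' powder-averaged log-signal expands as
#' `ln S(b) = ln s0 - b d + (b^2/2) mu2 + O(b^3)` where `d` is the mean and
#' `mu2` the variance of the apparent diffusivity over compartments and (for
#' LTE) uniformly distributed directions. For STE only the isotropic spread
#' across compartments contributes. The per-encoding powder kurtosis is
#' `K = 3 mu2 / d^2`.
#'
#' For a single tensor with eigenvalues `lambda`, the directional variance is
#' `(2/15) sum(lambda^2) - (2/45) (sum(lambda))^2`, i.e. `4 delta^2 / 45` in
#' the axisymmetric case with `delta = lambda_par - lambda_perp`.
#'
#' @param substrate A [voxel_substrate()].
#' @return A list with `d` (powder mean diffusivity, um^2/ms), `mu2_lte`,
#'   `mu2_iso` (variances, um^4/ms^2), `k_lte`, `k_ste` (dimensionless powder
#'   kurtosis per encoding).
#' @export
substrate_cumulants <- function(substrate) {
  stopifnot(inherits(substrate, "voxel_substrate"))
  fr <- vapply(substrate$compartments, `[[`, numeric(1), "fraction")
  md_i <- vapply(substrate$compartments,
                 function(cp) sum(diag(cp$tensor)) / 3, numeric(1))
  var_u <- vapply(substrate$compartments, function(cp) {
    ev <- eigen(cp$tensor, symmetric = TRUE, only.values = TRUE)$values
    (2 / 15) * sum(ev^2) - (2 / 45) * sum(ev)^2
  }, numeric(1))
  d <- sum(fr * md_i)
  mu2_iso <- sum(fr * md_i^2) - d^2
  mu2_lte <- sum(fr * var_u) + mu2_iso
  list(d = d, mu2_lte = mu2_lte, mu2_iso = mu2_iso,
       k_lte = if (d > 0) 3 * mu2_lte / d^2 else NA_real_,
       k_ste = if (d > 0) 3 * mu2_iso / d^2 else NA_real_)
}

#' Composite (voxel-scale) diffusion tensor of a substrate
#'
#' Signal-fraction-weighted sum of the compartment tensors: the tensor that a
#' small-b DTI fit converges to. Its FA conflates microscopic anisotropy with
#' orientation dispersion, which is exactly the confound microscopic FA
#' removes.
#'
#' @param substrate A [voxel_substrate()].
#' @return 3x3 symmetric matrix (um^2/ms).
#' @export
composite_tensor <- function(substrate) {
  Reduce(`+`, lapply(substrate$compartments,
                     function(cp) cp$fraction * cp$tensor))
}

#' Ground-truth scalar metrics of a substrate
#'
#' Analytic MD, FA (of the composite tensor) and microscopic FA (from the
#' closed-form cumulants) for a substrate; used as the reference the fitting
#' pipeline is validated against.
#'
#' @param substrate A [voxel_substrate()].
#' @return A one-row tibble with `md`, `fa`, `ufa`, `d`, `k_lte`, `k_ste`.
#' @export
substrate_truth <- function(substrate) {
  cum <- substrate_cumulants(substrate)
  ev <- eigen(composite_tensor(substrate), symmetric = TRUE,
              only.values = TRUE)$values
  tibble::tibble(
    md = cum$d,
    fa = fa_from_eigenvalues(ev[1], ev[2], ev[3]),
    ufa = ufa_from_cumulants(cum$d, cum$k_lte, cum$k_ste),
    d = cum$d, k_lte = cum$k_lte, k_ste = cum$k_ste
  )
}
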