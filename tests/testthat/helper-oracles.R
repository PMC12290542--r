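# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for the rank tests,
# Gauss-Legendre spherical quadrature for powder averages, and central
# finite differences of the log-signal for cumulants.

## exhaustive two-sided Mann-Whitney p over all C(n1+n2, n1) group splits
enum_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

## exhaustive two-sided Wilcoxon signed-rank p over all 2^n sign patterns
enum_wsr_p <- function(ipsi, contra) {
  d <- ipsi - contra
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

## Gauss-Legendre x uniform-phi quadrature of the powder-averaged LTE signal
## of a compartment mixture (tensors in `tensors`, fractions in `fracs`)
quadrature_powder_lte <- function(tensors, fracs, b, n_theta = 64,
                                  n_phi = 128) {
  gl <- pracma_gauss_legendre(n_theta)
  ct <- gl$nodes                      # cos(theta) in (-1, 1)
  wt <- gl$weights / 2                # normalise over the sphere
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  st <- sqrt(1 - ct^2)
  total <- 0
  for (j in seq_along(phi)) {
    u <- cbind(st * cos(phi[j]), st * sin(phi[j]), ct)
    s <- 0
    for (k in seq_along(fracs)) {
      du <- rowSums((u %*% tensors[[k]]) * u)
      s <- s + fracs[k] * exp(-b * du)
    }
    total <- total + sum(wt * s) / n_phi
  }
  total
}

## minimal Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
pracma_gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

## numerical powder cumulants from one-sided finite differences of ln S at
## tiny b (4-point stencils: O(h^3) for the slope, O(h^2) for the curvature)
oracle_cumulants <- function(substrate, h = 0.004) {
  fracs <- vapply(substrate$compartments, `[[`, numeric(1), "fraction")
  tensors <- lapply(substrate$compartments, `[[`, "tensor")
  bgrid <- c(0, h, 2 * h, 3 * h)
  lnS_lte <- vapply(bgrid, function(b)
    log(quadrature_powder_lte(tensors, fracs, b)), numeric(1))
  mds <- vapply(tensors, function(D) sum(diag(D)) / 3, numeric(1))
  lnS_ste <- vapply(bgrid, function(b)
    log(sum(fracs * exp(-b * mds))), numeric(1))
  fd <- function(f) {
    d <- -(-11 * f[1] + 18 * f[2] - 9 * f[3] + 2 * f[4]) / (6 * h)
    a <- (2 * f[1] - 5 * f[2] + 4 * f[3] - f[4]) / (2 * h^2)
    c(d = d, a = a)
  }
  l <- fd(lnS_lte)
  s <- fd(lnS_ste)
  list(d = unname(l["d"]),
       k_lte = unname(6 * l["a"] / l["d"]^2),
       k_ste = unname(6 * s["a"] / s["d"]^2))
}

## closed-form FA, restated independently of the package
oracle_fa <- function(l) {
  lb <- mean(l)
  sqrt(1.5 * sum((l - lb)^2) / sum(l^2))
}

## random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## noise-free single-tensor voxel substrate
single_tensor_substrate <- function(eigenvalues, rotation = diag(3), s0 = 1) {
  voxel_substrate(list(diffusion_compartment(
    eigenvalues = eigenvalues, rotation = rotation)), s0 = s0)
}
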