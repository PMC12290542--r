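#' Gradient direction sets
#'
#' Returns one of the electrostatic-repulsion direction sets shipped with the
#' package (n = 6, 8, 36 or 60 unit vectors). The sets are antipodally
#' symmetric point configurations obtained by minimising a Coulomb-type energy
#' over the sphere; they are frozen as versioned fixtures so that simulated
#' acquisitions are bit-reproducible across sessions.
#'
#' @param n Number of directions; one of 6, 8, 36, 60.
#' @return A numeric matrix with `n` rows and columns `x`, `y`, `z`; each row
#'   has unit Euclidean norm.
#' @examples
#' d <- gradient_directions(8)
#' rowSums(d^2)
#' @export
gradient_directions <- function(n) {
  if (!n %in% c(6L, 8L, 36L, 60L)) {
    stop("no shipped direction set with n = ", n,
         "; available: 6, 8, 36, 60", call. = FALSE)
  }
  path <- system.file("extdata", sprintf("dirset_n%02d.tsv", n),
                      package = "microfa", mustWork = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  m / sqrt(rowSums(m^2))
}

#' Quasi-uniform direction set of arbitrary size
#'
#' Deterministic Fibonacci-sphere point set, used for dense spherical
#' quadrature (for example when cross-checking analytic powder averages) and
#' for the uniformly dispersed orientation rule of the phantom module. For the
#' acquisition-sized sets prefer [gradient_directions()].
#'
#' @param n Number of points on the sphere.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq(0, n - 1)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(ga * i), y = r * sin(ga * i), z = z)
}
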