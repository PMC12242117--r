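# Field evaluation: basis functions, total density, kinetic and local
# energy densities.  All derivatives are analytic (recursions on the
# Gaussian monomials in the compiled basis); finite differences appear only
# in the test suite.

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("input error: points must be n x 3")
  if (!all(is.finite(points))) stop("input error: non-finite point coordinates")
  points
}

# Expand a length-6 packed Hessian row (xx, yy, zz, xy, xz, yz) to 3 x 3.
.unpack_hessian <- function(h) {
  matrix(c(h[1], h[4], h[5],
           h[4], h[2], h[6],
           h[5], h[6], h[3]), 3, 3)
}

#' Evaluate all basis functions at points
#'
#' @param wfn a `wavefunction`
#' @param points n x 3 matrix of coordinates (bohr)
#' @param deriv derivative order: 0 (values), 1 (+gradients), 2 (+Hessians)
#' @return list with `values` (n x m); for `deriv >= 1` also `gradients`
#'   (n x 3 x m); for `deriv == 2` also `hessians` (n x 6 x m, packed
#'   xx, yy, zz, xy, xz, yz)
#' @export
eval_basis <- function(wfn, points, deriv = 0L) {
  stopifnot(inherits(wfn, "wavefunction"), deriv %in% 0:2)
  cpp_eval_basis(compile_basis(wfn), .as_points(points), as.integer(deriv))
}

#' Evaluate the total electron density (and derivatives)
#'
#' \eqn{\rho(r) = \sum_l n_l |\psi_l(r)|^2} with analytic gradient and
#' Hessian.  The Laplacian is the trace of the Hessian.
#'
#' @inheritParams eval_basis
#' @return list with `value` (length n); for `deriv >= 1` `gradient`
#'   (n x 3); for `deriv == 2` `hessian` (n x 6, packed) and `laplacian`
#' @export
eval_density <- function(wfn, points, deriv = 0L) {
  stopifnot(inherits(wfn, "wavefunction"), deriv %in% 0:2)
  out <- cpp_eval_density(compile_basis(wfn), wfn$mo_coefficients,
                          wfn$occupations, .as_points(points),
                          as.integer(deriv), FALSE)
  if (deriv >= 2L)
    out$laplacian <- out$hessian[, 1] + out$hessian[, 2] + out$hessian[, 3]
  out
}

#' Positive-definite kinetic energy density
#'
#' \eqn{G(r) = \tfrac12 \sum_l n_l |\nabla\psi_l(r)|^2} (hartree/a0^3),
#' the positive-definite (Bader) form required by the local virial relation
#' used for the potential energy density.
#'
#' @inheritParams eval_basis
#' @return numeric vector of G values, strictly >= 0
#' @export
eval_kinetic_energy_density <- function(wfn, points) {
  stopifnot(inherits(wfn, "wavefunction"))
  out <- cpp_eval_density(compile_basis(wfn), wfn$mo_coefficients,
                          wfn$occupations, .as_points(points), 0L, TRUE)
  out$G
}

#' Local energy densities at a point
#'
#' Computes the kinetic (`G`), potential (`V`) and total (`H`) local energy
#' densities at one point.  `V` is defined through the local virial
#' relation \eqn{V = \tfrac14 \nabla^2\rho - 2G}, so `H = G + V` is
#' computable from density derivatives alone, as conventional for bond
#' critical point analysis.
#'
#' @param wfn a `wavefunction`
#' @param point length-3 coordinate (bohr)
#' @return list with `G`, `V`, `H` (hartree/a0^3), plus `laplacian` and
#'   `rho` for reference
#' @export
energy_densities_at <- function(wfn, point) {
  stopifnot(inherits(wfn, "wavefunction"))
  pts <- .as_points(point)
  if (nrow(pts) != 1L) stop("input error: energy_densities_at expects one point")
  out <- cpp_eval_density(compile_basis(wfn), wfn$mo_coefficients,
                          wfn$occupations, pts, 2L, TRUE)
  lap <- out$hessian[1, 1] + out$hessian[1, 2] + out$hessian[1, 3]
  G <- out$G[1]
  V <- 0.25 * lap - 2 * G
  list(G = G, V = V, H = G + V, laplacian = lap, rho = out$value[1])
}

# Closure evaluating value/gradient/hessian of the total density at one
# point, in the form the critical-point search consumes.
density_field_evaluator <- function(wfn) {
  wfn <- with_compiled_basis(wfn)
  fb <- attr(wfn, "flat_basis")
  C <- wfn$mo_coefficients
  occ <- wfn$occupations
  function(point) {
    out <- cpp_eval_density(fb, C, occ, matrix(point, 1, 3), 2L, FALSE)
    list(value = out$value[1], gradient = as.numeric(out$gradient[1, ]),
         hessian = .unpack_hessian(out$hessian[1, ]))
  }
}
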