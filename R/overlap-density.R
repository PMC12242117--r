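# The two-center (overlap) density of a fragment pair, its positive-region
# integral, the intra-overlap Coulomb repulsion, and bond-axis profiles.

#' Define a fragment pair for overlap-density analysis
#'
#' Fragments are disjoint non-empty sets of atoms; every basis function
#' belongs to its center atom (Mulliken-style attribution), which makes the
#' decomposition basis-set dependent in the same way as Mulliken
#' populations.
#'
#' @param fragment_a,fragment_b integer vectors of 1-based atom indices
#' @param label bond label for reporting (e.g. `"O-H(D)"`, `"H...O"`)
#' @return object of class `fragment_pair`
#' @export
fragment_pair <- function(fragment_a, fragment_b, label = NULL) {
  fragment_a <- as.integer(fragment_a)
  fragment_b <- as.integer(fragment_b)
  if (length(fragment_a) == 0L || length(fragment_b) == 0L)
    stop("input error: fragments must be non-empty")
  if (length(intersect(fragment_a, fragment_b)) > 0L)
    stop("input error: fragments must be disjoint")
  structure(list(fragment_a = fragment_a, fragment_b = fragment_b,
                 label = label %||% paste0("atoms{",
                   paste(fragment_a, collapse = ","), "}-{",
                   paste(fragment_b, collapse = ","), "}")),
            class = "fragment_pair")
}

# Signed pair density (+ optional derivatives) as a list from the C++ core.
.pair_density_raw <- function(wfn, pair, points, deriv = 0L) {
  stopifnot(inherits(wfn, "wavefunction"), inherits(pair, "fragment_pair"))
  ia <- fragment_basis_indices(wfn, pair$fragment_a)
  ib <- fragment_basis_indices(wfn, pair$fragment_b)
  cpp_pair_density(compile_basis(wfn), wfn$mo_coefficients, wfn$occupations,
                   ia - 1L, ib - 1L, .as_points(points), as.integer(deriv))
}

#' Overlap density of a fragment pair at points
#'
#' Pointwise two-center density
#' \eqn{2 \sum_l n_l \sum_{i \in A} \sum_{j \in B} c_{li} c_{lj}
#' \phi_i(r) \phi_j(r)}.  With `clamp = TRUE` (the default) the value is
#' restricted to its positive part: the overlap density keeps only the
#' constructive-interference contributions, and the restriction applies to
#' the total pair sum at each point (not per orbital or per primitive).
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @param points n x 3 matrix (bohr)
#' @param clamp clamp negative values to zero (the overlap-density
#'   positivity restriction); set `FALSE` for the signed two-center field
#' @return numeric vector of densities (e/a0^3)
#' @export
overlap_density_at <- function(wfn, pair, points, clamp = TRUE) {
  v <- .pair_density_raw(wfn, pair, points, 0L)$value
  if (clamp) pmax(v, 0) else v
}

#' Integrate the overlap density of a fragment pair on a grid
#'
#' Computes the integrated overlap density `rho_op_integrated`
#' (\eqn{\sum_k w_k \max(\rho^{OP}(r_k), 0)}, electrons) together with the
#' signed integral of the unclamped two-center density.  The signed
#' integral equals the analytic Mulliken overlap population
#' (see [mulliken_overlap_population()]) up to grid error, which is the
#' built-in sanity check for grid adequacy.
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @param grid a `molecular_grid` covering the region where the pair
#'   products are non-negligible
#' @param boundary_threshold pair-box grids only: warn and record a
#'   truncation diagnostic when the clamped density on the outer grid layer
#'   exceeds this value (e/a0^3)
#' @return an `op_field` object: the pair, grid provenance, clamped values,
#'   `rho_op_integrated`, `signed_integral`, `j_intra` (`NA` until
#'   [j_op_intra()] runs)
#' @export
integrate_rho_op <- function(wfn, pair, grid, boundary_threshold = 1e-6) {
  stopifnot(inherits(grid, "molecular_grid"))
  signed <- .pair_density_raw(wfn, pair, grid$points, 0L)$value
  clamped <- pmax(signed, 0)
  truncation <- NULL
  if (identical(grid$provenance$scheme, "pair_box")) {
    bmax <- max(clamped[.box_boundary_mask(grid)])
    if (bmax > boundary_threshold) {
      truncation <- list(boundary_max = bmax, threshold = boundary_threshold)
      warning("truncation warning: overlap density on the grid boundary (",
              format(bmax, digits = 3), " e/a0^3) exceeds ",
              boundary_threshold, "; enlarge padding")
    }
  }
  structure(list(
    pair = pair, grid = grid, values = clamped,
    rho_op_integrated = sum(grid$weights * clamped),
    signed_integral = sum(grid$weights * signed),
    j_intra = NA_real_,
    provenance = c(grid$provenance, list(truncation = truncation))),
    class = "op_field")
}

#' @export
print.op_field <- function(x, ...) {
  cat("<op_field>", x$pair$label, ": rho_op =",
      format(x$rho_op_integrated, digits = 6), "e, signed =",
      format(x$signed_integral, digits = 6), "e",
      if (!is.na(x$j_intra)) paste(", J =", format(x$j_intra, digits = 6),
                                   "eV"), "\n")
  invisible(x)
}

#' Intra-overlap Coulomb repulsion of an overlap-density field
#'
#' Numerical double integration
#' \eqn{J = \int\int \rho^{OP}(r_1) r_{12}^{-1} \rho^{OP}(r_2) dr_1 dr_2}
#' over the positive region, as a direct double sum over grid cells plus a
#' per-cell self-term (the Coulomb energy of the cell's charge spread
#' uniformly over a cube of the cell's volume, full cube constant
#' 1.88231: the ordered double integral carries no 1/2).  The
#' self-term and the charge neglected below `threshold` are reported in the
#' result attributes; at the default pair-box spacing the self-term is a
#' fraction of a percent and shrinks with the spacing.
#'
#' @param field an `op_field` from [integrate_rho_op()] (pair-box grids
#'   keep the double sum affordable; any positively-weighted grid works)
#' @param threshold density floor (e/a0^3) below which grid cells are left
#'   out of the double sum; their total charge is reported as a diagnostic
#' @return J in eV (scalar) with attributes `hartree`, `self_term_hartree`,
#'   `n_points`, `dropped_charge`
#' @export
j_op_intra <- function(field, threshold = 1e-7) {
  stopifnot(inherits(field, "op_field"))
  if (all(field$values <= 0)) {
    warning("empty positive region; J = 0")
    return(structure(0, hartree = 0, self_term_hartree = 0, n_points = 0L,
                     dropped_charge = 0))
  }
  npos <- sum(field$values > threshold)
  if (npos > 2e5)
    warning("J double sum over ", npos, " points; this is O(N^2) and slow")
  res <- cpp_j_double_sum(field$grid$points, field$grid$weights,
                          field$values, threshold)
  j_h <- res$pair_sum + res$self_term
  if (j_h > 0 && res$self_term / j_h > 0.006)
    warning("J self-term is ", format(100 * res$self_term / j_h, digits = 2),
            "% of the total; refine the grid spacing")
  structure(j_h * HARTREE_TO_EV, hartree = j_h,
            self_term_hartree = res$self_term, n_points = res$n_points,
            dropped_charge = res$dropped_charge)
}

#' Total and overlap density profile along a segment
#'
#' Equally spaced samples of the total density and the (clamped) pair
#' overlap density along a line segment, as plotted along hydrogen-bond
#' axes.
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @param from,to segment endpoints (bohr)
#' @param n_samples number of samples (>= 2)
#' @return data.frame with `s_bohr`, `s_angstrom` (arc length from `from`),
#'   `rho_total`, `rho_op`
#' @export
profile_along_axis <- function(wfn, pair, from, to, n_samples = 200L) {
  if (n_samples < 2L) stop("input error: n_samples must be >= 2")
  from <- as.numeric(from); to <- as.numeric(to)
  if (sqrt(sum((to - from)^2)) < 1e-12)
    stop("input error: coincident profile endpoints")
  t <- seq(0, 1, length.out = n_samples)
  pts <- cbind(from[1] + t * (to[1] - from[1]),
               from[2] + t * (to[2] - from[2]),
               from[3] + t * (to[3] - from[3]))
  s <- t * sqrt(sum((to - from)^2))
  data.frame(s_bohr = s, s_angstrom = s * BOHR_TO_ANGSTROM,
             rho_total = eval_density(wfn, pts, 0L)$value,
             rho_op = overlap_density_at(wfn, pair, pts, clamp = TRUE))
}

# Closure for the signed pair-density field (value/gradient/hessian at one
# point); the overlap critical point search runs on this unclamped field
# and verifies afterwards that the stationary point lies in the positive
# basin, because clamping creates gradient discontinuities at the
# rho_op = 0 boundary.
pair_field_evaluator <- function(wfn, pair) {
  wfn <- with_compiled_basis(wfn)
  fb <- attr(wfn, "flat_basis")
  ia <- fragment_basis_indices(wfn, pair$fragment_a) - 1L
  ib <- fragment_basis_indices(wfn, pair$fragment_b) - 1L
  C <- wfn$mo_coefficients
  occ <- wfn$occupations
  function(point) {
    out <- cpp_pair_density(fb, C, occ, ia, ib, matrix(point, 1, 3), 2L)
    list(value = out$value[1], gradient = as.numeric(out$gradient[1, ]),
         hessian = .unpack_hessian(out$hessian[1, ]))
  }
}
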