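# Critical-point location and classification for scalar fields (total
# density -> bond critical points; overlap density -> overlap critical
# points), and the descriptor sets evaluated at them.

#' Locate a critical point of a scalar field
#'
#' Damped Newton-Raphson search \eqn{x \leftarrow x - H^{-1}\nabla f} with a
#' trust radius (default 0.3 bohr; steps are halved while the gradient norm
#' increases).  Convergence requires the gradient norm below `tol`; the
#' Hessian at convergence classifies the point by rank and signature with a
#' relative degeneracy threshold of `1e-12 * max |lambda|`.  A singular
#' Hessian switches the search to gradient-norm minimization (flagged in
#' the result).
#'
#' @param field function(point) returning `list(value, gradient, hessian)`
#' @param seed starting point (bohr)
#' @param field_kind label stored on the result (`"total_density"` /
#'   `"overlap_density"` / other)
#' @param tol gradient-norm convergence threshold
#' @param max_iter maximum Newton iterations
#' @param trust_radius maximum step length (bohr)
#' @return object of class `critical_point`: `position`, `value`,
#'   `gradient_norm`, `hessian`, `eigenvalues` (ascending), `laplacian`,
#'   `rank`, `signature`, `iterations`, `fallback` (logical)
#' @export
find_critical_point <- function(field, seed, field_kind = "field",
                                tol = 1e-10, max_iter = 200L,
                                trust_radius = 0.3) {
  x <- as.numeric(seed)
  if (length(x) != 3L || !all(is.finite(x)))
    stop("input error: seed must be a finite 3-vector")
  fallback <- FALSE
  f <- field(x)
  gnorm <- sqrt(sum(f$gradient^2))
  iter <- 0L
  while (gnorm > tol && iter < max_iter) {
    iter <- iter + 1L
    step <- try(solve(f$hessian, -f$gradient), silent = TRUE)
    if (inherits(step, "try-error") || !all(is.finite(step))) {
      # singular Hessian: minimize |grad|^2 from the current iterate
      fallback <- TRUE
      obj <- function(p) sum(field(p)$gradient^2)
      opt <- stats::optim(x, obj, method = "BFGS",
                          control = list(reltol = 1e-16, maxit = 500))
      x <- opt$par
      f <- field(x)
      gnorm <- sqrt(sum(f$gradient^2))
      break
    }
    slen <- sqrt(sum(step^2))
    if (slen > trust_radius) step <- step * (trust_radius / slen)
    # halve the step while it increases the gradient norm (up to 8 times)
    for (h in 0:8) {
      xn <- x + step
      fn <- field(xn)
      gn <- sqrt(sum(fn$gradient^2))
      if (is.finite(gn) && (gn < gnorm || h == 8L)) break
      step <- step / 2
    }
    x <- xn; f <- fn; gnorm <- gn
  }
  if (gnorm > tol)
    stop("search-failure: no critical point within ", max_iter,
         " iterations (last |grad| = ", format(gnorm, digits = 3),
         " at ", paste(format(x, digits = 6), collapse = ", "), ")")
  ev <- eigen(f$hessian, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  if (max(abs(ev)) < 1e-8)
    stop("search-failure: converged in a degenerate (vanishing-field) ",
         "region at ", paste(format(x, digits = 6), collapse = ", "))
  thr <- 1e-12 * max(abs(ev))
  nondeg <- abs(ev) > thr
  structure(list(
    position = x, field_kind = field_kind, value = f$value,
    gradient_norm = gnorm, hessian = f$hessian, eigenvalues = ev,
    laplacian = sum(ev), rank = as.integer(sum(nondeg)),
    signature = as.integer(sum(sign(ev[nondeg]))), iterations = iter,
    fallback = fallback),
    class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat("<critical_point>", x$field_kind, sprintf("(%d,%+d)", x$rank,
      x$signature), "at (", paste(format(x$position, digits = 6),
      collapse = ", "), ") value =", format(x$value, digits = 6),
      "laplacian =", format(x$laplacian, digits = 6), "\n")
  invisible(x)
}

#' Locate a bond critical point of the total density
#'
#' @param wfn a `wavefunction`
#' @param seed starting point, typically a bond midpoint (bohr)
#' @param ... passed to [find_critical_point()]
#' @return a `critical_point` with `field_kind = "total_density"`
#' @export
find_bcp <- function(wfn, seed, ...) {
  find_critical_point(density_field_evaluator(wfn), seed,
                      field_kind = "total_density", ...)
}

#' Locate an overlap critical point of a pair overlap density
#'
#' The search runs on the signed (unclamped) two-center field, since the
#' positivity clamp has gradient discontinuities at its zero boundary; a
#' converged point outside the positive basin is an error.
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @param seed starting point (bohr)
#' @param ... passed to [find_critical_point()]
#' @return a `critical_point` with `field_kind = "overlap_density"`
#' @export
find_ocp <- function(wfn, pair, seed, ...) {
  cp <- find_critical_point(pair_field_evaluator(wfn, pair), seed,
                            field_kind = "overlap_density", ...)
  if (cp$value <= 0)
    stop("search-failure: overlap critical point search left the positive ",
         "basin (value = ", format(cp$value, digits = 3), ")")
  cp
}

#' QTAIM descriptors at a bond critical point
#'
#' Density, Laplacian and local energy densities at a (3,-1) critical
#' point of the total density.  `h_bcp_ev` applies the hartree-to-eV
#' conversion used for reporting; all other members stay in atomic units.
#'
#' @param wfn a `wavefunction`
#' @param bcp a `critical_point` with `field_kind = "total_density"` and
#'   signature -1
#' @return list: `rho_bcp`, `laplacian_bcp` (a.u.), `G`, `V`, `H`
#'   (hartree/a0^3), `h_bcp_ev` (eV/a0^3)
#' @export
bcp_descriptors <- function(wfn, bcp) {
  stopifnot(inherits(bcp, "critical_point"))
  if (!identical(bcp$field_kind, "total_density"))
    stop("contract error: not a total-density critical point")
  if (bcp$signature != -1L)
    stop("contract error: signature ", bcp$signature,
         " is not a (3,-1) bond critical point")
  ed <- energy_densities_at(wfn, bcp$position)
  list(rho_bcp = ed$rho, laplacian_bcp = ed$laplacian,
       G = ed$G, V = ed$V, H = ed$H, h_bcp_ev = ed$H * HARTREE_TO_EV)
}

#' Overlap-density descriptors at an overlap critical point
#'
#' Value and Laplacian of the pair overlap density at an in-bond overlap
#' critical point.  In-bond overlap critical points are maxima of the
#' overlap density: all three Hessian curvatures negative, hence a negative
#' Laplacian.
#'
#' @param wfn a `wavefunction`
#' @param pair the [fragment_pair()] the field belongs to
#' @param ocp a `critical_point` with `field_kind = "overlap_density"`
#' @return list: `rho_ocp` (e/a0^3), `laplacian_ocp` (e/a0^5)
#' @export
ocp_descriptors <- function(wfn, pair, ocp) {
  stopifnot(inherits(ocp, "critical_point"))
  if (!identical(ocp$field_kind, "overlap_density"))
    stop("contract error: not an overlap-density critical point")
  if (any(ocp$eigenvalues >= 0))
    stop("classification error: positive curvature present; not an in-bond ",
         "overlap critical point")
  list(rho_ocp = ocp$value, laplacian_ocp = ocp$laplacian)
}

#' Seed points for bond critical-point searches
#'
#' Midpoint of every bonded pair; hydrogen bonds (pairs flagged in `hbond`,
#' by default any pair longer than 1.55 Angstrom involving hydrogen) get a
#' second seed at the 40/60 split toward the hydrogen atom.
#'
#' @param atoms atoms data.frame (bohr coordinates)
#' @param bonds list of length-2 integer vectors (or an n x 2 matrix) of
#'   1-based atom indices
#' @param hbond optional logical vector, one per bond, marking hydrogen
#'   bonds; `NULL` enables the distance heuristic
#' @return list of seeds; each a list(`point`, `bond`, `kind`)
#' @export
seed_bond_points <- function(atoms, bonds, hbond = NULL) {
  if (is.matrix(bonds)) bonds <- lapply(seq_len(nrow(bonds)),
                                        function(i) bonds[i, ])
  if (length(bonds) == 0L) return(list())
  seeds <- list()
  for (k in seq_along(bonds)) {
    b <- as.integer(bonds[[k]])
    p1 <- c(atoms$x[b[1]], atoms$y[b[1]], atoms$z[b[1]])
    p2 <- c(atoms$x[b[2]], atoms$y[b[2]], atoms$z[b[2]])
    seeds[[length(seeds) + 1L]] <-
      list(point = (p1 + p2) / 2, bond = k, kind = "midpoint")
    is_h <- any(atoms$element[b] == "H")
    d_ang <- sqrt(sum((p2 - p1)^2)) * BOHR_TO_ANGSTROM
    is_hb <- if (is.null(hbond)) (is_h && d_ang > 1.55) else isTRUE(hbond[k])
    if (is_hb) {
      # 40/60 split toward the hydrogen end
      toward_h <- if (atoms$element[b[1]] == "H") p1 else p2
      other <- if (atoms$element[b[1]] == "H") p2 else p1
      seeds[[length(seeds) + 1L]] <-
        list(point = other + 0.6 * (toward_h - other), bond = k,
             kind = "hbond_60_40")
    }
  }
  seeds
}
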