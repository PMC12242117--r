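# Molecular quadrature grids: atom-centered Becke fuzzy-cell grids for
# whole-space integrals, and uniform rectangular pair-region grids for
# overlap-density maps and the Coulomb double sum.

# Angular-point counts accepted for the atom-centered grid, with the
# polynomial degree of the corresponding octahedral (Lebedev) rule.  The
# spherical rule used internally is a Gauss-Legendre (cos theta) x uniform
# (phi) product grid of at least the same degree: it integrates all
# spherical harmonics up to that degree exactly, which is the property the
# quadrature needs (see the methods vignette for why the product rule is
# preferred here).
.ANGULAR_DEGREE <- c(
  `6` = 3, `14` = 5, `26` = 7, `38` = 9, `50` = 11, `74` = 13, `86` = 15,
  `110` = 17, `146` = 19, `170` = 21, `194` = 23, `230` = 25, `266` = 27,
  `302` = 29, `350` = 31, `434` = 35, `590` = 41)

# Gauss-Legendre nodes/weights on [-1, 1] by Newton iteration.
gauss_legendre <- function(n) {
  k <- seq_len(n)
  x <- cos(pi * (k - 0.25) / (n + 0.5))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (j in 2:n) {
      p2 <- ((2 * j - 1) * x * p1 - (j - 1) * p0) / j
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    dx <- p1 / dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  list(nodes = x, weights = 2 / ((1 - x^2) * dp^2))
}

.unit_sphere_grid <- function(degree) {
  ntheta <- ceiling((degree + 1) / 2)
  nphi <- 2L * ntheta
  gl <- gauss_legendre(ntheta)
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ct <- rep(gl$nodes, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  wt <- rep(gl$weights, each = nphi) * (2 * pi / nphi)
  cbind(x = st * cos(phi), y = st * sin(phi), z = ct, w = wt)
}

.slater_radius_bohr <- function(element) {
  r <- BRAGG_SLATER_A[element]
  if (anyNA(r)) stop("no Bragg-Slater radius for element: ",
                     element[is.na(r)][1])
  unname(r) / BOHR_TO_ANGSTROM
}

#' Build an atom-centered Becke quadrature grid
#'
#' Atom-centered grid with Becke fuzzy-cell weights: per atom, a
#' Gauss-Chebyshev (second kind) radial rule mapped to `r = R (1+x)/(1-x)`
#' with `R` the element's Bragg-Slater radius, crossed with a spherical rule
#' whose polynomial degree matches the requested angular count (see
#' `build_becke_grid`'s provenance for the realized point counts).  Cell
#' weights use Becke's iterated cutoff polynomial (k = 3) with heteronuclear
#' size adjustment.
#'
#' @param atoms atoms data.frame (as in [wavefunction()]), coordinates bohr
#' @param radial_points radial points per atom (>= 10)
#' @param angular_points requested angular count; must be one of the
#'   standard octahedral-rule sizes (6, 14, 26, 38, 50, 74, 86, 110, 146,
#'   170, 194, 230, 266, 302, 350, 434, 590)
#' @return a `molecular_grid`: list with `points` (n x 3, bohr), `weights`
#'   (length n, includes the volume element), `provenance`
#' @export
build_becke_grid <- function(atoms, radial_points = 75L,
                             angular_points = 302L) {
  if (!is.numeric(radial_points) || radial_points < 10)
    stop("configuration error: radial_points must be >= 10")
  key <- as.character(as.integer(angular_points))
  if (!key %in% names(.ANGULAR_DEGREE))
    stop("configuration error: invalid angular order ", angular_points,
         " (valid: ", paste(names(.ANGULAR_DEGREE), collapse = ", "), ")")
  degree <- .ANGULAR_DEGREE[[key]]
  sph <- .unit_sphere_grid(degree)
  nr <- as.integer(radial_points)
  i <- seq_len(nr)
  xr <- cos(i * pi / (nr + 1))                  # Gauss-Chebyshev 2nd kind
  wr <- (pi / (nr + 1)) * sin(i * pi / (nr + 1))^2 / sqrt(1 - xr^2)
  nat <- nrow(atoms)
  radii <- .slater_radius_bohr(atoms$element)
  pts <- vector("list", nat)
  wts <- vector("list", nat)
  owner <- vector("list", nat)
  for (a in seq_len(nat)) {
    R <- radii[a]
    r <- R * (1 + xr) / (1 - xr)
    jac <- 2 * R / (1 - xr)^2
    wrad <- wr * jac * r^2
    px <- outer(sph[, "x"], r) ; py <- outer(sph[, "y"], r)
    pz <- outer(sph[, "z"], r)
    w <- outer(sph[, "w"], wrad)
    pts[[a]] <- cbind(as.vector(px) + atoms$x[a], as.vector(py) + atoms$y[a],
                      as.vector(pz) + atoms$z[a])
    wts[[a]] <- as.vector(w)
    owner[[a]] <- rep(a - 1L, length(wts[[a]]))
  }
  points <- do.call(rbind, pts)
  weights <- unlist(wts)
  own <- unlist(owner)
  if (nat > 1L) {
    cell <- cpp_becke_weights(as.matrix(atoms[, c("x", "y", "z")]), radii,
                              own, points)
    weights <- weights * cell
  }
  structure(list(
    points = points, weights = weights,
    provenance = list(scheme = "becke", radial_points = nr,
                      angular_points = as.integer(angular_points),
                      angular_degree = degree,
                      n_points = length(weights),
                      radii_bohr = stats::setNames(radii, atoms$element))),
    class = "molecular_grid")
}

#' Build a uniform rectangular grid around an atom pair
#'
#' Midpoint-rule box grid enclosing both atoms plus `padding` bohr on every
#' side; all weights equal `spacing^3`.  This is the grid the intra-overlap
#' Coulomb repulsion is summed on (the overlap density of a bond is
#' localized between the bonded atoms, so a padded bond box converges; the
#' boundary values are checked at integration time and a truncation warning
#' is attached when density leaks through the box faces).
#'
#' @param atoms atoms data.frame, coordinates in bohr
#' @param pair length-2 integer vector of 1-based atom indices
#' @param padding box padding beyond the two atoms, bohr
#' @param spacing grid step, bohr (> 0)
#' @return a `molecular_grid` with extra fields `origin`, `dims`, `spacing`
#' @export
build_pair_region_grid <- function(atoms, pair, padding = 5, spacing = 0.15) {
  if (!is.numeric(spacing) || spacing <= 0)
    stop("configuration error: spacing must be > 0")
  if (length(pair) != 2L || any(pair < 1L) || any(pair > nrow(atoms)))
    stop("configuration error: pair must be two valid atom indices")
  xy <- as.matrix(atoms[pair, c("x", "y", "z")])
  lo <- apply(xy, 2, min) - padding
  hi <- apply(xy, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 0.5) * spacing)
  points <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(points) <- NULL
  structure(list(
    points = points, weights = rep(spacing^3, nrow(points)),
    origin = lo, dims = dims, spacing = spacing,
    provenance = list(scheme = "pair_box", pair = as.integer(pair),
                      padding = padding, spacing = spacing,
                      dims = dims, n_points = nrow(points))),
    class = "molecular_grid")
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat("<molecular_grid>", x$provenance$scheme, "-", nrow(x$points),
      "points\n")
  invisible(x)
}

# Logical mask of points lying on the outermost layer of a pair-box grid.
.box_boundary_mask <- function(grid) {
  stopifnot(grid$provenance$scheme == "pair_box")
  d <- grid$dims
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  ix == 1L | ix == d[1] | iy == 1L | iy == d[2] | iz == 1L | iz == d[3]
}
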