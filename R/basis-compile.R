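# Compilation of a wavefunction's shell list into the flat primitive-monomial
# representation consumed by the C++ evaluators, plus analytic overlap
# utilities built on the same representation.

# Molden component orders.
.cart_components <- list(
  # l = 0 .. 4; rows are (ax, ay, az) exponent triples in Molden order
  `0` = matrix(c(0, 0, 0), ncol = 3, byrow = TRUE),
  `1` = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE),
  `2` = matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 0, 1, 0, 1, 0, 1, 1),
               ncol = 3, byrow = TRUE),
  `3` = matrix(c(3, 0, 0, 0, 3, 0, 0, 0, 3, 1, 2, 0, 2, 1, 0, 2, 0, 1,
                 1, 0, 2, 0, 1, 2, 0, 2, 1, 1, 1, 1), ncol = 3, byrow = TRUE),
  `4` = matrix(c(4, 0, 0, 0, 4, 0, 0, 0, 4, 3, 1, 0, 3, 0, 1, 1, 3, 0,
                 0, 3, 1, 1, 0, 3, 0, 1, 3, 2, 2, 0, 2, 0, 2, 0, 2, 2,
                 2, 1, 1, 1, 2, 1, 1, 1, 2), ncol = 3, byrow = TRUE)
)

# Real solid harmonics as monomial expansions (relative coefficients; the
# absolute normalization is fixed afterwards by analytic self-overlap).
# Component order within a shell follows the Molden convention:
# m = 0, +1, -1, +2, -2, ...  (p shells are x, y, z).
.sph_components <- list(
  `0` = list(list(p = rbind(c(0, 0, 0)), c = 1)),
  `1` = list(
    list(p = rbind(c(1, 0, 0)), c = 1),
    list(p = rbind(c(0, 1, 0)), c = 1),
    list(p = rbind(c(0, 0, 1)), c = 1)
  ),
  `2` = list(
    list(p = rbind(c(0, 0, 2), c(2, 0, 0), c(0, 2, 0)), c = c(2, -1, -1)),
    list(p = rbind(c(1, 0, 1)), c = 1),
    list(p = rbind(c(0, 1, 1)), c = 1),
    list(p = rbind(c(2, 0, 0), c(0, 2, 0)), c = c(1, -1)),
    list(p = rbind(c(1, 1, 0)), c = 1)
  ),
  `3` = list(
    list(p = rbind(c(0, 0, 3), c(2, 0, 1), c(0, 2, 1)), c = c(2, -3, -3)),
    list(p = rbind(c(1, 0, 2), c(3, 0, 0), c(1, 2, 0)), c = c(4, -1, -1)),
    list(p = rbind(c(0, 1, 2), c(2, 1, 0), c(0, 3, 0)), c = c(4, -1, -1)),
    list(p = rbind(c(2, 0, 1), c(0, 2, 1)), c = c(1, -1)),
    list(p = rbind(c(1, 1, 1)), c = 1),
    list(p = rbind(c(3, 0, 0), c(1, 2, 0)), c = c(1, -3)),
    list(p = rbind(c(2, 1, 0), c(0, 3, 0)), c = c(3, -1))
  ),
  `4` = list(
    list(p = rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(2, 2, 0),
                   c(2, 0, 2), c(0, 2, 2)), c = c(3, 3, 8, 6, -24, -24)),
    list(p = rbind(c(1, 0, 3), c(3, 0, 1), c(1, 2, 1)), c = c(4, -3, -3)),
    list(p = rbind(c(0, 1, 3), c(2, 1, 1), c(0, 3, 1)), c = c(4, -3, -3)),
    list(p = rbind(c(2, 0, 2), c(0, 2, 2), c(4, 0, 0), c(0, 4, 0)),
         c = c(6, -6, -1, 1)),
    list(p = rbind(c(1, 1, 2), c(3, 1, 0), c(1, 3, 0)), c = c(6, -1, -1)),
    list(p = rbind(c(3, 0, 1), c(1, 2, 1)), c = c(1, -3)),
    list(p = rbind(c(2, 1, 1), c(0, 3, 1)), c = c(3, -1)),
    list(p = rbind(c(4, 0, 0), c(2, 2, 0), c(0, 4, 0)), c = c(1, -6, 1)),
    list(p = rbind(c(3, 1, 0), c(1, 3, 0)), c = c(1, -1))
  )
)

.double_factorial <- function(n) {
  if (n <= 1) return(1)
  prod(seq(n, 2, by = -2))
}

# Normalization of the (l,0,0)-type cartesian primitive; within a solid
# harmonic all monomials share this common alpha-dependent factor so the
# primitive-relative contraction weighting is preserved.
.prim_norm <- function(alpha, ax, ay, az) {
  l <- ax + ay + az
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) /
    sqrt(.double_factorial(2 * ax - 1) * .double_factorial(2 * ay - 1) *
           .double_factorial(2 * az - 1))
}

#' Number of basis functions contributed by each shell
#' @noRd
shell_component_counts <- function(shells) {
  vapply(shells, function(sh) {
    if (isTRUE(sh$spherical)) 2L * sh$l + 1L else
      ((sh$l + 1L) * (sh$l + 2L)) %/% 2L
  }, integer(1))
}

# Build the flat basis list (term arrays + offsets) with every contracted
# function renormalized to unit self-overlap.  Cached on the wavefunction.
compile_basis <- function(wfn) {
  cached <- attr(wfn, "flat_basis")
  if (!is.null(cached)) return(cached)
  shells <- wfn$shells
  atoms <- wfn$atoms
  coef <- numeric(0); alpha <- numeric(0)
  ax <- integer(0); ay <- integer(0); az <- integer(0)
  cx <- numeric(0); cy <- numeric(0); cz <- numeric(0)
  offsets <- 0L
  fn_atom <- integer(0)
  for (sh in shells) {
    if (sh$l > 4L)
      stop("unsupported angular momentum l = ", sh$l, " (max supported: 4)")
    at <- sh$atom
    pos <- c(atoms$x[at], atoms$y[at], atoms$z[at])
    if (isTRUE(sh$spherical)) {
      comps <- .sph_components[[as.character(sh$l)]]
      for (comp in comps) {
        n_new <- 0L
        for (p in seq_along(sh$exponents)) {
          a <- sh$exponents[p]
          d <- sh$coefficients[p]
          nrm <- .prim_norm(a, sh$l, 0L, 0L)
          for (k in seq_len(nrow(comp$p))) {
            coef <- c(coef, d * nrm * comp$c[k])
            alpha <- c(alpha, a)
            ax <- c(ax, comp$p[k, 1]); ay <- c(ay, comp$p[k, 2]); az <- c(az, comp$p[k, 3])
            n_new <- n_new + 1L
          }
        }
        cx <- c(cx, rep(pos[1], n_new)); cy <- c(cy, rep(pos[2], n_new))
        cz <- c(cz, rep(pos[3], n_new))
        offsets <- c(offsets, offsets[length(offsets)] + n_new)
        fn_atom <- c(fn_atom, at)
      }
    } else {
      comps <- .cart_components[[as.character(sh$l)]]
      for (k in seq_len(nrow(comps))) {
        n_new <- 0L
        for (p in seq_along(sh$exponents)) {
          a <- sh$exponents[p]
          d <- sh$coefficients[p]
          coef <- c(coef, d * .prim_norm(a, comps[k, 1], comps[k, 2], comps[k, 3]))
          alpha <- c(alpha, a)
          ax <- c(ax, comps[k, 1]); ay <- c(ay, comps[k, 2]); az <- c(az, comps[k, 3])
          n_new <- n_new + 1L
        }
        cx <- c(cx, rep(pos[1], n_new)); cy <- c(cy, rep(pos[2], n_new))
        cz <- c(cz, rep(pos[3], n_new))
        offsets <- c(offsets, offsets[length(offsets)] + n_new)
        fn_atom <- c(fn_atom, at)
      }
    }
  }
  fb <- list(offsets = as.integer(offsets), coef = coef, alpha = alpha,
             ax = as.integer(ax), ay = as.integer(ay), az = as.integer(az),
             cx = cx, cy = cy, cz = cz, fn_atom = fn_atom)
  # contracted-function renormalization to unit self-overlap
  S <- cpp_overlap_matrix(fb)
  scale <- 1 / sqrt(diag(S))
  m <- length(fn_atom)
  for (f in seq_len(m)) {
    idx <- (fb$offsets[f] + 1L):fb$offsets[f + 1L]
    fb$coef[idx] <- fb$coef[idx] * scale[f]
  }
  fb
}

# Attach the compiled basis so repeated evaluations skip recompilation.
with_compiled_basis <- function(wfn) {
  if (is.null(attr(wfn, "flat_basis")))
    attr(wfn, "flat_basis") <- compile_basis(wfn)
  wfn
}

#' Analytic overlap matrix of the basis set
#'
#' Computes the full overlap matrix \eqn{S_{ij} = \int \phi_i \phi_j \, dr}
#' of the (renormalized) contracted basis functions by Gaussian product
#' integrals.  The diagonal is 1 by construction; off-diagonal blocks feed
#' the Mulliken overlap-population sum rule used to validate grid integrals
#' of the pair overlap density.
#'
#' @param wfn a `wavefunction` object
#' @return symmetric numeric matrix, `n_basis x n_basis`
#' @export
overlap_matrix <- function(wfn) {
  stopifnot(inherits(wfn, "wavefunction"))
  cpp_overlap_matrix(compile_basis(wfn))
}

#' Analytic Mulliken overlap population of a fragment pair
#'
#' The signed two-center population \eqn{2 \sum_l n_l \sum_{i \in A, j \in B}
#' c_{li} c_{lj} S_{ij}}: the exact value of the spatial integral of the
#' unclamped pair overlap density.
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @return scalar (electrons)
#' @export
mulliken_overlap_population <- function(wfn, pair) {
  stopifnot(inherits(wfn, "wavefunction"), inherits(pair, "fragment_pair"))
  S <- overlap_matrix(wfn)
  ia <- fragment_basis_indices(wfn, pair$fragment_a)
  ib <- fragment_basis_indices(wfn, pair$fragment_b)
  C <- wfn$mo_coefficients
  # 2 * sum_l n_l (C_A^T S_AB C_B)_ll
  CA <- C[ia, , drop = FALSE]
  CB <- C[ib, , drop = FALSE]
  SAB <- S[ia, ib, drop = FALSE]
  2 * sum(wfn$occupations * colSums(CA * (SAB %*% CB)))
}
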