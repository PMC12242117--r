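# Shared helpers: finite-difference derivative checks and quick access to
# the shipped DFT wavefunctions (parsed once per test run).

fixture_cache <- new.env(parent = emptyenv())

fixture_wfn <- function(system) {
  key <- paste0("wfn_", system)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- opdensity:::with_compiled_basis(
      op_example_wavefunction(system))
  fixture_cache[[key]]
}

# central finite differences of a scalar field sampled through fun(points)
fd_gradient <- function(fun, point, h = 1e-4) {
  vapply(1:3, function(k) {
    e <- c(0, 0, 0); e[k] <- h
    (fun(point + e) - fun(point - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(fun, point, h = 1e-4) {
  H <- matrix(0, 3, 3)
  f0 <- fun(point)
  for (i in 1:3) {
    ei <- c(0, 0, 0); ei[i] <- h
    H[i, i] <- (fun(point + ei) - 2 * f0 + fun(point - ei)) / h^2
    for (j in seq_len(i - 1)) {
      ej <- c(0, 0, 0); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fun(point + ei + ej) - fun(point + ei - ej) -
           fun(point - ei + ej) + fun(point - ei - ej)) / (4 * h^2)
    }
  }
  H
}

# midpoint between two atoms of a wavefunction
bond_midpoint <- function(wfn, i, j) {
  a <- wfn$atoms
  c(a$x[i] + a$x[j], a$y[i] + a$y[j], a$z[i] + a$z[j]) / 2
}

bond_length_angstrom <- function(wfn, i, j) {
  a <- wfn$atoms
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2) *
    opdensity:::BOHR_TO_ANGSTROM
}

# one-center density of a single atom's basis functions (0.5 x the "pair"
# density of the atom with itself), used by the decomposition tests
one_center_density <- function(wfn, atom, points) {
  fb <- opdensity:::compile_basis(wfn)
  idx <- fragment_basis_indices(wfn, atom) - 1L
  0.5 * opdensity:::cpp_pair_density(fb, wfn$mo_coefficients,
                                     wfn$occupations, idx, idx,
                                     points, 0L)$value
}
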