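# The two-center toy systems have closed forms for every quantity below:
# with two unit-normalized s Gaussians phi_1, phi_2 (exponent a, distance R,
# overlap S = exp(-a R^2 / 2)) and the doubly occupied bonding orbital
# c (phi_1 + phi_2), c = [2(1+S)]^(-1/2), the pair density is
# 4 c^2 phi_1 phi_2 and its integral the Mulliken population 4 c^2 S.

test_that("toy overlap density matches the closed form at the midpoint", {
  a <- 1; R <- 1.4
  w <- make_h2_toy(a, R, "symmetric")
  pair <- fragment_pair(1, 2, "H-H")
  S <- gaussian_s_overlap(a, R)
  cc <- 1 / (2 * (1 + S))
  phi_mid <- (2 * a / pi)^0.75 * exp(-a * (R / 2)^2)
  expect_equal(overlap_density_at(w, pair, c(0, 0, R / 2)),
               4 * cc * phi_mid^2, tolerance = 1e-12)
  # far from fragment B every pairwise product vanishes numerically
  expect_equal(overlap_density_at(w, pair, c(0, 0, -40)), 0)
})

test_that("antibonding orbital has a clamped node between the nuclei", {
  w <- make_h2_toy(1, 1.4, "antisymmetric")
  pair <- fragment_pair(1, 2)
  z <- seq(0.05, 1.35, length.out = 40)
  pts <- cbind(0, 0, z)
  signed <- overlap_density_at(w, pair, pts, clamp = FALSE)
  clamped <- overlap_density_at(w, pair, pts, clamp = TRUE)
  expect_true(all(signed < 0))        # destructive interference throughout
  expect_true(all(clamped == 0))
  # at the orbital node the signed two-center term is maximally negative,
  # -4 c^2 phi(R/2)^2 (the one-center terms cancel it to give psi^2 = 0)
  S <- gaussian_s_overlap(1, 1.4)
  phi_mid <- (2 / pi)^0.75 * exp(-0.49)
  expect_equal(overlap_density_at(w, pair, c(0, 0, 0.7), clamp = FALSE),
               -4 * phi_mid^2 / (2 * (1 - S)), tolerance = 1e-12)
})

test_that("clamping is idempotent and clamps the total pair sum per point", {
  w <- fixture_wfn("h2o_dimer")
  pair <- fragment_pair(3, 4, "H...O")  # donor H, acceptor O
  set.seed(5)
  pts <- matrix(rnorm(300, sd = 2), ncol = 3)
  v1 <- overlap_density_at(w, pair, pts)
  expect_true(all(v1 >= 0))
  expect_identical(pmax(v1, 0), v1)
  signed <- overlap_density_at(w, pair, pts, clamp = FALSE)
  expect_identical(v1, pmax(signed, 0))
})

test_that("signed pair integral equals the Mulliken population (sum rule)", {
  # property-style sweep over exponents and bond lengths, both orbitals
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = 0, y = 0, z = c(0, 1))
  for (a in c(0.5, 1, 2)) {
    for (R in c(1.0, 1.4, 2.0)) {
      for (kind in c("symmetric", "antisymmetric")) {
        w <- make_h2_toy(a, R, kind)
        pair <- fragment_pair(1, 2)
        g <- build_becke_grid(w$atoms, 60, 110)
        f <- integrate_rho_op(w, pair, g)
        S <- gaussian_s_overlap(a, R)
        pop <- if (kind == "symmetric") 4 * S / (2 * (1 + S)) else
          -4 * S / (2 * (1 - S))
        expect_equal(f$signed_integral, pop, tolerance = 1e-4)
        expect_equal(mulliken_overlap_population(w, pair), pop,
                     tolerance = 1e-12)
        expect_gte(f$rho_op_integrated, max(f$signed_integral, 0))
      }
    }
  }
})

test_that("total density decomposes into one- plus two-center terms", {
  w <- fixture_wfn("h2o")
  set.seed(9)
  pts <- matrix(rnorm(60, sd = 1.5), ncol = 3)
  rho <- eval_density(w, pts)$value
  recon <- Reduce(`+`, lapply(1:3, function(a)
    one_center_density(w, a, pts)))
  for (a in 1:2) for (b in (a + 1):3)
    recon <- recon + overlap_density_at(w, fragment_pair(a, b), pts,
                                        clamp = FALSE)
  expect_lt(max(abs(recon - rho)), 1e-10)
})

test_that("integrated overlap density is invariant under rigid motion", {
  base <- make_h2_toy(0.8, 1.5)
  pair <- fragment_pair(1, 2)
  g <- build_becke_grid(base$atoms, 75, 302)
  f0 <- integrate_rho_op(base, pair, g)
  # rotate the bond axis and translate (s functions carry no orientation,
  # so the toy coefficients transfer unchanged)
  th <- 0.63
  Rz <- 1.5 * c(sin(th), 0, cos(th))
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = c(1, 1 + Rz[1]), y = c(-2, -2 + Rz[2]),
                      z = c(0.5, 0.5 + Rz[3]))
  rot <- wavefunction(atoms, lapply(base$shells, function(s) s),
                      base$mo_coefficients, base$occupations)
  g2 <- build_becke_grid(rot$atoms, 75, 302)
  f1 <- integrate_rho_op(rot, pair, g2)
  expect_equal(f1$rho_op_integrated, f0$rho_op_integrated, tolerance = 1e-6)
})

test_that("Gaussian self-repulsion closed form is recovered within 0.5%", {
  # synthetic unit-charge field rho = (a/pi)^(3/2) exp(-a r^2):
  # J = sqrt(2 a / pi) hartree exactly
  a_field <- 1
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = 0, y = 0, z = c(-0.01, 0.01))
  g <- build_pair_region_grid(atoms, c(1, 2), padding = 4.2, spacing = 0.2)
  vals <- (a_field / pi)^1.5 * exp(-a_field * rowSums(g$points^2))
  f <- structure(list(pair = fragment_pair(1, 2, "synthetic"), grid = g,
                      values = vals, rho_op_integrated = sum(g$weights * vals),
                      signed_integral = NA_real_, j_intra = NA_real_,
                      provenance = list()), class = "op_field")
  J <- suppressWarnings(j_op_intra(f, threshold = 1e-7))
  expect_equal(attr(J, "hartree"), sqrt(2 * a_field / pi), tolerance = 5e-3)
})

test_that("J decreases when the same charge spreads over a larger volume", {
  # scaled Gaussians all carry unit charge; J scales as sqrt(a)
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = 0, y = 0, z = c(-0.01, 0.01))
  g <- build_pair_region_grid(atoms, c(1, 2), padding = 5, spacing = 0.3)
  js <- vapply(c(2, 1, 0.5), function(a) {
    vals <- (a / pi)^1.5 * exp(-a * rowSums(g$points^2))
    f <- structure(list(pair = fragment_pair(1, 2), grid = g, values = vals,
                        rho_op_integrated = sum(g$weights * vals),
                        signed_integral = NA_real_, j_intra = NA_real_,
                        provenance = list()), class = "op_field")
    attr(suppressWarnings(j_op_intra(f)), "hartree")
  }, numeric(1))
  expect_true(all(diff(js) < 0))
})

test_that("degenerate overlap-density inputs error cleanly", {
  w <- make_h2_toy()
  expect_error(fragment_pair(1, integer(0)), "non-empty")
  expect_error(fragment_pair(c(1, 2), 2), "disjoint")
  f0 <- structure(list(pair = fragment_pair(1, 2),
                       grid = build_pair_region_grid(w$atoms, c(1, 2),
                                                     padding = 1,
                                                     spacing = 0.5),
                       values = 0, rho_op_integrated = 0,
                       signed_integral = 0, j_intra = NA_real_,
                       provenance = list()), class = "op_field")
  f0$values <- rep(0, nrow(f0$grid$points))
  expect_warning(j0 <- j_op_intra(f0), "empty positive region")
  expect_equal(as.numeric(j0), 0)
})

test_that("bond-axis profiles behave as the geometry dictates", {
  w <- make_h2_toy(1, 1.4)
  pair <- fragment_pair(1, 2)
  prof <- profile_along_axis(w, pair, c(0, 0, 0), c(0, 0, 1.4), 101)
  # symmetric about the midpoint
  expect_equal(prof$rho_op, rev(prof$rho_op), tolerance = 1e-10)
  # total density dominates the overlap density at the nuclei
  expect_true(all(prof$rho_total >= prof$rho_op - 1e-12))
  expect_error(profile_along_axis(w, pair, c(0, 0, 0), c(0, 0, 0)),
               "coincident")
  expect_error(profile_along_axis(w, pair, c(0, 0, 0), c(0, 0, 1), 1),
               "n_samples")
})

test_that("hydrogen-bond overlap profile peaks where the OCP sits", {
  # the overlap density along the H...O axis carries a local maximum in the
  # bond interior (the overlap critical point); closer than ~1 bohr to the
  # acceptor oxygen the donor-tail x acceptor-core products rise again, so
  # the in-bond extremum is checked in the window between the atomic cores
  # against an independent 1000-sample scan
  w <- fixture_wfn("h2o_dimer")
  a <- w$atoms
  pair <- fragment_pair(3, 4, "H...O")  # donor H (3) -> acceptor O (4)
  from <- c(a$x[3], a$y[3], a$z[3]); to <- c(a$x[4], a$y[4], a$z[4])
  len <- sqrt(sum((to - from)^2))
  prof <- profile_along_axis(w, pair, from, to, 1000)
  # seed 40/60 toward the hydrogen: the midpoint seed of a hydrogen bond
  # can land on the saddle between the in-bond lobe and the acceptor-core
  # bump instead of the in-bond maximum
  ocp <- find_ocp(w, pair, from + 0.4 * (to - from))
  expect_true(all(ocp$eigenvalues < 0))
  s_ocp <- sqrt(sum((ocp$position - from)^2))
  expect_gt(s_ocp, 0.5); expect_lt(s_ocp, len - 1.0)
  # the hydrogen bond is bent, so the OCP lies near but not exactly on the
  # internuclear line: the line scan has its in-bond local maximum within
  # a tenth of a bohr of the OCP arc position, slightly below the OCP value
  win <- which(abs(prof$s_bohr - s_ocp) < 0.5)
  peak <- win[which.max(prof$rho_op[win])]
  expect_gt(peak, min(win)); expect_lt(peak, max(win))
  expect_lt(abs(s_ocp - prof$s_bohr[peak]), 0.1)
  expect_lte(max(prof$rho_op[win]), ocp$value)
  expect_equal(max(prof$rho_op[win]), ocp$value, tolerance = 0.05)
  # direct 3-d sampling confirms a genuine local maximum of the pair field
  set.seed(21)
  off <- matrix(rnorm(900), ncol = 3)
  off <- off / sqrt(rowSums(off^2)) * runif(300, 0.02, 0.25)
  nb <- overlap_density_at(w, pair, sweep(off, 2, ocp$position, `+`))
  expect_true(all(nb < ocp$value))
})
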