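test_that("a single Gaussian density peak is found as a (3,-3) maximum", {
  # orbital exponent 0.5: the density exp(-r^2) keeps a 0.5-bohr-off-center
  # seed inside the Newton basin of the maximum (inflection at r = 0.71)
  w <- make_h2_toy(0.5, 60, "custom", coefficients = c(1, 0), occupation = 1)
  cp <- find_bcp(w, c(0.4, -0.2, 0.25))
  expect_equal(cp$position, c(0, 0, 0), tolerance = 1e-8)
  expect_identical(cp$rank, 3L)
  expect_identical(cp$signature, -3L)
  expect_lt(cp$gradient_norm, 1e-10)
  expect_lt(cp$laplacian, 0)
})

test_that("homonuclear toy bond critical point sits at the exact midpoint", {
  w <- make_h2_toy(1.1, 1.6)
  cp <- find_bcp(w, c(0.05, -0.03, 0.9))  # seed off the midpoint
  expect_equal(cp$position, c(0, 0, 0.8), tolerance = 1e-8)
  expect_identical(cp$signature, -1L)
  # independently re-evaluated gradient at the reported position
  g <- opdensity:::density_field_evaluator(w)(cp$position)$gradient
  expect_lt(sqrt(sum(g^2)), 1e-10)
})

test_that("toy overlap critical point is the symmetric in-bond maximum", {
  w <- make_h2_toy(1, 1.4)
  pair <- fragment_pair(1, 2)
  ocp <- find_ocp(w, pair, c(0.1, 0.1, 0.6))
  expect_equal(ocp$position, c(0, 0, 0.7), tolerance = 1e-8)
  expect_true(all(ocp$eigenvalues < 0))
  expect_lt(ocp$laplacian, 0)
  d <- ocp_descriptors(w, pair, ocp)
  expect_equal(d$rho_ocp, ocp$value)
})

test_that("critical point searches honor their contracts", {
  w <- make_h2_toy(1, 1.4)
  pair <- fragment_pair(1, 2)
  bcp <- find_bcp(w, c(0, 0, 0.7))
  # wrong field kind / signature
  ocp <- find_ocp(w, pair, c(0, 0, 0.7))
  expect_error(bcp_descriptors(w, ocp), "contract error")
  max3 <- find_bcp(w, c(0.2, 0, 0.05))   # nuclear-region (3,-3) maximum
  expect_error(bcp_descriptors(w, max3), "contract error")
  expect_error(ocp_descriptors(w, pair, bcp), "contract error")
  # antibonding orbital: no positive basin between the nuclei
  wa <- make_h2_toy(1, 1.4, "antisymmetric")
  expect_error(find_ocp(wa, pair, c(0, 0, 0.7)), "search-failure")
  # far-from-density seed cannot converge onto a bond CP
  expect_error(find_bcp(w, c(80, 80, 80), max_iter = 25), "search-failure")
  expect_error(find_bcp(w, c(0, NA, 0)), "input error")
})

test_that("line-scan minimum agrees with the Newton bond critical point", {
  w <- fixture_wfn("h2o")
  a <- w$atoms
  bcp <- find_bcp(w, bond_midpoint(w, 1, 2))
  # dense scan along the (near-linear) O-H bond path, with parabolic
  # refinement of the discrete minimum
  t <- seq(0.02, 0.98, by = 0.02 / 1.81)
  pts <- cbind(a$x[1] + t * (a$x[2] - a$x[1]),
               a$y[1] + t * (a$y[2] - a$y[1]),
               a$z[1] + t * (a$z[2] - a$z[1]))
  rho <- eval_density(w, pts)$value
  k <- which.min(rho)
  y <- rho[(k - 1):(k + 1)]
  refined <- y[2] - (y[3] - y[1])^2 / (8 * (y[1] - 2 * y[2] + y[3]))
  # the O-H bond path bends slightly off the internuclear line (the line
  # scan dips below the saddle by ~1e-4), so the straight-line oracle is
  # held to 2e-4; the exactly-linear toy below carries the tight bound
  expect_equal(refined, bcp$value, tolerance = 2e-4)
  wt <- make_h2_toy(1.1, 1.6)
  tb <- find_bcp(wt, c(0.02, 0, 0.82))
  tt <- seq(0.3, 1.3, by = 0.002)
  trho <- eval_density(wt, cbind(0, 0, tt))$value
  tk <- which.min(trho)
  ty <- trho[(tk - 1):(tk + 1)]
  trefined <- ty[2] - (ty[3] - ty[1])^2 / (8 * (ty[1] - 2 * ty[2] + ty[3]))
  expect_equal(trefined, tb$value, tolerance = 1e-6)
})

test_that("DFT water O-H descriptors are internally consistent", {
  w <- fixture_wfn("h2o")
  bcp <- find_bcp(w, bond_midpoint(w, 1, 2))
  expect_identical(bcp$signature, -1L)
  bd <- bcp_descriptors(w, bcp)
  expect_identical(bd$h_bcp_ev / opdensity:::HARTREE_TO_EV, bd$G + bd$V)
  expect_lt(bd$H, 0)   # shared-shell covalent bond
  pair <- fragment_pair(1, 2)
  ocp <- find_ocp(w, pair, bond_midpoint(w, 1, 2))
  expect_true(all(ocp$eigenvalues < 0))
})

test_that("descriptors are invariant under rigid-body transformation", {
  base <- make_h2_toy(0.9, 1.5)
  cp0 <- find_bcp(base, c(0, 0, 0.75))
  th <- 1.1
  d <- 1.5 * c(sin(th), 0, cos(th))
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = c(2, 2 + d[1]), y = c(1, 1), z = c(-1, -1 + d[3]))
  rot <- wavefunction(atoms, base$shells, base$mo_coefficients,
                      base$occupations)
  cp1 <- find_bcp(rot, c(2, 1, -1) + d / 2 + c(0.02, -0.02, 0.01))
  expect_equal(cp1$value, cp0$value, tolerance = 1e-8)
  expect_equal(cp1$laplacian, cp0$laplacian, tolerance = 1e-8)
  expect_equal(sort(cp1$eigenvalues), sort(cp0$eigenvalues),
               tolerance = 1e-8)
})

test_that("bond seeds are midpoints plus hydrogen-bond splits", {
  atoms <- data.frame(element = c("O", "H"), zatom = c(8L, 1L),
                      x = c(0, 0), y = c(0, 0), z = c(0, 2))
  s <- seed_bond_points(atoms, list(c(1, 2)))
  expect_length(s, 1L)
  expect_equal(s[[1]]$point, c(0, 0, 1))
  expect_identical(seed_bond_points(atoms, list()), list())
  # 1.9 A apart with an H atom: hydrogen bond, two distinct seeds
  atoms$z[2] <- 1.9 / opdensity:::BOHR_TO_ANGSTROM
  s <- seed_bond_points(atoms, list(c(1, 2)))
  expect_length(s, 2L)
  expect_false(isTRUE(all.equal(s[[1]]$point, s[[2]]$point)))
  expect_equal(s[[2]]$point[3], 0.6 * atoms$z[2])  # 40/60 toward H
})
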