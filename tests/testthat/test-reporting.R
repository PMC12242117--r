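# Pipeline tests run on economical grids: the descriptor values they check
# are self-consistency and determinism properties, not reference numbers,
# so a (35, 110) Becke grid and 0.3-bohr pair boxes keep them fast.

fast_config <- function(path, bonds, label = "test") {
  analysis_config(wavefunction_path = path, bonds = bonds,
                  system_label = label,
                  grid = list(radial = 35L, angular = 110L),
                  pair_grid = list(spacing = 0.3, padding = 3.5))
}

test_that("analyze_bonds produces a complete record per bond", {
  path <- op_example_wavefunction("h2o", as_path = TRUE)
  cfg <- fast_config(path, list(list(i = 1L, j = 2L, label = "O-H"),
                                list(i = 1L, j = 3L, label = "O-H'")))
  tab <- suppressWarnings(analyze_bonds(cfg))
  expect_s3_class(tab, "bond_descriptor_table")
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.na(tab$error)))
  expect_equal(tab$r_angstrom[1], bond_length_angstrom(fixture_wfn("h2o"),
                                                       1, 2),
               tolerance = 1e-12)
  expect_true(all(tab$rho_op_e > 0))
  expect_true(all(tab$j_intra_ev > 0))
  expect_true(all(tab$rho_ocp > 0 & tab$laplacian_ocp < 0))
  expect_true(all(tab$h_bcp_ev < 0 & tab$rho_bcp > 0))
  # the two O-H bonds of water are symmetry-equivalent
  expect_equal(tab$rho_bcp[1], tab$rho_bcp[2], tolerance = 1e-6)
})

test_that("per-bond failures are recorded without aborting the batch", {
  w <- fixture_wfn("h2o_dimer")
  path <- op_example_wavefunction("h2o_dimer", as_path = TRUE)
  # atoms 2 and 6 are on different molecules > 5 A apart: no CP between them
  expect_gt(bond_length_angstrom(w, 2, 6), 3.5)
  cfg <- fast_config(path, list(list(i = 1L, j = 2L, label = "O-H"),
                                list(i = 2L, j = 6L, label = "far")))
  tab <- suppressWarnings(analyze_bonds(cfg))
  expect_true(is.na(tab$error[1]))
  expect_match(tab$error[2], "critical point|search-failure")
  expect_true(is.na(tab$rho_ocp[2]))
  # a bond naming a missing atom fails the whole config upfront
  bad <- fast_config(path, list(list(i = 1L, j = 99L, label = "bad")))
  expect_error(analyze_bonds(bad), "missing atom")
})

test_that("the pipeline is deterministic: identical CSV byte-for-byte", {
  path <- op_example_wavefunction("h2o", as_path = TRUE)
  cfg <- fast_config(path, list(list(i = 1L, j = 2L, label = "O-H")))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(suppressWarnings(analyze_bonds(cfg)), f1)
  write_descriptor_csv(suppressWarnings(analyze_bonds(cfg)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # provenance header names the tool version and the grid
  expect_match(readLines(f1)[1], "opdensity .*becke grid \\(35,110\\)")
})

test_that("correlation matrix handles exact dependences and degeneracies", {
  rec <- data.frame(rho_op_e = c(1, 2, 3, 4), rho_ocp = c(0.5, 1, 1.5, 2),
                    j_intra_ev = c(4, 3, 2, 1), laplacian_ocp = 1)
  cm <- suppressWarnings(correlation_matrix(
    rec, c("rho_op_e", "rho_ocp", "j_intra_ev")))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(unname(cm["rho_op_e", "rho_ocp"]), 1)       # exact 2x scaling
  expect_equal(unname(cm["rho_op_e", "j_intra_ev"]), -1)   # anti-proportional
  expect_true(all(cm >= -1 & cm <= 1))
  expect_identical(cm, t(cm))
  expect_warning(correlation_matrix(rec, c("rho_op_e", "laplacian_ocp")),
                 "constant")
  expect_error(correlation_matrix(rec[1:2, ], c("rho_op_e", "rho_ocp")),
               "at least 3")
})

test_that("cube export writes valid files that round-trip", {
  atoms <- fixture_wfn("h2o")$atoms
  # 2x2x2 constant payload
  f <- withr::local_tempfile(fileext = ".cube")
  export_cube(array(7, c(2, 2, 2)), c(0, 0, 0), c(0.5, 0.5, 0.5), atoms, f)
  back <- read_cube(f)
  expect_equal(as.vector(back$values), rep(7, 8))
  expect_identical(back$natoms, 3L)
  # overlap-density cube: non-trivial payload, all values >= 0
  w <- fixture_wfn("h2o")
  f2 <- withr::local_tempfile(fileext = ".cube")
  cube_rho_op(w, fragment_pair(1, 2, "O-H"), f2, padding = 2, spacing = 0.4)
  back2 <- read_cube(f2)
  expect_true(all(back2$values >= 0))
  expect_gt(max(back2$values), 0.1)
  # round-trip of the written values against a direct re-evaluation
  g <- build_pair_region_grid(atoms, c(1, 2), padding = 2, spacing = 0.4)
  direct <- overlap_density_at(w, fragment_pair(1, 2), g$points)
  expect_equal(as.vector(back2$values), as.vector(array(direct, g$dims)),
               tolerance = 1e-4)
})

test_that("the command-line interface runs end to end", {
  out <- withr::local_tempdir()
  path <- op_example_wavefunction("h2o", as_path = TRUE)
  st <- suppressWarnings(suppressMessages(opdensity_cli(c(
    "analyze", "--wfn", path, "--bonds", "1-2:O-H", "--grid", "35,110",
    "--spacing", "0.3", "--padding", "3.5", "--out", out,
    "--log-level", "warning"))))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "descriptors.csv")))
  st2 <- suppressMessages(opdensity_cli(c(
    "profile", "--wfn", path, "--bonds", "1-2:O-H", "--n", "50",
    "--out", out)))
  expect_identical(st2, 0L)
  prof <- utils::read.csv(file.path(out, "profile_O_H.csv"))
  expect_identical(names(prof), c("s_angstrom", "rho_total", "rho_op"))
  expect_identical(nrow(prof), 50L)
  expect_identical(suppressMessages(opdensity_cli(character(0))), 2L)
})
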