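# Test-input generation: closed-form toy wavefunctions built in memory, the
# driver for regenerating DFT fixtures with an external SCF engine, and
# loaders for the DFT wavefunctions shipped with the package.

#' Analytic overlap of two s-type Gaussian primitives with equal exponent
#'
#' \eqn{S = \exp(-\alpha R^2 / 2)} for unit-normalized s Gaussians a
#' distance `R` apart: the closed form behind the two-center toy fixtures.
#'
#' @param alpha Gaussian exponent (1/bohr^2)
#' @param distance center separation (bohr)
#' @return overlap integral in (0, 1]
#' @export
gaussian_s_overlap <- function(alpha, distance) exp(-alpha * distance^2 / 2)

#' Minimal H2-like toy wavefunction
#'
#' Two protons on the z axis a bond length apart, one single-primitive
#' s shell each, and one doubly occupied molecular orbital: the symmetric
#' (bonding) or antisymmetric (antibonding) combination with the exact
#' normalization \eqn{c = [2(1 \pm S)]^{-1/2}}, or custom coefficients.
#' Every quantity of this fixture has a closed form, which makes it the
#' oracle substrate for the overlap-density and topology tests.
#'
#' @param alpha s-Gaussian exponent (> 0)
#' @param bond_length internuclear distance, bohr (> 0)
#' @param mo_kind "symmetric", "antisymmetric", or "custom"
#' @param coefficients length-2 coefficients when `mo_kind = "custom"`
#' @param occupation occupation of the single orbital (default 2)
#' @return a `wavefunction`
#' @export
make_h2_toy <- function(alpha = 1, bond_length = 1.4,
                        mo_kind = c("symmetric", "antisymmetric", "custom"),
                        coefficients = NULL, occupation = 2) {
  stopifnot(alpha > 0, bond_length > 0)
  mo_kind <- match.arg(mo_kind)
  S <- gaussian_s_overlap(alpha, bond_length)
  co <- switch(mo_kind,
    symmetric = rep(1 / sqrt(2 * (1 + S)), 2),
    antisymmetric = c(1, -1) / sqrt(2 * (1 - S)),
    custom = coefficients)
  if (is.null(co) || length(co) != 2L)
    stop("custom mo_kind needs length-2 coefficients")
  atoms <- data.frame(element = c("H", "H"), zatom = c(1L, 1L),
                      x = c(0, 0), y = c(0, 0), z = c(0, bond_length),
                      stringsAsFactors = FALSE)
  shells <- list(
    list(atom = 1L, l = 0L, exponents = alpha, coefficients = 1,
         spherical = FALSE),
    list(atom = 2L, l = 0L, exponents = alpha, coefficients = 1,
         spherical = FALSE))
  wavefunction(atoms, shells, matrix(co, 2, 1), occupation,
               orbital_energies = NA_real_)
}

#' Path to (or wavefunction from) a shipped DFT fixture
#'
#' The package ships compact Molden files for small hydrogen-bond systems,
#' produced by the external-engine driver (see [make_dft_fixture()]) at
#' the wB97X-D/def2-TZVP level with virtual orbitals removed.  Each file
#' has a JSON provenance sidecar recording the engine, final SCF energy and
#' optimized geometry.
#'
#' @param system one of `"h2o"`, `"h2o_r0960"` (monomer with the O-H bonds
#'   constrained to the 0.960-Angstrom reference length), `"h2o_dimer"`,
#'   `"meoh_h2o"`, `"dme_h2o"`
#' @param as_path return the file path instead of parsing it
#' @return a `wavefunction`, or a path when `as_path = TRUE`
#' @export
op_example_wavefunction <- function(system = c("h2o", "h2o_r0960",
                                               "h2o_dimer", "meoh_h2o",
                                               "dme_h2o"),
                                    as_path = FALSE) {
  system <- match.arg(system)
  path <- system.file("extdata", paste0(system, ".molden"),
                      package = "opdensity", mustWork = TRUE)
  if (as_path) path else parse_molden(path)
}

#' Regenerate a DFT fixture with an external SCF engine
#'
#' Drives the shipped pyscf script (geometry optimization + SCF at
#' wB97X-D/def2-TZVP, Molden export).  The package itself never depends on
#' the engine; when the engine or its Python modules are unavailable the
#' function returns a skip marker instead of failing, and the shipped
#' fixtures remain the test inputs.
#'
#' @param system_id one of `"h2o"`, `"h2o_r0960"`, `"h2o_dimer"`,
#'   `"meoh_h2o"`, `"dme_h2o"`
#' @param outdir output directory for the Molden + provenance files
#' @param engine_command Python interpreter with pyscf + geometric
#' @return list with `status` ("ok" or "skipped"), `molden`, `provenance`
#' @export
make_dft_fixture <- function(system_id, outdir = tempdir(),
                               engine_command = "python") {
  script <- system.file("scripts", "make_fixture.py", package = "opdensity",
                        mustWork = TRUE)
  probe <- suppressWarnings(system2(engine_command,
    c("-c", shQuote("import pyscf, geometric")),
    stdout = FALSE, stderr = FALSE))
  if (!identical(probe, 0L))
    return(list(status = "skipped",
                reason = "SCF engine (python + pyscf + geometric) unavailable"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  code <- system2(engine_command, c(script, system_id, outdir))
  if (!identical(code, 0L)) stop("fixture generation failed for ", system_id)
  list(status = "ok",
       molden = file.path(outdir, paste0(system_id, ".molden")),
       provenance = file.path(outdir, paste0(system_id, ".provenance.json")))
}
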