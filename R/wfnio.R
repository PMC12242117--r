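# Molden wavefunction I/O and the in-memory wavefunction representation.
#
# A `wavefunction` is a list with:
#   atoms:   data.frame(element, z, x, y, z) -- coordinates in bohr
#   shells:  list of shells: list(atom, l, exponents, coefficients, spherical)
#   mo_coefficients: m x M matrix (basis functions x orbitals, Molden order)
#   occupations: length-M vector of n_l >= 0 (spin channels summed for
#                closed-shell input; open-shell files keep separate columns
#                per spin orbital with their own occupations)
#   orbital_energies, spins: length-M metadata
# Internal units are atomic (bohr, hartree) everywhere.

.L_FROM_LETTER <- c(s = 0L, p = 1L, d = 2L, f = 3L, g = 4L)
.LETTER_FROM_L <- c("s", "p", "d", "f", "g")

#' Construct and validate a wavefunction object
#'
#' @param atoms data.frame with columns `element`, `zatom` (atomic number),
#'   `x`, `y`, `z` (coordinates in bohr)
#' @param shells list of Gaussian shells; each a list with `atom` (1-based
#'   index), `l` (angular momentum, 0--4), `exponents`, `coefficients`
#'   (equal-length positive/real vectors), `spherical` (logical)
#' @param mo_coefficients numeric matrix, basis functions x orbitals
#' @param occupations orbital occupation numbers `n_l >= 0`
#' @param orbital_energies optional orbital energies (hartree)
#' @param spins optional character vector ("alpha"/"beta")
#' @return object of class `wavefunction`
#' @export
wavefunction <- function(atoms, shells, mo_coefficients, occupations,
                         orbital_energies = NULL, spins = NULL) {
  if (length(shells) == 0L) stop("validation error: empty shell list")
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("validation error: non-finite atom positions")
  if (any(atoms$zatom < 1L)) stop("validation error: atomic number < 1")
  for (sh in shells) {
    if (length(sh$exponents) != length(sh$coefficients))
      stop("validation error: exponent/coefficient length mismatch")
    if (any(sh$exponents <= 0))
      stop("validation error: non-positive Gaussian exponent")
    if (sh$atom < 1L || sh$atom > nrow(atoms))
      stop("validation error: shell centered on missing atom")
    if (sh$l > 4L)
      stop("unsupported angular momentum l = ", sh$l, " (max supported: 4)")
  }
  mo_coefficients <- as.matrix(mo_coefficients)
  m_expected <- sum(shell_component_counts(shells))
  if (nrow(mo_coefficients) != m_expected)
    stop("validation error: MO coefficient rows (", nrow(mo_coefficients),
         ") != basis size (", m_expected, ")")
  if (ncol(mo_coefficients) != length(occupations))
    stop("validation error: MO columns != number of occupations")
  if (any(occupations < 0)) stop("validation error: negative occupation")
  structure(
    list(atoms = atoms, shells = shells, mo_coefficients = mo_coefficients,
         occupations = as.numeric(occupations),
         orbital_energies = orbital_energies %||% rep(NA_real_, length(occupations)),
         spins = spins %||% rep("alpha", length(occupations))),
    class = "wavefunction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wavefunction <- function(x, ...) {
  cat("<wavefunction>", nrow(x$atoms), "atoms,", length(x$shells), "shells,",
      nrow(x$mo_coefficients), "basis functions,",
      ncol(x$mo_coefficients), "orbitals, sum(occ) =",
      format(sum(x$occupations)), "\n")
  invisible(x)
}

#' Total electron count implied by the occupations
#' @param wfn a `wavefunction`
#' @return numeric scalar
#' @export
electron_count <- function(wfn) sum(wfn$occupations)

.section_lines <- function(lines, name) {
  tags <- grep("^\\s*\\[", lines)
  hit <- grep(paste0("^\\s*\\[", name, "\\]"), lines, ignore.case = TRUE)
  if (length(hit) == 0L) return(NULL)
  start <- hit[1]
  nexts <- tags[tags > start]
  end <- if (length(nexts)) nexts[1] - 1L else length(lines)
  list(header = lines[start], body = lines[seq(start + 1L, end)])
}

#' Parse a Molden wavefunction file
#'
#' Reads the `[Atoms]`, `[GTO]` and `[MO]` sections of a Molden file into a
#' validated [wavefunction()].  The `[5D]`/`[7F]`/`[9G]` pure-spherical flags
#' and the `AU`/`Angs` unit tag are honored; contracted basis functions are
#' renormalized on load, so files from engines with differing primitive
#' normalization conventions evaluate identically.
#'
#' @param path path to a Molden file
#' @param expected_electrons optional electron count to validate the summed
#'   occupations against (e.g. from a known molecular charge)
#' @return a `wavefunction`
#' @export
parse_molden <- function(path, expected_electrons = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  for (sec in c("Atoms", "GTO", "MO"))
    if (is.null(.section_lines(lines, sec)))
      stop("parse error: missing [", sec, "] section")

  spherical <- list(d = FALSE, f = FALSE, g = FALSE)
  if (any(grepl("\\[5D\\]|\\[5D7F\\]|\\[5D10F\\]", lines, ignore.case = TRUE)))
    spherical$d <- TRUE
  if (any(grepl("\\[5D\\]$|\\[5D7F\\]|\\[7F\\]", lines, ignore.case = TRUE)))
    spherical$f <- TRUE
  if (any(grepl("\\[5D10F\\]", lines, ignore.case = TRUE)))
    spherical$f <- FALSE
  if (any(grepl("\\[9G\\]", lines, ignore.case = TRUE)))
    spherical$g <- TRUE

  at <- .section_lines(lines, "Atoms")
  unit_scale <- if (grepl("Angs", at$header, ignore.case = TRUE))
    1 / BOHR_TO_ANGSTROM else 1
  arows <- at$body[nzchar(trimws(at$body))]
  afields <- strsplit(trimws(arows), "\\s+")
  atoms <- data.frame(
    element = vapply(afields, `[`, "", 1L),
    zatom = as.integer(vapply(afields, `[`, "", 3L)),
    x = as.numeric(vapply(afields, `[`, "", 4L)) * unit_scale,
    y = as.numeric(vapply(afields, `[`, "", 5L)) * unit_scale,
    z = as.numeric(vapply(afields, `[`, "", 6L)) * unit_scale,
    stringsAsFactors = FALSE)

  gto <- .section_lines(lines, "GTO")
  shells <- list()
  body <- gto$body
  i <- 1L
  n <- length(body)
  while (i <= n) {
    ln <- trimws(body[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    parts <- strsplit(ln, "\\s+")[[1]]
    atom_idx <- suppressWarnings(as.integer(parts[1]))
    if (is.na(atom_idx)) stop("parse error: malformed [GTO] atom header: ", ln)
    i <- i + 1L
    while (i <= n && nzchar(trimws(body[i]))) {
      hdr <- strsplit(trimws(body[i]), "\\s+")[[1]]
      type <- tolower(hdr[1])
      nprim <- as.integer(hdr[2])
      i <- i + 1L
      prim <- matrix(0, nprim, if (type == "sp") 3L else 2L)
      for (p in seq_len(nprim)) {
        row <- gsub("[dD]", "e", trimws(body[i]))
        prim[p, ] <- as.numeric(strsplit(row, "\\s+")[[1]])
        i <- i + 1L
      }
      if (type == "sp") {
        shells[[length(shells) + 1L]] <- list(atom = atom_idx, l = 0L,
          exponents = prim[, 1], coefficients = prim[, 2], spherical = FALSE)
        shells[[length(shells) + 1L]] <- list(atom = atom_idx, l = 1L,
          exponents = prim[, 1], coefficients = prim[, 3], spherical = FALSE)
      } else {
        l <- .L_FROM_LETTER[[type]]
        if (is.null(l)) stop("unsupported shell type: ", type)
        sph <- switch(type, d = spherical$d, f = spherical$f, g = spherical$g,
                      FALSE)
        if (l <= 1L) sph <- FALSE  # s/p identical in both conventions
        shells[[length(shells) + 1L]] <- list(atom = atom_idx, l = l,
          exponents = prim[, 1], coefficients = prim[, 2], spherical = sph)
      }
    }
    i <- i + 1L
  }
  # shells arrive grouped per atom in file order; keep that order (defines
  # the basis-function ordering the [MO] coefficients refer to)

  mo <- .section_lines(lines, "MO")
  m <- sum(shell_component_counts(shells))
  occ <- numeric(0); ene <- numeric(0); spin <- character(0)
  cols <- list()
  cur <- NULL
  cur_meta <- list(occ = 0, ene = NA_real_, spin = "alpha")
  flush <- function() {
    if (!is.null(cur)) {
      cols[[length(cols) + 1L]] <<- cur
      occ <<- c(occ, cur_meta$occ); ene <<- c(ene, cur_meta$ene)
      spin <<- c(spin, cur_meta$spin)
    }
  }
  for (ln in mo$body) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^Sym\\s*=", t, ignore.case = TRUE)) {
      flush(); cur <- rep(0, m)
      cur_meta <- list(occ = 0, ene = NA_real_, spin = "alpha")
    } else if (grepl("^Ene\\s*=", t, ignore.case = TRUE)) {
      if (is.null(cur)) { cur <- rep(0, m) }
      cur_meta$ene <- as.numeric(sub("^Ene\\s*=\\s*", "", t, ignore.case = TRUE))
    } else if (grepl("^Spin\\s*=", t, ignore.case = TRUE)) {
      cur_meta$spin <- tolower(trimws(sub("^Spin\\s*=\\s*", "", t, ignore.case = TRUE)))
    } else if (grepl("^Occup\\s*=", t, ignore.case = TRUE)) {
      cur_meta$occ <- as.numeric(sub("^Occup\\s*=\\s*", "", t, ignore.case = TRUE))
    } else {
      parts <- strsplit(t, "\\s+")[[1]]
      if (length(parts) >= 2L && !is.null(cur)) {
        idx <- as.integer(parts[1])
        if (is.na(idx) || idx < 1L || idx > m)
          stop("parse error: MO coefficient index ", parts[1],
               " outside basis size ", m)
        cur[idx] <- as.numeric(gsub("[dD]", "e", parts[2]))
      }
    }
  }
  flush()
  if (length(cols) == 0L) stop("parse error: [MO] section holds no orbitals")
  C <- do.call(cbind, cols)

  wfn <- wavefunction(atoms, shells, C, occ, ene, spin)
  if (!is.null(expected_electrons) &&
      abs(sum(occ) - expected_electrons) > 1e-6)
    stop("validation error: occupations sum to ", sum(occ),
         " but declared charge implies ", expected_electrons, " electrons")
  wfn
}

#' Write a wavefunction to a Molden file
#'
#' Numeric fields round-trip through [parse_molden()] to better than 1e-12
#' (coefficients are written with 17 significant digits).  Spherical shells
#' are declared with `[5D]`/`[7F]`/`[9G]` flags; mixed spherical/cartesian
#' sets within one angular momentum are rejected since Molden cannot express
#' them.
#'
#' @param wfn a `wavefunction`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_molden <- function(wfn, path) {
  stopifnot(inherits(wfn, "wavefunction"))
  for (l in 2:4) {
    flags <- vapply(wfn$shells, function(sh)
      if (sh$l == l) isTRUE(sh$spherical) else NA, NA)
    flags <- flags[!is.na(flags)]
    if (length(unique(flags)) > 1L)
      stop("cannot write Molden: mixed spherical/cartesian shells for l = ", l)
  }
  sph_flag <- function(l) {
    f <- vapply(wfn$shells, function(sh)
      if (sh$l == l) isTRUE(sh$spherical) else NA, NA)
    any(f[!is.na(f)])
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("I/O error: cannot write ", path)
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[Molden Format]")
  w("[Title]")
  w("written by opdensity")
  w("[Atoms] (AU)")
  a <- wfn$atoms
  for (i in seq_len(nrow(a)))
    w("%-3s %4d %4d %21.14e %21.14e %21.14e", a$element[i], i, a$zatom[i],
      a$x[i], a$y[i], a$z[i])
  w("[GTO]")
  for (i in seq_len(nrow(a))) {
    w("%d 0", i)
    for (sh in wfn$shells) {
      if (sh$atom != i) next
      w("%s %4d 1.00", .LETTER_FROM_L[sh$l + 1L], length(sh$exponents))
      for (p in seq_along(sh$exponents))
        w("  %21.14e %21.14e", sh$exponents[p], sh$coefficients[p])
    }
    w("")
  }
  if (sph_flag(2L)) w("[5D]")
  if (sph_flag(3L)) w("[7F]")
  if (sph_flag(4L)) w("[9G]")
  w("[MO]")
  C <- wfn$mo_coefficients
  for (l in seq_len(ncol(C))) {
    w(" Sym= A")
    w(" Ene= %21.14e", if (is.na(wfn$orbital_energies[l])) 0 else
      wfn$orbital_energies[l])
    w(" Spin= %s", if (tolower(wfn$spins[l]) == "beta") "Beta" else "Alpha")
    w(" Occup= %21.14e", wfn$occupations[l])
    for (f in seq_len(nrow(C)))
      w(" %4d %21.14e", f, C[f, l])
  }
  invisible(path)
}

#' Basis-function indices centered on a set of atoms
#'
#' Maps fragment atoms to the indices of the basis functions they carry
#' (Mulliken-style attribution of a function to its center atom).  Index
#' sets of disjoint fragments are disjoint, and the sets over all atoms
#' partition `1..n_basis`.
#'
#' @param wfn a `wavefunction`
#' @param atom_indices integer vector of 1-based atom indices (may be empty)
#' @return sorted integer vector of 1-based basis-function indices
#' @export
fragment_basis_indices <- function(wfn, atom_indices) {
  stopifnot(inherits(wfn, "wavefunction"))
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) == 0L) return(integer(0))
  if (any(atom_indices < 1L | atom_indices > nrow(wfn$atoms)))
    stop("index error: atom index out of range")
  counts <- shell_component_counts(wfn$shells)
  owner <- rep(vapply(wfn$shells, function(sh) sh$atom, integer(1)), counts)
  which(owner %in% atom_indices)
}
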