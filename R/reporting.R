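# End-to-end descriptor pipeline: wavefunction + bond list -> per-bond
# descriptor records, correlation summaries, cube export.

#' Analysis configuration
#'
#' @param wavefunction_path path to a Molden file (or `NULL` when a
#'   `wavefunction` is passed to [analyze_bonds()] directly)
#' @param bonds list of bonds; each `list(i, j, label)` with 1-based atom
#'   indices (labels must be unique)
#' @param system_label label for the molecular system
#' @param grid list(radial, angular) for the whole-space Becke grid
#' @param pair_grid list(spacing, padding) for the Coulomb pair-box grid
#' @param outdir optional output directory for CSV export
#' @return an `analysis_config` list
#' @export
analysis_config <- function(wavefunction_path = NULL, bonds,
                            system_label = "system",
                            grid = list(radial = 75L, angular = 302L),
                            pair_grid = list(spacing = 0.15, padding = 5),
                            outdir = NULL) {
  labels <- vapply(bonds, function(b) as.character(b$label %||%
    paste0(b$i, "-", b$j)), "")
  if (anyDuplicated(labels)) stop("bond labels must be unique")
  structure(list(wavefunction_path = wavefunction_path, bonds = bonds,
                 system_label = system_label, grid = grid,
                 pair_grid = pair_grid, outdir = outdir),
            class = "analysis_config")
}

#' Compute the full descriptor record for every configured bond
#'
#' For each bond: internuclear distance from the input geometry, integrated
#' overlap density and intra-overlap Coulomb repulsion of the two-atom
#' fragment pair, overlap-critical-point descriptors, and QTAIM
#' bond-critical-point descriptors (density, Laplacian, local energy
#' density).  Per-bond failures are recorded in the `error` column without
#' aborting the batch.
#'
#' @param config an [analysis_config()], or a `wavefunction` together with
#'   `bonds`
#' @param wfn optional pre-parsed `wavefunction` overriding
#'   `config$wavefunction_path`
#' @return data.frame (class `bond_descriptor_table`) with one row per
#'   bond: `system_label`, `bond_label`, `r_angstrom`, `rho_op_e`,
#'   `j_intra_ev`, `rho_ocp`, `laplacian_ocp`, `h_bcp_ev`, `laplacian_bcp`,
#'   `rho_bcp`, `error`; grid and file provenance in attributes
#' @export
analyze_bonds <- function(config, wfn = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(wfn)) {
    if (is.null(config$wavefunction_path))
      stop("no wavefunction: set wavefunction_path or pass wfn")
    wfn <- parse_molden(config$wavefunction_path)
  }
  wfn <- with_compiled_basis(wfn)
  atoms <- wfn$atoms
  for (b in config$bonds)
    if (any(c(b$i, b$j) < 1L) || any(c(b$i, b$j) > nrow(atoms)))
      stop("configuration error: bond references a missing atom")
  becke <- build_becke_grid(atoms, config$grid$radial, config$grid$angular)
  rows <- lapply(config$bonds, function(b) {
    label <- as.character(b$label %||% paste0(b$i, "-", b$j))
    p1 <- c(atoms$x[b$i], atoms$y[b$i], atoms$z[b$i])
    p2 <- c(atoms$x[b$j], atoms$y[b$j], atoms$z[b$j])
    r_ang <- sqrt(sum((p2 - p1)^2)) * BOHR_TO_ANGSTROM
    rec <- list(system_label = config$system_label, bond_label = label,
                atom_i = b$i, atom_j = b$j, r_angstrom = r_ang,
                rho_op_e = NA_real_, j_intra_ev = NA_real_,
                rho_ocp = NA_real_, laplacian_ocp = NA_real_,
                h_bcp_ev = NA_real_, laplacian_bcp = NA_real_,
                rho_bcp = NA_real_, error = NA_character_)
    tryCatch({
      pair <- fragment_pair(b$i, b$j, label)
      field <- integrate_rho_op(wfn, pair, becke)
      rec$rho_op_e <- field$rho_op_integrated
      box <- build_pair_region_grid(atoms, c(b$i, b$j),
                                    padding = config$pair_grid$padding,
                                    spacing = config$pair_grid$spacing)
      jfield <- integrate_rho_op(wfn, pair, box)
      rec$j_intra_ev <- as.numeric(j_op_intra(jfield))
      seeds <- seed_bond_points(atoms, list(c(b$i, b$j)))
      ocp_all <- lapply(seeds, function(s)
        try(find_ocp(wfn, pair, s$point), silent = TRUE))
      # the in-bond OCP is a maximum (all curvatures negative); hydrogen
      # bonds also have a saddle of the pair field nearer the acceptor,
      # which midpoint seeds may hit first
      ocp <- .best_cp(ocp_all, signature = -3L)
      if (is.null(ocp)) stop("no overlap critical point in search region")
      od <- ocp_descriptors(wfn, pair, ocp)
      rec$rho_ocp <- od$rho_ocp
      rec$laplacian_ocp <- od$laplacian_ocp
      bcp <- .best_cp(lapply(seeds, function(s)
        try(find_bcp(wfn, s$point), silent = TRUE)), signature = -1L)
      if (is.null(bcp)) stop("no critical point in search region")
      bd <- bcp_descriptors(wfn, bcp)
      rec$h_bcp_ev <- bd$h_bcp_ev
      rec$laplacian_bcp <- bd$laplacian_bcp
      rec$rho_bcp <- bd$rho_bcp
      rec
    }, error = function(e) { rec$error <- conditionMessage(e); rec })
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "provenance") <- list(
    package_version = as.character(utils::packageVersion("opdensity")),
    becke_grid = becke$provenance,
    pair_grid = config$pair_grid,
    wavefunction = config$wavefunction_path %||% "<in-memory>",
    wavefunction_sha = if (!is.null(config$wavefunction_path))
      unname(tools::md5sum(config$wavefunction_path)) else NA_character_)
  class(out) <- c("bond_descriptor_table", class(out))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_descriptor_csv(out, file.path(config$outdir, "descriptors.csv"))
  }
  out
}

# Pick the first successfully converged CP (optionally of a required
# signature) out of a list of try() results.
.best_cp <- function(cps, signature = NULL) {
  for (cp in cps) {
    if (inherits(cp, "try-error")) next
    if (!is.null(signature) && cp$signature != signature) next
    return(cp)
  }
  NULL
}

#' Write a descriptor table as CSV with provenance header comments
#' @param records a `bond_descriptor_table`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_descriptor_csv <- function(records, path) {
  prov <- attr(records, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) {
    writeLines(sprintf("# opdensity %s | becke grid (%d,%d) | wfn %s md5 %s",
                       prov$package_version, prov$becke_grid$radial_points,
                       prov$becke_grid$angular_points, prov$wavefunction,
                       prov$wavefunction_sha), con)
  }
  utils::write.csv(as.data.frame(records), con, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation matrix of descriptor columns
#'
#' @param records a `bond_descriptor_table` (or any data.frame), needs at
#'   least 3 complete rows
#' @param descriptors character vector of numeric columns to correlate
#' @return symmetric correlation matrix with unit diagonal
#' @export
correlation_matrix <- function(records,
                               descriptors = c("rho_op_e", "j_intra_ev",
                                               "rho_ocp", "laplacian_ocp",
                                               "h_bcp_ev", "laplacian_bcp",
                                               "rho_bcp")) {
  df <- as.data.frame(records)[, descriptors, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 complete records")
  keep <- vapply(df, function(col) stats::sd(col) > 0, TRUE)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(names(df)[!keep], collapse = ", "))
    df <- df[, keep, drop = FALSE]
  }
  stats::cor(as.matrix(df))
}

#' Export a volumetric field as a Gaussian cube file
#'
#' Standard cube layout: comment lines, atom count + origin, three voxel
#' vectors (bohr; positive atom count indicates bohr units), atom records,
#' then values with the last (z) index fastest.
#'
#' @param values 3-d numeric array (nx x ny x nz)
#' @param origin length-3 origin of the first voxel center minus half a
#'   step is not applied: `origin` is written as given (bohr)
#' @param step length-3 voxel edge lengths (bohr; axis-aligned voxels)
#' @param atoms atoms data.frame (may have zero rows)
#' @param path output path
#' @param comment first header line
#' @return invisibly, `path`
#' @export
export_cube <- function(values, origin, step, atoms, path,
                        comment = "opdensity field") {
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("I/O error: cannot write ", path)
  on.exit(close(con))
  d <- dim(values)
  writeLines(c(comment, sprintf("opdensity cube | %d x %d x %d voxels",
                                d[1], d[2], d[3])), con)
  writeLines(sprintf("%5d %13.6f %13.6f %13.6f", nrow(atoms),
                     origin[1], origin[2], origin[3]), con)
  writeLines(sprintf("%5d %13.6f %13.6f %13.6f", d[1], step[1], 0, 0), con)
  writeLines(sprintf("%5d %13.6f %13.6f %13.6f", d[2], 0, step[2], 0), con)
  writeLines(sprintf("%5d %13.6f %13.6f %13.6f", d[3], 0, 0, step[3]), con)
  if (nrow(atoms) > 0L)
    for (i in seq_len(nrow(atoms)))
      writeLines(sprintf("%5d %13.6f %13.6f %13.6f %13.6f", atoms$zatom[i],
                         as.numeric(atoms$zatom[i]), atoms$x[i], atoms$y[i],
                         atoms$z[i]), con)
  # z fastest: iterate x, then y, 6 values per line
  for (ix in seq_len(d[1]))
    for (iy in seq_len(d[2])) {
      vals <- values[ix, iy, ]
      for (k in seq(1L, length(vals), by = 6L)) {
        chunk <- vals[k:min(k + 5L, length(vals))]
        writeLines(paste(sprintf("%13.5e", chunk), collapse = " "), con)
      }
    }
  invisible(path)
}

#' Read a Gaussian cube file written by [export_cube()]
#'
#' @param path cube file path
#' @return list with `values` (3-d array), `origin`, `step`, `natoms`
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr3 <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  natoms <- as.integer(hdr3[1])
  origin <- hdr3[2:4]
  ax <- lapply(4:6, function(i)
    as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
  d <- vapply(ax, function(a) as.integer(a[1]), 1L)
  step <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4])
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(7 + abs(natoms)):length(lines)]), "\\s+")))
  arr <- array(0, dim = d)
  # file order: x slowest, z fastest
  arr_perm <- array(vals, dim = rev(d))
  arr <- aperm(arr_perm, c(3, 2, 1))
  list(values = arr, origin = origin, step = step, natoms = natoms)
}

#' Export the overlap density of a bond as a cube file
#'
#' Evaluates the clamped pair overlap density on a pair-box grid and writes
#' it as a Gaussian cube.
#'
#' @param wfn a `wavefunction`
#' @param pair a [fragment_pair()]
#' @param path output path
#' @param padding,spacing pair-box parameters (bohr)
#' @return invisibly, `path`
#' @export
cube_rho_op <- function(wfn, pair, path, padding = 4, spacing = 0.25) {
  atoms <- wfn$atoms
  box <- build_pair_region_grid(atoms, c(pair$fragment_a[1],
                                         pair$fragment_b[1]),
                                padding = padding, spacing = spacing)
  v <- overlap_density_at(wfn, pair, box$points, clamp = TRUE)
  arr <- array(v, dim = box$dims)  # expand.grid: x fastest in memory
  export_cube(arr, box$origin + spacing / 2, rep(spacing, 3), atoms, path,
              comment = paste("overlap density", pair$label))
}
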