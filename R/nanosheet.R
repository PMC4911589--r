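# Orthorhombic 2H-MoS2 monolayer builder. The monolayer is a S-Mo-S
# tri-atomic layer: Mo atoms on a hexagonal plane, sulfur planes at z +/- dz
# in trigonal-prismatic coordination (every Mo bonded to 3 S above and 3 S
# below at identical bond length sqrt(a^2/3 + dz^2)).
#
# Cell convention: rectangular cell with vectors (a, 0) and (0, a*sqrt(3))
# holding 2 Mo and 4 S; x is the zigzag direction. Fractional positions:
#   Mo: (0, 0), (1/2, 1/2)       S columns: (1/2, 1/6), (0, 2/3)

#' Lattice specification for a 2H-MoS2 monolayer patch
#'
#' @param a in-plane hexagonal lattice constant (nm). Default 0.316 nm, the
#'   standard 2H-MoS2 value; overridable because published force fields vary
#'   slightly.
#' @param dz vertical offset of each sulfur plane from the Mo plane (nm);
#'   default 0.1564 nm (half the crystallographic S-S separation).
#' @param nx,ny integer repeats of the orthorhombic cell along x and y.
#' @param origin length-3 offset (nm) of the cell origin; the Mo plane sits
#'   at `origin[3]`.
#' @return a validated list of class `"lattice_spec"`.
#' @export
lattice_spec <- function(a = 0.316, dz = 0.1564, nx = 1L, ny = 1L,
                         origin = c(0, 0, 0)) {
  check_positive <- function(value, field) {
    if (length(value) != 1 || !is.finite(value) || value <= 0) {
      stop(sprintf("invalid lattice spec: '%s' must be a positive number", field))
    }
  }
  check_positive(a, "a")
  check_positive(dz, "dz")
  for (f in c("nx", "ny")) {
    v <- get(f)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop(sprintf("invalid lattice spec: '%s' must be an integer >= 1", f))
    }
  }
  stopifnot(length(origin) == 3)
  structure(list(a = a, dz = dz, nx = as.integer(nx), ny = as.integer(ny),
                 origin = as.numeric(origin)),
            class = "lattice_spec")
}

#' Nonbonded parameter set
#'
#' Per-species Lennard-Jones and charge parameters plus the cross-term
#' combination rule. Values are configuration data, never hard-coded: the
#' default set shipped in `inst/extdata/mos2_params.yml` is labelled
#' provisional there.
#'
#' @param species named list: `species -> list(sigma, epsilon, charge)` with
#'   sigma in nm, epsilon in kcal/mol, charge in e.
#' @param combination_rule `"lorentz-berthelot"` (arithmetic sigma,
#'   geometric epsilon; the CHARMM convention) or `"geometric"`.
#' @return list of class `"nonbonded_params"`.
#' @export
nonbonded_params <- function(species,
                             combination_rule = c("lorentz-berthelot",
                                                  "geometric")) {
  combination_rule <- match.arg(combination_rule)
  for (sp in names(species)) {
    p <- species[[sp]]
    if (is.null(p$sigma) || p$sigma <= 0) {
      stop(sprintf("species '%s': sigma must be > 0", sp))
    }
    if (is.null(p$epsilon) || p$epsilon < 0) {
      stop(sprintf("species '%s': epsilon must be >= 0", sp))
    }
    if (is.null(p$charge)) stop(sprintf("species '%s': charge missing", sp))
  }
  structure(list(species = species, combination_rule = combination_rule),
            class = "nonbonded_params")
}

#' Read nonbonded parameters from a YAML config
#'
#' Schema: `species: {Mo: {sigma: .., epsilon: .., charge: ..}, ...}` and
#' `combination_rule:`. See `inst/extdata/mos2_params.yml` for the shipped
#' default and its provenance notes.
#'
#' @param path YAML file; default the packaged config.
#' @return a [nonbonded_params()] object.
#' @export
read_nonbonded_params <- function(path = default_params_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) stop("params config must have a 'species' map")
  nonbonded_params(cfg$species,
                   combination_rule = cfg$combination_rule %||%
                     "lorentz-berthelot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path of the packaged default nonbonded parameter config
#' @export
default_params_path <- function() {
  system.file("extdata", "mos2_params.yml", package = "nanoadsorb",
              mustWork = TRUE)
}

#' Build an orthorhombic 2H-MoS2 monolayer patch
#'
#' Either give explicit repeats (`nx`, `ny` inside `spec`) or target extents
#' via [monolayer_for_extents()]. Atom order is cell-major: within each cell
#' Mo, Mo, S_top, S_bottom, S_top, S_bottom.
#'
#' @param spec a [lattice_spec()].
#' @param params a [nonbonded_params()] carrying Mo and S entries.
#' @return object of class `"sheet_model"`: `atoms` data.frame (species,
#'   x, y, z, layer), `extents` c(Lx, Ly), `a`, `dz`, `params`, and a
#'   `frozen` flag (the sheet is held rigid in the simulations this mirrors;
#'   the flag is metadata propagated to index-group output, not dynamics).
#' @export
build_monolayer <- function(spec, params = read_nonbonded_params()) {
  stopifnot(inherits(spec, "lattice_spec"))
  needed <- c("Mo", "S")
  missing_sp <- setdiff(needed, names(params$species))
  if (length(missing_sp) > 0) {
    stop(sprintf("params missing species: %s", paste(missing_sp, collapse = ", ")))
  }
  a <- spec$a; dz <- spec$dz
  ly1 <- a * sqrt(3)
  cells <- expand.grid(ix = seq_len(spec$nx) - 1L, iy = seq_len(spec$ny) - 1L)
  cells <- cells[order(cells$iy, cells$ix), , drop = FALSE]
  one_cell <- data.frame(
    species = c("Mo", "Mo", "S", "S", "S", "S"),
    fx = c(0, 0.5, 0.5, 0.5, 0, 0),
    fy = c(0, 0.5, 1 / 6, 1 / 6, 2 / 3, 2 / 3),
    z  = c(0, 0, dz, -dz, dz, -dz),
    layer = c("Mo", "Mo", "S_top", "S_bottom", "S_top", "S_bottom"),
    stringsAsFactors = FALSE
  )
  atoms <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      species = one_cell$species,
      x = (cells$ix[i] + one_cell$fx) * a + spec$origin[1],
      y = (cells$iy[i] + one_cell$fy) * ly1 + spec$origin[2],
      z = one_cell$z + spec$origin[3],
      layer = one_cell$layer,
      stringsAsFactors = FALSE
    )
  }))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 extents = c(spec$nx * a, spec$ny * ly1),
                 a = a, dz = dz, nx = spec$nx, ny = spec$ny,
                 params = params, frozen = TRUE),
            class = "sheet_model")
}

#' Build a monolayer matching target extents
#'
#' Picks the integer repeats minimising `|extent - target|` per axis (the
#' requested size is rarely an integer multiple of the lattice constant) and
#' reports the achieved extents via a message.
#'
#' @param target_lx,target_ly requested extents (nm).
#' @param a,dz,origin as in [lattice_spec()].
#' @param params a [nonbonded_params()].
#' @return a `"sheet_model"`; achieved extents are within half a lattice
#'   spacing of the target per axis.
#' @export
monolayer_for_extents <- function(target_lx, target_ly, a = 0.316,
                                  dz = 0.1564, origin = c(0, 0, 0),
                                  params = read_nonbonded_params()) {
  if (target_lx <= 0 || target_ly <= 0) stop("target extents must be positive")
  nx <- max(1L, as.integer(round(target_lx / a)))
  ny <- max(1L, as.integer(round(target_ly / (a * sqrt(3)))))
  sheet <- build_monolayer(lattice_spec(a, dz, nx, ny, origin), params)
  message(sprintf("target extents (%.3f, %.3f) nm -> %d x %d cells, achieved (%.3f, %.3f) nm",
                  target_lx, target_ly, nx, ny,
                  sheet$extents[1], sheet$extents[2]))
  sheet
}

#' Sheet extents
#'
#' Returns the periodic extents (Lx, Ly) in nm: the max-min coordinate span
#' per axis plus one lattice spacing (a/2 along x, a*sqrt(3)/3 along y, the
#' grid spacings of the atom columns), which recovers exactly (nx*a,
#' ny*a*sqrt(3)) and is invariant under translation of the sheet.
#'
#' @param sheet a `"sheet_model"`.
#' @return numeric c(Lx, Ly).
#' @export
sheet_extents <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_model"))
  if (nrow(sheet$atoms) == 0) stop("empty sheet")
  span <- c(max(sheet$atoms$x) - min(sheet$atoms$x),
            max(sheet$atoms$y) - min(sheet$atoms$y))
  unname(span + c(sheet$a / 2, sheet$a * sqrt(3) / 3))
}

#' Sheet coordinates as a matrix
#' @param sheet a `"sheet_model"`.
#' @return N x 3 matrix (nm).
#' @export
sheet_xyz <- function(sheet) {
  as.matrix(sheet$atoms[, c("x", "y", "z")])
}

#' Convert a sheet to the package topology/frame model
#'
#' Sheet atoms get residue name `"MOS"`, one residue per sheet, and their
#' `lj_type`/charge from the sheet's nonbonded parameters.
#'
#' @param sheet a `"sheet_model"`.
#' @param resid residue id assigned to the sheet.
#' @return list(topology, frame).
#' @export
sheet_as_structure <- function(sheet, resid = 1L) {
  sp <- sheet$atoms$species
  charges <- vapply(sp, function(s) sheet$params$species[[s]]$charge,
                    numeric(1))
  top <- topology(name = toupper(sp), resid = resid, resname = SHEET_RESNAME,
                  chain = "X", element = sp, charge = charges, lj_type = sp)
  list(topology = top, frame = make_frame(sheet_xyz(sheet)))
}

#' Write a sheet to PDB or GRO
#'
#' Round-trips species (via element column / atom names), positions to
#' format precision, and atom order. An optional GROMACS-style index file
#' lists the frozen sheet atoms as group `[ frozen_MOS ]`.
#'
#' @param sheet a `"sheet_model"`.
#' @param path output path.
#' @param format `"pdb"`, `"gro"`, or `NULL` to infer from extension.
#' @param index_path optional path for the frozen-atom index group file.
#' @return `path`, invisibly.
#' @export
write_sheet <- function(sheet, path, format = NULL, index_path = NULL) {
  st <- sheet_as_structure(sheet)
  write_structure(st$topology, st$frame, path, format = format,
                  title = sprintf("2H-MoS2 monolayer %dx%d cells, extents %.3f x %.3f nm (span + one lattice spacing)",
                                  sheet$nx, sheet$ny,
                                  sheet_extents(sheet)[1], sheet_extents(sheet)[2]))
  if (!is.null(index_path)) {
    idx <- seq_len(nrow(sheet$atoms))
    rows <- split(idx, ceiling(seq_along(idx) / 15))
    writeLines(c("[ frozen_MOS ]",
                 vapply(rows, function(r) paste(sprintf("%5d", r),
                                                collapse = " "),
                        character(1))), index_path)
  }
  invisible(path)
}

#' Nearest-neighbour Mo-S bond lengths
#'
#' Utility for geometry checks: distances from each Mo to its 6 nearest S
#' atoms (3 in the top plane, 3 in the bottom). In-plane periodicity is
#' applied by default so edge Mo atoms see their wrapped neighbours; all 6
#' bonds then equal sqrt(a^2/3 + dz^2).
#'
#' @param sheet a `"sheet_model"`.
#' @param periodic wrap in x and y with the sheet extents.
#' @return numeric matrix, one row per Mo, 6 sorted bond lengths (nm).
#' @export
mo_s_bonds <- function(sheet, periodic = TRUE) {
  xyz <- sheet_xyz(sheet)
  mo <- xyz[sheet$atoms$species == "Mo", , drop = FALSE]
  s <- xyz[sheet$atoms$species == "S", , drop = FALSE]
  box <- if (periodic) c(sheet_extents(sheet), Inf) else NULL
  d <- pair_distances(mo, s, box = box)
  t(apply(d, 1, function(r) sort(r)[1:6]))
}
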