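# Protein-on-sheet system assembly: rigid placement at a prescribed gap,
# formal-charge neutralisation, and box sizing. Water insertion is left to
# the MD engine's solvation tool; this module computes counts and geometry.

#' HP35 villin headpiece subdomain sequence (residues 42-76)
#'
#' One-letter sequence of the 35-residue three-helix bundle used throughout
#' the examples, numbered 42-76 as in its crystal structure.
#' @export
hp35_sequence <- function() "LSDEDFKAVFGMTRSAFANLPLWKQQNLKKEKGLF"

#' First residue id of the HP35 numbering
#' @export
hp35_start_resid <- function() 42L

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Sidechain formal charges at pH 7: Asp/Glu -1, Lys/Arg +1, His 0.
SIDECHAIN_CHARGE <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L)

#' Normalise a residue sequence to three-letter codes
#'
#' Accepts a one-letter string, a vector of one-letter codes, or a vector of
#' three-letter codes (case-insensitive); unknown codes raise an error
#' naming the code.
#'
#' @param sequence residue sequence in any of the accepted forms.
#' @return character vector of three-letter codes.
#' @export
as_residue_codes <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 3 &&
      !grepl("[ ,]", sequence)) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  out <- character(length(sequence))
  for (i in seq_along(sequence)) {
    s <- sequence[i]
    if (nchar(s) == 1) {
      if (!s %in% names(AA1TO3)) {
        stop(sprintf("unknown residue code '%s'", s))
      }
      out[i] <- AA1TO3[[s]]
    } else if (s %in% AMINO3) {
      out[i] <- s
    } else {
      stop(sprintf("unknown residue code '%s'", s))
    }
  }
  out
}

#' Formal charge of a protein sequence
#'
#' Standard protonation at pH 7: Asp/Glu -1, Lys/Arg +1, His neutral, plus
#' the terminal contribution (zwitterionic termini: +1 at the N terminus and
#' -1 at the C terminus, net 0; `"neutral"` termini contribute nothing).
#' The HP35 sequence gives +2, hence the two chloride counterions needed to
#' neutralise the solvated system.
#'
#' @param sequence residue sequence (see [as_residue_codes()]).
#' @param termini `"zwitterionic"` or `"neutral"`.
#' @return integer net formal charge (e).
#' @export
formal_charge <- function(sequence, termini = c("zwitterionic", "neutral")) {
  termini <- match.arg(termini)
  codes <- as_residue_codes(sequence)
  side <- sum(SIDECHAIN_CHARGE[codes], na.rm = TRUE)
  term <- if (termini == "zwitterionic") 1L - 1L else 0L
  as.integer(side + term)
}

#' Counterions needed to neutralise a sequence
#'
#' @param sequence residue sequence.
#' @param termini as in [formal_charge()].
#' @return list(species, count): chloride for a positive protein, sodium for
#'   a negative one.
#' @export
counterions <- function(sequence, termini = "zwitterionic") {
  q <- formal_charge(sequence, termini)
  if (q > 0) list(species = "CL", count = q)
  else if (q < 0) list(species = "NA", count = -q)
  else list(species = NA_character_, count = 0L)
}

#' Place a protein above a sheet at a prescribed gap
#'
#' Rigid-body move only: the protein is translated so its xy centroid sits
#' over the sheet's xy centre and then shifted along +z until the minimum
#' distance between any protein heavy atom and any sheet atom (S or Mo; the
#' realized-gap definition is recorded in the result) equals `gap`. All
#' intra-protein distances are preserved exactly (pure translation).
#'
#' @param protein list(topology, frame) for the protein.
#' @param sheet a `"sheet_model"`.
#' @param gap target minimum heavy-atom distance (nm); the headline
#'   adsorption setup uses 0.8 nm.
#' @param center_xy align the protein xy centroid to the sheet centre
#'   (default TRUE; FALSE keeps the lateral position, useful for idempotence
#'   on already-placed systems).
#' @param warn_overhang warn when the protein footprint exceeds the sheet.
#' @return list of class `"nano_system"`: `protein` (with moved frame),
#'   `sheet`, `gap`, `realized_gap`, `gap_definition`.
#' @export
place_protein <- function(protein, sheet, gap = 0.8, center_xy = TRUE,
                          warn_overhang = TRUE) {
  if (gap <= 0) stop("gap must be > 0")
  stopifnot(inherits(sheet, "sheet_model"))
  top <- protein$topology
  xyz <- protein$frame$xyz
  if (nrow(top) == 0 || nrow(sheet$atoms) == 0) {
    stop("protein and sheet must be non-empty")
  }
  sxyz <- sheet_xyz(sheet)
  shift <- c(0, 0, 0)
  if (center_xy) {
    sheet_center <- c(mean(range(sxyz[, 1])), mean(range(sxyz[, 2])))
    prot_center <- colMeans(xyz[, 1:2, drop = FALSE])
    shift[1:2] <- sheet_center - prot_center
  }
  xyz <- sweep(xyz, 2L, shift, "+")
  heavy <- which(top$heavy)
  if (length(heavy) == 0) stop("protein has no heavy atoms")
  # Exact vertical solve: for each (protein heavy, sheet) pair with lateral
  # separation dxy, shifting the protein up by s puts the pair at distance
  # sqrt(dxy^2 + (dz + s)^2). Taking s as the maximum over pairs of
  # sqrt(max(gap^2 - dxy^2, 0)) - dz leaves every pair at distance >= gap,
  # with the binding pair at exactly gap (whenever some pair has dxy <= gap,
  # i.e. the protein lies laterally over the sheet).
  dxy2 <- outer(xyz[heavy, 1], sxyz[, 1], "-")^2 +
    outer(xyz[heavy, 2], sxyz[, 2], "-")^2
  dz <- outer(xyz[heavy, 3], sxyz[, 3], "-")
  s <- max(sqrt(pmax(gap^2 - dxy2, 0)) - dz)
  xyz[, 3] <- xyz[, 3] + s
  realized <- sqrt(min(dxy2 + (dz + s)^2))
  if (warn_overhang &&
      (diff(range(xyz[, 1])) > sheet$extents[1] ||
       diff(range(xyz[, 2])) > sheet$extents[2])) {
    warning("protein is wider than the sheet in xy")
  }
  structure(list(protein = list(topology = top, frame = make_frame(xyz)),
                 sheet = sheet, gap = gap, realized_gap = realized,
                 gap_definition = "min distance, protein heavy atom to any sheet atom"),
            class = "nano_system")
}

#' Suggest a rectangular box for a placed system
#'
#' x and y come from the sheet extents plus `pad_xy` per side; z is the
#' overall atom z-span plus `margin_z`. The returned box is checked to
#' enclose every atom after shifting the origin to the system minimum.
#'
#' @param system a `"nano_system"` from [place_protein()].
#' @param margin_z extra z headroom (nm), split above the system.
#' @param pad_xy lateral padding per side (nm).
#' @return list(box = c(x, y, z) nm, origin = coordinate shift applied to
#'   bring all atoms into [0, box]).
#' @export
suggest_box <- function(system, margin_z = 1.0, pad_xy = 0.1) {
  if (margin_z < 0) stop("margin_z must be >= 0")
  if (pad_xy < 0) stop("pad_xy must be >= 0")
  all_xyz <- rbind(system$protein$frame$xyz, sheet_xyz(system$sheet))
  span_z <- max(all_xyz[, 3]) - min(all_xyz[, 3])
  ext <- sheet_extents(system$sheet)
  box <- c(ext[1] + 2 * pad_xy, ext[2] + 2 * pad_xy, span_z + margin_z)
  origin <- c(min(all_xyz[, 1]) - pad_xy, min(all_xyz[, 2]) - pad_xy,
              min(all_xyz[, 3]))
  list(box = box, origin = origin)
}

#' Assemble a setup report
#'
#' The quantities an engine-level solvation step needs: realized gap, formal
#' charge, counterion count, suggested box.
#'
#' @param system a `"nano_system"`.
#' @param sequence protein sequence for the charge calculation; defaults to
#'   the residue names in the system topology.
#' @param margin_z,pad_xy forwarded to [suggest_box()].
#' @return named list, suitable for `jsonlite::write_json()`.
#' @export
setup_report <- function(system, sequence = NULL, margin_z = 1.0,
                         pad_xy = 0.1) {
  if (is.null(sequence)) {
    top <- system$protein$topology
    sequence <- vapply(split(top$resname, top$resid), `[`, character(1), 1)
  }
  q <- formal_charge(sequence)
  ions <- counterions(sequence)
  box <- suggest_box(system, margin_z, pad_xy)
  list(realized_gap_nm = system$realized_gap,
       gap_definition = system$gap_definition,
       formal_charge_e = q,
       counterion_species = ions$species,
       counterion_count = ions$count,
       box_nm = box$box)
}
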