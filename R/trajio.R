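# Atom metadata model, structure/trajectory I/O, and the selection grammar
# shared by all analysis modules. Internal length unit is nm everywhere; PDB
# Angstroms are converted on read/write.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

DEFAULT_WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3")
SHEET_RESNAME <- "MOS"

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                    "HA", "HA1", "HA2", "HN")

TWO_LETTER_ELEMENTS <- c("MO", "CL", "NA", "MG", "FE", "ZN", "BR", "MN")

#' Build an atom-metadata table (topology)
#'
#' The per-atom table every analysis function consumes. Derived flags are
#' computed here and nowhere else:
#' \itemize{
#'   \item \code{heavy}: element is not hydrogen (contact and hydration
#'     criteria use heavy atoms only);
#'   \item \code{water}: residue name in \code{water_resnames};
#'   \item \code{sheet}: residue name \code{"MOS"} (nanosheet atoms);
#'   \item \code{protein}: neither water nor sheet;
#'   \item \code{backbone}/\code{sidechain}: protein atoms split by PDB atom
#'     name; the two flags are mutually exclusive by construction.
#' }
#'
#' @param name atom names (PDB convention, e.g. "CA", "OW", "MO").
#' @param resid integer residue ids (kept verbatim from input files; never
#'   renumbered, so literature residue labels match directly).
#' @param resname three-letter residue names.
#' @param chain chain identifiers (recycled).
#' @param element chemical elements; inferred from `name` when `NA` (see
#'   [infer_element()]).
#' @param charge partial charges (e).
#' @param lj_type Lennard-Jones type labels used to look up nonbonded
#'   parameters; defaults to the element.
#' @param water_resnames residue names identifying water.
#' @return a `data.frame` of class `"nanotop"`.
#' @export
topology <- function(name, resid, resname, chain = "A", element = NA,
                     charge = 0, lj_type = NA,
                     water_resnames = DEFAULT_WATER_RESNAMES) {
  n <- length(name)
  resid <- rep_len(resid, n)
  resname <- rep_len(resname, n)
  element <- rep_len(as.character(element), n)
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- infer_element(name[missing_el])
  lj_type <- rep_len(as.character(lj_type), n)
  lj_type[is.na(lj_type)] <- element[is.na(lj_type)]
  top <- data.frame(
    name = as.character(name),
    element = element,
    resid = as.integer(resid),
    resname = as.character(resname),
    chain = rep_len(as.character(chain), n),
    charge = rep_len(as.numeric(charge), n),
    lj_type = lj_type,
    stringsAsFactors = FALSE
  )
  top$heavy <- toupper(top$element) != "H"
  top$water <- top$resname %in% water_resnames
  top$sheet <- top$resname == SHEET_RESNAME
  top$protein <- !top$water & !top$sheet
  top$backbone <- top$protein & top$name %in% BACKBONE_NAMES
  top$sidechain <- top$protein & !top$backbone
  class(top) <- c("nanotop", "data.frame")
  top
}

#' Infer chemical elements from atom names
#'
#' Documented rule: digits are stripped; if the remaining letters match a
#' known two-letter element (Mo, Cl, Na, Mg, Fe, Zn, Br, Mn) that element is
#' used, otherwise the first letter. Protein "CA" therefore maps to carbon
#' (calcium never appears in these systems).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name) {
  letters_only <- toupper(gsub("[^A-Za-z]", "", name))
  out <- substr(letters_only, 1L, 1L)
  two <- letters_only %in% TWO_LETTER_ELEMENTS
  out[two] <- paste0(substr(letters_only[two], 1L, 1L),
                     tolower(substr(letters_only[two], 2L, 2L)))
  out
}

#' Construct a single coordinate frame
#'
#' @param xyz N x 3 coordinate matrix (nm).
#' @param time_ps frame time in ps.
#' @param box optional length-3 orthorhombic box (nm); when absent,
#'   coordinates are treated as unwrapped and no minimum-image convention is
#'   applied.
#' @return object of class `"nanoframe"`.
#' @export
make_frame <- function(xyz, time_ps = 0, box = NULL) {
  xyz <- coord_matrix(xyz)
  if (!all(is.finite(xyz))) stop("frame coordinates must be finite")
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
    box <- as.numeric(box)
  }
  structure(list(xyz = xyz, time_ps = as.numeric(time_ps), box = box),
            class = "nanoframe")
}

#' In-memory trajectory
#'
#' @param topology a [topology()] table.
#' @param frames list of N x 3 coordinate matrices (nm), time order.
#' @param times_ps frame times (ps), strictly increasing.
#' @param box optional shared box (nm).
#' @return object of class `"nanotraj"`.
#' @export
trajectory <- function(topology, frames, times_ps, box = NULL) {
  stopifnot(length(frames) == length(times_ps))
  if (length(times_ps) > 1 && any(diff(times_ps) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  natom <- nrow(topology)
  for (f in frames) {
    if (nrow(f) != natom) {
      stop(sprintf("frame has %d atoms but topology has %d", nrow(f), natom))
    }
  }
  structure(list(topology = topology, frames = frames,
                 times_ps = as.numeric(times_ps), box = box),
            class = "nanotraj")
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return a `"nanoframe"`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  make_frame(traj$frames[[i]], time_ps = traj$times_ps[i], box = traj$box)
}

#' Frame times in ns
#' @param traj a [trajectory()].
#' @export
traj_times_ns <- function(traj) traj$times_ps / 1000

# ---------------------------------------------------------------------------
# Structure I/O

#' Read a structure file (PDB or GRO)
#'
#' PDB files are parsed with bio3d; GRO files with the package's own
#' fixed-width reader. Residue numbering is preserved verbatim (a villin
#' headpiece file numbered 42-76 keeps those ids). Elements come from the
#' file's element column when present, otherwise from [infer_element()].
#'
#' @param path file path; format from extension unless `format` given.
#' @param format `"pdb"`, `"gro"`, or `NULL` to infer.
#' @return list with components `topology` and `frame`.
#' @export
read_structure <- function(path, format = NULL) {
  format <- resolve_format(path, format, ok = c("pdb", "gro"))
  if (format == "pdb") read_pdb_structure(path) else read_gro_structure(path)
}

resolve_format <- function(path, format, ok) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% ok) {
    stop(sprintf("unsupported format '%s'; supported: %s",
                 format, paste(ok, collapse = ", ")))
  }
  format
}

read_pdb_structure <- function(path, multi = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el)) el <- NA
  el <- ifelse(is.na(el) | trimws(el) == "", NA, trimws(el))
  top <- topology(name = trimws(at$elety), resid = at$resno,
                  resname = trimws(at$resid),
                  chain = ifelse(is.na(at$chain), "A", at$chain),
                  element = el)
  xyz_all <- pdb$xyz / 10  # Angstrom -> nm
  if (multi && nrow(xyz_all) > 1) {
    frames <- lapply(seq_len(nrow(xyz_all)), function(i) {
      matrix(xyz_all[i, ], ncol = 3, byrow = TRUE)
    })
    return(list(topology = top, frames = frames))
  }
  xyz <- matrix(xyz_all[1, ], ncol = 3, byrow = TRUE)
  list(topology = top, frame = make_frame(xyz))
}

read_gro_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short at line 2")
  natom <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natom)) stop("unparseable atom count at line 2")
  if (length(lines) < 2 + natom + 1) {
    stop(sprintf("GRO file truncated: expected %d atom lines", natom))
  }
  rec <- lines[3:(2 + natom)]
  parse_field <- function(x, from, to) substr(x, from, to)
  resid <- suppressWarnings(as.integer(parse_field(rec, 1, 5)))
  resname <- trimws(parse_field(rec, 6, 10))
  name <- trimws(parse_field(rec, 11, 15))
  x <- suppressWarnings(as.numeric(parse_field(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(parse_field(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(parse_field(rec, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop(sprintf("unparseable GRO record at line %d", 2 + bad[1]))
  }
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + natom]),
                                                  "\\s+")[[1]]))
  box <- if (length(boxline) >= 3 && all(is.finite(boxline[1:3])) &&
             all(boxline[1:3] > 0)) boxline[1:3] else NULL
  top <- topology(name = name, resid = resid, resname = resname)
  list(topology = top, frame = make_frame(cbind(x, y, z), box = box))
}

#' Write a structure file (PDB or GRO)
#'
#' PDB output uses fixed-width ATOM records with the element column filled;
#' GRO output is nm with 3 decimals (the format's precision). Both re-read
#' losslessly apart from coordinate rounding (1e-4 nm for PDB, 1e-3 nm for
#' GRO).
#'
#' @param topology a [topology()] table.
#' @param frame a [make_frame()] frame.
#' @param path output path.
#' @param format `"pdb"`, `"gro"`, or `NULL` to infer from extension.
#' @param title header/title line.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frame, path, format = NULL,
                            title = "generated by nanoadsorb") {
  format <- resolve_format(path, format, ok = c("pdb", "gro"))
  if (format == "pdb") {
    writeLines(c(sprintf("TITLE     %s", title),
                 pdb_atom_lines(topology, frame$xyz), "END"), path)
  } else {
    writeLines(gro_lines(topology, frame, title), path)
  }
  invisible(path)
}

pdb_atom_lines <- function(top, xyz_nm, serial_offset = 0L) {
  xyz <- coord_matrix(xyz_nm) * 10  # nm -> Angstrom
  n <- nrow(top)
  name4 <- vapply(top$name, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else sprintf(" %-3s", nm)  # short names start in column 14
  }, character(1))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (seq_len(n) + serial_offset - 1L) %% 99999L + 1L, name4,
          substr(top$resname, 1, 3), substr(top$chain, 1, 1), top$resid,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(top$element))
}

gro_lines <- function(top, frame, title) {
  n <- nrow(top)
  box <- if (is.null(frame$box)) {
    apply(frame$xyz, 2, function(v) max(v) - min(v)) + 0.1
  } else frame$box
  c(title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            top$resid %% 100000L, substr(top$resname, 1, 5),
            substr(top$name, 1, 5), seq_len(n) %% 100000L,
            frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

# ---------------------------------------------------------------------------
# Trajectory I/O

#' Read a trajectory (multi-model PDB or DCD)
#'
#' Formats readable in this stack are multi-model PDB (text) and DCD
#' (binary, via bio3d); XTC/TRR are not supported and raise an error naming
#' the supported formats. Frame times are taken from the multi-model PDB
#' `TITLE`/`REMARK t=` fields when present, otherwise assigned on a uniform
#' grid of `dt_ps`.
#'
#' @param topology the matching [topology()]; atom counts are checked.
#' @param path trajectory file.
#' @param stride keep every `stride`-th frame (>= 1).
#' @param dt_ps frame spacing used when the file stores no times (default
#'   20 ps, the usual output interval of the production runs this package
#'   analyses).
#' @param format `"pdb"`, `"dcd"`, or `NULL` to infer.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(topology, path, stride = 1L, dt_ps = 20,
                            format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format %in% c("xtc", "trr")) {
    stop(sprintf("unsupported trajectory format '%s'; supported: pdb (multi-model), dcd",
                 format))
  }
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (format == "pdb") {
    parsed <- read_multimodel_pdb(path)
    frames <- parsed$frames
    times <- parsed$times_ps
    if (nrow(parsed$topology) != nrow(topology)) {
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   nrow(parsed$topology), nrow(topology)))
    }
  } else if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10
    if (ncol(xyz) != 3 * nrow(topology)) {
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   ncol(xyz) / 3, nrow(topology)))
    }
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    })
    times <- NULL
  } else {
    stop(sprintf("unsupported trajectory format '%s'; supported: pdb (multi-model), dcd",
                 format))
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * dt_ps
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("trajectory frame times are not strictly increasing")
  }
  keep <- seq(1L, length(frames), by = stride)
  trajectory(topology, frames[keep], times[keep])
}

# Minimal multi-model PDB reader: MODEL/ENDMDL blocks of ATOM records.
# Times are read from "REMARK t= <ps>" lines inside each model when present.
read_multimodel_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 1L
  model_of <- findInterval(seq_along(lines), model_starts)
  atom_lines <- lines[is_atom]
  atom_model <- model_of[is_atom]
  nmodel <- length(model_starts)
  first <- atom_lines[atom_model == atom_model[1]]
  top <- topology(
    name = trimws(substr(first, 13, 16)),
    resid = as.integer(substr(first, 23, 26)),
    resname = trimws(substr(first, 18, 20)),
    chain = ifelse(trimws(substr(first, 22, 22)) == "", "A",
                   substr(first, 22, 22)),
    element = ifelse(trimws(substr(first, 77, 78)) == "", NA,
                     trimws(substr(first, 77, 78)))
  )
  frames <- lapply(unique(atom_model), function(m) {
    rec <- atom_lines[atom_model == m]
    if (length(rec) != nrow(top)) {
      stop(sprintf("model %d has %d atoms, expected %d", m, length(rec),
                   nrow(top)))
    }
    cbind(as.numeric(substr(rec, 31, 38)),
          as.numeric(substr(rec, 39, 46)),
          as.numeric(substr(rec, 47, 54))) / 10
  })
  tlines <- grep("^REMARK +t= *[-0-9.eE+]+", lines, value = TRUE)
  times <- if (length(tlines) == length(frames)) {
    as.numeric(sub("^REMARK +t= *([-0-9.eE+]+).*$", "\\1", tlines))
  } else NULL
  list(topology = top, frames = frames, times_ps = times)
}

#' Write a trajectory as a multi-model PDB
#'
#' Each frame becomes one MODEL block, preceded by a `REMARK t=` line with
#' the frame time in ps so that times round-trip through [read_trajectory()].
#'
#' @param traj a [trajectory()].
#' @param path output path (.pdb).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("TITLE     nanoadsorb trajectory", con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("MODEL     %4d", i),
                 sprintf("REMARK t= %.6f", traj$times_ps[i]),
                 pdb_atom_lines(traj$topology, traj$frames[[i]]),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selection grammar

#' Select atoms with a small boolean grammar
#'
#' Grammar: keywords `protein`, `water`, `sheet`, `heavy`, `sidechain`,
#' `backbone`; `resid A-B` (inclusive) or `resid A`; `resname X`; combined
#' with `and`, `or`, `not` and parentheses (`and` binds tighter than `or`).
#' `protein and sidechain and heavy` is the contact atom set used throughout
#' the adsorption analyses.
#'
#' @param topology a [topology()] table.
#' @param expression selection string.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(topology, expression) {
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, topology)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("selection syntax error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$text[st$pos]))
  }
  which(mask)
}

tokenize_selection <- function(expression) {
  pattern <- "\\(|\\)|[A-Za-z0-9_]+(-[0-9]+)?"
  m <- gregexpr(pattern, expression)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  text <- regmatches(expression, gregexpr(pattern, expression))[[1]]
  leftover <- gsub(pattern, " ", expression)
  if (grepl("[^ \t]", leftover)) {
    bad <- regexpr("[^ \t]", leftover)
    stop(sprintf("selection syntax error at position %d: unexpected '%s'",
                 bad, substr(expression, bad, bad)))
  }
  data.frame(text = text, at = as.integer(m), stringsAsFactors = FALSE)
}

peek_tok <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA
next_tok <- function(st) {
  t <- peek_tok(st)
  st$pos <- st$pos + 1L
  t
}

parse_or <- function(st, top) {
  lhs <- parse_and(st, top)
  while (!is.na(peek_tok(st)) && tolower(peek_tok(st)) == "or") {
    next_tok(st)
    lhs <- lhs | parse_and(st, top)
  }
  lhs
}

parse_and <- function(st, top) {
  lhs <- parse_unary(st, top)
  while (!is.na(peek_tok(st)) && tolower(peek_tok(st)) == "and") {
    next_tok(st)
    lhs <- lhs & parse_unary(st, top)
  }
  lhs
}

parse_unary <- function(st, top) {
  t <- peek_tok(st)
  if (is.na(t)) stop("selection syntax error: unexpected end of expression")
  if (tolower(t) == "not") {
    next_tok(st)
    return(!parse_unary(st, top))
  }
  if (t == "(") {
    next_tok(st)
    inner <- parse_or(st, top)
    if (is.na(peek_tok(st)) || peek_tok(st) != ")") {
      stop(sprintf("selection syntax error at position %d: expected ')'",
                   if (st$pos <= nrow(st$toks)) st$toks$at[st$pos]
                   else nchar(paste(st$toks$text, collapse = " "))))
    }
    next_tok(st)
    return(inner)
  }
  parse_primary(st, top)
}

parse_primary <- function(st, top) {
  t <- next_tok(st)
  kw <- tolower(t)
  flags <- c(protein = "protein", water = "water", sheet = "sheet",
             heavy = "heavy", sidechain = "sidechain", backbone = "backbone")
  if (kw %in% names(flags)) return(top[[flags[[kw]]]])
  if (kw == "resid") {
    arg <- next_tok(st)
    if (is.na(arg) || !grepl("^[0-9]+(-[0-9]+)?$", arg)) {
      stop(sprintf("selection syntax error at position %d: resid needs A or A-B",
                   st$toks$at[st$pos - 1L]))
    }
    parts <- as.integer(strsplit(arg, "-")[[1]])
    lo <- parts[1]
    hi <- if (length(parts) == 2) parts[2] else parts[1]
    return(top$resid >= lo & top$resid <= hi)
  }
  if (kw == "resname") {
    arg <- next_tok(st)
    if (is.na(arg)) stop("selection syntax error: resname needs an argument")
    return(toupper(top$resname) == toupper(arg))
  }
  stop(sprintf("selection syntax error at position %d: unknown token '%s'",
               st$toks$at[st$pos - 1L], t))
}
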