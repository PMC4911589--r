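# Structural observables of the adsorption/denaturation analyses: heavy-atom
# contact counts, native-contact fraction Q(t), dihedral-based helix ratio,
# hydrogen-bond counts, salt-bridge and cation-pi detectors, and the
# hydrophobic-fraction bookkeeping.

#' Default helix spans of the three-helix bundle
#'
#' Helix 1: residues 43-52, helix 2: 54-61, helix 3: 62-74 (HP35 numbering).
#' Spans are configurable everywhere they are consumed.
#'
#' @param helix1,helix2,helix3 integer ranges (inclusive).
#' @return named list of class `"helix_spans"`.
#' @export
helix_spans <- function(helix1 = 43:52, helix2 = 54:61, helix3 = 62:74) {
  spans <- list(helix1 = helix1, helix2 = helix2, helix3 = helix3)
  all_res <- unlist(spans)
  if (anyDuplicated(all_res)) stop("helix spans must be disjoint")
  structure(spans, class = "helix_spans")
}

#' Heavy-atom contact count between two atom sets
#'
#' The adsorption contact number: an atom of `set_a` is "in contact" when at
#' least one atom of `set_b` lies within `rc` (default 0.6 nm, the
#' sidechain-heavy-atom-to-sheet criterion). By default the count is the
#' number of contacting `set_a` atoms; `pairs = TRUE` counts contacting
#' pairs instead (both readings of a "contact number" are in circulation, so
#' outputs label the convention).
#'
#' @param frame a [make_frame()] frame.
#' @param set_a,set_b disjoint integer atom index sets.
#' @param rc contact cutoff (nm).
#' @param pairs count pairs instead of `set_a` atoms.
#' @return integer count.
#' @export
heavy_atom_contacts <- function(frame, set_a, set_b, rc = 0.6,
                                pairs = FALSE) {
  if (rc <= 0) stop("rc must be > 0")
  if (length(intersect(set_a, set_b)) > 0) {
    stop("atom sets must be disjoint")
  }
  if (length(set_a) == 0 || length(set_b) == 0) return(0L)
  d <- pair_distances(frame$xyz[set_a, , drop = FALSE],
                      frame$xyz[set_b, , drop = FALSE], box = frame$box)
  if (pairs) sum(d <= rc) else sum(apply(d <= rc, 1, any))
}

#' Native-contact set of a reference structure
#'
#' Residue pairs (i, j) with sequence separation `j - i >= min_sep`
#' (default 3: only pairs at least 3 residues apart count) whose minimum
#' heavy-atom distance in the reference frame is at most `rc` (default
#' 0.6 nm, the same cutoff as the sheet-contact criterion). All heavy atoms
#' (backbone + sidechain) define the pair distance by default; restrict
#' with `part = "sidechain"`.
#'
#' @param ref list(topology, frame): the reference (crystal-like) structure.
#' @param rc distance cutoff (nm).
#' @param min_sep minimum residue separation.
#' @param part `"heavy"` (all heavy atoms) or `"sidechain"`.
#' @return data.frame of class `"native_contacts"` with columns `i`, `j`
#'   (ordered, unique) and attributes `rc`, `min_sep`, `part`.
#' @export
native_contacts <- function(ref, rc = 0.6, min_sep = 3L,
                            part = c("heavy", "sidechain")) {
  part <- match.arg(part)
  top <- ref$topology
  keep <- top$protein & top$heavy
  if (part == "sidechain") keep <- keep & top$sidechain
  if (!any(keep)) stop("reference has no protein heavy atoms")
  resids <- sort(unique(top$resid[keep]))
  if (length(resids) < 2) stop("reference protein has fewer than 2 residues")
  idx_by_res <- lapply(resids, function(r) which(keep & top$resid == r))
  pairs <- list()
  for (ii in seq_along(resids)) {
    for (jj in seq_along(resids)) {
      if (jj <= ii) next
      if (resids[jj] - resids[ii] < min_sep) next
      d <- min(pair_distances(ref$frame$xyz[idx_by_res[[ii]], , drop = FALSE],
                              ref$frame$xyz[idx_by_res[[jj]], , drop = FALSE],
                              box = ref$frame$box))
      if (d <= rc) pairs[[length(pairs) + 1L]] <- c(resids[ii], resids[jj])
    }
  }
  out <- if (length(pairs) == 0) {
    data.frame(i = integer(0), j = integer(0))
  } else {
    as.data.frame(do.call(rbind, pairs)) |> stats::setNames(c("i", "j"))
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rc") <- rc
  attr(out, "min_sep") <- as.integer(min_sep)
  attr(out, "part") <- part
  class(out) <- c("native_contacts", "data.frame")
  out
}

#' Fraction of native contacts retained in a frame
#'
#' Q(t): the number of native residue pairs whose minimum heavy-atom
#' distance still satisfies the cutoff in this frame, divided by the size of
#' the native set (the count at time zero in the reference structure). Q of
#' the reference frame itself is 1 by construction.
#'
#' @param frame a [make_frame()] frame.
#' @param topology the matching [topology()].
#' @param ncs a [native_contacts()] set (non-empty).
#' @param rc cutoff (nm); defaults to the cutoff stored in `ncs`.
#' @return fraction in [0, 1].
#' @export
q_fraction <- function(frame, topology, ncs, rc = attr(ncs, "rc")) {
  if (nrow(ncs) == 0) stop("native-contact set is empty: Q is undefined")
  part <- attr(ncs, "part") %||% "heavy"
  keep <- topology$protein & topology$heavy
  if (part == "sidechain") keep <- keep & topology$sidechain
  retained <- 0L
  for (k in seq_len(nrow(ncs))) {
    ia <- which(keep & topology$resid == ncs$i[k])
    ja <- which(keep & topology$resid == ncs$j[k])
    d <- min(pair_distances(frame$xyz[ia, , drop = FALSE],
                            frame$xyz[ja, , drop = FALSE], box = frame$box))
    if (d <= rc) retained <- retained + 1L
  }
  retained / nrow(ncs)
}

# ---------------------------------------------------------------------------
# Backbone dihedrals and helix assignment

#' Backbone phi/psi angles per residue
#'
#' phi_i = C(i-1)-N(i)-CA(i)-C(i), psi_i = N(i)-CA(i)-C(i)-N(i+1); NA where
#' a flanking residue or a backbone atom is missing (chain termini are
#' therefore unassignable).
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @return data.frame with columns `resid`, `phi`, `psi` (degrees).
#' @export
phi_psi <- function(frame, topology) {
  prot <- topology$protein
  resids <- sort(unique(topology$resid[prot]))
  bb_index <- function(r, nm) {
    i <- which(prot & topology$resid == r & topology$name == nm)
    if (length(i) == 1) i else NA_integer_
  }
  n_i <- vapply(resids, bb_index, integer(1), nm = "N")
  ca_i <- vapply(resids, bb_index, integer(1), nm = "CA")
  c_i <- vapply(resids, bb_index, integer(1), nm = "C")
  phi <- psi <- rep(NA_real_, length(resids))
  for (k in seq_along(resids)) {
    prev <- match(resids[k] - 1L, resids)
    nxt <- match(resids[k] + 1L, resids)
    at <- c(n_i[k], ca_i[k], c_i[k])
    if (!is.na(prev) && !anyNA(c(c_i[prev], at))) {
      phi[k] <- dihedral_angle(frame$xyz[c_i[prev], ], frame$xyz[n_i[k], ],
                               frame$xyz[ca_i[k], ], frame$xyz[c_i[k], ])
    }
    if (!is.na(nxt) && !anyNA(c(at, n_i[nxt]))) {
      psi[k] <- dihedral_angle(frame$xyz[n_i[k], ], frame$xyz[ca_i[k], ],
                               frame$xyz[c_i[k], ], frame$xyz[n_i[nxt], ])
    }
  }
  data.frame(resid = resids, phi = phi, psi = psi)
}

#' Helical-state flags from phi/psi windows
#'
#' A residue is helical when (phi, psi) lies within `window` degrees of the
#' ideal alpha-helix (-57, -47) and it belongs to a run of at least
#' `min_run` consecutive such residues — the run rule mirrors the fact that
#' a lone residue with helical dihedrals is not a helix.
#'
#' @param pp output of [phi_psi()] (or a logical vector of in-window states
#'   via [helical_run_filter()]).
#' @param phi0,psi0 window centres (degrees).
#' @param window half-width (degrees).
#' @param min_run minimum consecutive run length.
#' @return data.frame `resid`, `assignable`, `helical`.
#' @export
helical_states <- function(pp, phi0 = -57, psi0 = -47, window = 30,
                           min_run = 4L) {
  assignable <- !is.na(pp$phi) & !is.na(pp$psi)
  in_window <- assignable &
    abs(angle_diff(pp$phi, phi0)) <= window &
    abs(angle_diff(pp$psi, psi0)) <= window
  # Runs must be consecutive in residue id as well as in table order.
  contiguous <- c(TRUE, diff(pp$resid) == 1L)
  helical <- helical_run_filter(in_window & !is.na(in_window), contiguous,
                                min_run)
  data.frame(resid = pp$resid, assignable = assignable, helical = helical)
}

# Minimal-image difference between two angles in degrees.
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Run-length filter for helical assignment
#'
#' Keeps TRUE entries only inside maximal runs of length >= `min_run`;
#' `contiguous[i]` FALSE breaks the run between i-1 and i (residue-id gap).
#'
#' @param state logical vector of in-window states.
#' @param contiguous logical vector marking positions contiguous with their
#'   predecessor.
#' @param min_run minimum run length.
#' @return logical vector.
#' @export
helical_run_filter <- function(state, contiguous = NULL, min_run = 4L) {
  n <- length(state)
  if (is.null(contiguous)) contiguous <- rep(TRUE, n)
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    if (!state[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] && contiguous[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_run) out[i:j] <- TRUE
    i <- j + 1L
  }
  out
}

#' Alpha-helix ratio of a frame
#'
#' Fraction of assignable residues (those with both phi and psi defined)
#' currently in a helical run, optionally restricted to given spans. With
#' the default spans this is the helix ratio tracked alongside the
#' hydrogen-bond ratio during denaturation.
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param spans a [helix_spans()] list restricting the denominator, or NULL
#'   for all assignable residues.
#' @inheritParams helical_states
#' @return fraction in [0, 1] (NaN when no residue is assignable).
#' @export
helix_ratio <- function(frame, topology, spans = NULL, phi0 = -57,
                        psi0 = -47, window = 30, min_run = 4L) {
  pp <- phi_psi(frame, topology)
  st <- helical_states(pp, phi0, psi0, window, min_run)
  if (!is.null(spans)) {
    keep <- st$resid %in% unlist(spans)
    st <- st[keep, , drop = FALSE]
  }
  n_assign <- sum(st$assignable)
  if (n_assign == 0) {
    warning("no assignable residues for helix ratio")
    return(NaN)
  }
  sum(st$helical & st$assignable) / n_assign
}

# ---------------------------------------------------------------------------
# Hydrogen bonds

#' Hydrogen-bond count
#'
#' Geometric criterion: donor-acceptor (N/O heavy atoms of different,
#' non-adjacent residues; covalently adjacent backbone N/O pairs sit at
#' bonded distances and are excluded) distance <= `rc` (default 0.35 nm)
#' and, when a hydrogen is attached to either partner, a donor-H-acceptor
#' angle >= `angle_min` (default 150 deg) for at least one such hydrogen. Without hydrogens the
#' heavy-atom distance criterion alone is used (common for trajectories
#' stored without H), and a note records that.
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param donors,acceptors atom index sets; default all N and O heavy atoms
#'   outside the sheet.
#' @param rc donor-acceptor cutoff (nm).
#' @param angle_min donor-H-acceptor angle cutoff (degrees).
#' @return integer count of donor-acceptor pairs (unordered, counted once).
#' @export
hbond_count <- function(frame, topology, donors = NULL, acceptors = NULL,
                        rc = 0.35, angle_min = 150) {
  is_da <- topology$heavy & !topology$sheet &
    toupper(topology$element) %in% c("N", "O")
  if (is.null(donors)) donors <- which(is_da)
  if (is.null(acceptors)) acceptors <- which(is_da)
  if (length(donors) == 0 || length(acceptors) == 0) return(0L)
  hyd <- which(!topology$heavy)
  # Attach each hydrogen to its nearest heavy N/O within covalent range.
  h_owner <- integer(0)
  if (length(hyd) > 0) {
    da_all <- which(is_da)
    dh <- pair_distances(frame$xyz[hyd, , drop = FALSE],
                         frame$xyz[da_all, , drop = FALSE], box = frame$box)
    nearest <- apply(dh, 1, which.min)
    close_enough <- dh[cbind(seq_along(hyd), nearest)] <= 0.12
    h_owner <- ifelse(close_enough, da_all[nearest], NA_integer_)
  }
  d <- pair_distances(frame$xyz[donors, , drop = FALSE],
                      frame$xyz[acceptors, , drop = FALSE], box = frame$box)
  hits <- which(d <= rc, arr.ind = TRUE)
  count <- 0L
  seen <- character(0)
  for (row in seq_len(nrow(hits))) {
    ia <- donors[hits[row, 1]]
    ja <- acceptors[hits[row, 2]]
    if (ia == ja) next
    # same residue never pairs; covalently adjacent protein residues are
    # excluded too (their backbone N/O sit at bonded distances)
    same_chain <- topology$chain[ia] == topology$chain[ja]
    dres <- abs(topology$resid[ia] - topology$resid[ja])
    is_water_pair <- topology$water[ia] || topology$water[ja]
    if (same_chain && !is_water_pair && dres <= 1L) next
    if (same_chain && is_water_pair && dres == 0L) next
    key <- paste(min(ia, ja), max(ia, ja))
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(hyd) > 0) {
      ok <- hbond_angle_ok(frame, hyd, h_owner, ia, ja, angle_min) ||
        hbond_angle_ok(frame, hyd, h_owner, ja, ia, angle_min)
      has_h <- any(h_owner %in% c(ia, ja), na.rm = TRUE)
      if (has_h && !ok) next
    }
    count <- count + 1L
  }
  count
}

hbond_angle_ok <- function(frame, hyd, h_owner, donor, acceptor, angle_min) {
  hs <- hyd[!is.na(h_owner) & h_owner == donor]
  for (h in hs) {
    v1 <- frame$xyz[donor, ] - frame$xyz[h, ]
    v2 <- frame$xyz[acceptor, ] - frame$xyz[h, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    if (ang >= angle_min) return(TRUE)
  }
  FALSE
}

#' Hydrogen-bond ratio relative to a reference count
#'
#' @param frame,topology as in [hbond_count()].
#' @param reference_count H-bond count of the reference structure.
#' @param ... forwarded to [hbond_count()].
#' @return ratio (count / reference).
#' @export
hbond_ratio <- function(frame, topology, reference_count, ...) {
  if (reference_count <= 0) stop("reference H-bond count must be positive")
  hbond_count(frame, topology, ...) / reference_count
}

# ---------------------------------------------------------------------------
# Specific interaction detectors

BASIC_N_NAMES <- c(ARG = "NE|NH1|NH2", LYS = "NZ")
ACIDIC_O_NAMES <- c(ASP = "OD1|OD2", GLU = "OE1|OE2")
RING_NAMES <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")  # six-membered ring
)

residue_atoms <- function(topology, resid, pattern = NULL) {
  idx <- which(topology$resid == resid & topology$protein)
  if (!is.null(pattern)) {
    idx <- idx[grepl(paste0("^(", pattern, ")$"), topology$name[idx])]
  }
  idx
}

#' Salt-bridge detector
#'
#' TRUE when the minimum distance between the basic residue's sidechain
#' nitrogens (Arg: NE/NH1/NH2; Lys: NZ) and the acidic residue's carboxylate
#' oxygens (Asp: OD1/OD2; Glu: OE1/OE2) is at most `rc` (default 0.4 nm).
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param basic_resid,acidic_resid residue ids; types are checked.
#' @param rc cutoff (nm).
#' @return logical.
#' @export
salt_bridge <- function(frame, topology, basic_resid, acidic_resid,
                        rc = 0.4) {
  bname <- unique(topology$resname[topology$resid == basic_resid &
                                     topology$protein])
  aname <- unique(topology$resname[topology$resid == acidic_resid &
                                     topology$protein])
  if (length(bname) != 1 || !bname %in% names(BASIC_N_NAMES)) {
    stop(sprintf("residue %d is not basic (Arg/Lys)", basic_resid))
  }
  if (length(aname) != 1 || !aname %in% names(ACIDIC_O_NAMES)) {
    stop(sprintf("residue %d is not acidic (Asp/Glu)", acidic_resid))
  }
  ni <- residue_atoms(topology, basic_resid, BASIC_N_NAMES[[bname]])
  oi <- residue_atoms(topology, acidic_resid, ACIDIC_O_NAMES[[aname]])
  if (length(ni) == 0 || length(oi) == 0) {
    stop("charged-group atoms missing for salt-bridge test")
  }
  min(pair_distances(frame$xyz[ni, , drop = FALSE],
                     frame$xyz[oi, , drop = FALSE], box = frame$box)) <= rc
}

#' Cation-pi stacking detector
#'
#' TRUE when the distance from the cation group centre (Arg: guanidinium
#' carbon CZ; Lys: NZ) to the aromatic ring centroid (mean of ring-atom
#' positions; Trp uses its six-membered ring) is at most `rc` (default
#' 0.5 nm).
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param cation_resid Arg or Lys residue id.
#' @param aromatic_resid Phe, Tyr or Trp residue id.
#' @param rc cutoff (nm).
#' @return logical.
#' @export
cation_pi <- function(frame, topology, cation_resid, aromatic_resid,
                      rc = 0.5) {
  cname <- unique(topology$resname[topology$resid == cation_resid &
                                     topology$protein])
  rname <- unique(topology$resname[topology$resid == aromatic_resid &
                                     topology$protein])
  if (length(cname) != 1 || !cname %in% c("ARG", "LYS")) {
    stop(sprintf("residue %d is not a cation donor (Arg/Lys)", cation_resid))
  }
  if (length(rname) != 1 || !rname %in% names(RING_NAMES)) {
    stop(sprintf("residue %d is not aromatic (Phe/Tyr/Trp)", aromatic_resid))
  }
  cat_name <- if (cname == "ARG") "CZ" else "NZ"
  ci <- residue_atoms(topology, cation_resid, cat_name)
  ring <- residue_atoms(topology, aromatic_resid,
                        paste(RING_NAMES[[rname]], collapse = "|"))
  if (length(ci) != 1 || length(ring) < 5) {
    stop("cation or ring atoms missing for cation-pi test")
  }
  centroid <- colMeans(frame$xyz[ring, , drop = FALSE])
  sqrt(sum((frame$xyz[ci, ] - centroid)^2)) <= rc
}

# ---------------------------------------------------------------------------
# Residue classification

HYDROPHOBIC_SET <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

#' Hydrophobic percentage of a residue list
#'
#' Share of residues classified hydrophobic (default set Ala, Val, Leu, Ile,
#' Met, Phe, Trp, Pro — aromatics Phe/Trp included), in percent. Accepts
#' three-letter codes, one-letter codes, or `"Arg-55"`-style labels.
#'
#' @param residues character vector of residue names/labels.
#' @param classification character vector of hydrophobic three-letter codes.
#' @return percentage in [0, 100].
#' @export
hydrophobic_fraction <- function(residues, classification = HYDROPHOBIC_SET) {
  if (length(residues) == 0) stop("empty residue list")
  names_only <- sub("[-_ ]?[0-9]+$", "", trimws(residues))
  codes <- as_residue_codes(names_only)
  100 * mean(codes %in% toupper(classification))
}
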