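# Deterministic synthetic systems and trajectories with exact ground truth
# for every analysis stage: an ideal three-helix-bundle builder, backbone
# dihedral manipulation (helix melting), and a scenario generator emulating
# the phenomenology of protein adsorption on a monolayer (rigid-body
# approach, programmed per-residue contact onsets, progressive helix loss,
# explicitly placed hydration-shell waters). No forces are ever computed:
# every frame is constructed, which is what makes the ground truth exact.

# Heavy-atom counts of amino-acid sidechains (standard residues).
SIDECHAIN_HEAVY <- c(ALA = 1L, ARG = 7L, ASN = 4L, ASP = 4L, CYS = 2L,
                     GLN = 5L, GLU = 5L, GLY = 0L, HIS = 6L, ILE = 4L,
                     LEU = 4L, LYS = 5L, MET = 4L, PHE = 7L, PRO = 3L,
                     SER = 2L, THR = 3L, TRP = 10L, TYR = 8L, VAL = 3L)

# Ideal backbone internal coordinates (nm / degrees).
BB_GEOM <- list(b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
                b_c_o = 0.1229, b_ca_cb = 0.1530,
                a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                a_ca_c_o = 120.8, a_n_ca_cb = 110.5, omega = 180)

HELIX_PHI <- -57; HELIX_PSI <- -47
COIL_PHI <- -120; COIL_PSI <- 120

#' Build an ideal three-helix-bundle model
#'
#' Backbone N/CA/C/O atoms are chained with ideal internal coordinates;
#' residues inside the helix spans get alpha-helical dihedrals (phi -57,
#' psi -47: 0.15 nm rise and ~100 deg twist per residue), loop residues get
#' extended dihedrals (phi -120, psi +120). Sidechains are a CB atom plus a
#' pseudo-atom cluster sized to the residue's heavy-atom count (contact,
#' hydration and energy metrics need heavy-atom positions and counts, not
#' rotamers). Formal charges sit on the terminal pseudo-atom of charged
#' sidechains and on the termini (zwitterionic), so the chain's net charge
#' equals [formal_charge()] of the sequence.
#'
#' @param sequence residue sequence (default the HP35 subdomain).
#' @param start_resid first residue id (default 42, the HP35 numbering).
#' @param spans a [helix_spans()] list (residue ids).
#' @param phi,psi optional per-residue dihedral vectors overriding the
#'   span-based defaults.
#' @return list(topology, frame).
#' @export
build_ideal_bundle <- function(sequence = hp35_sequence(),
                               start_resid = hp35_start_resid(),
                               spans = helix_spans(),
                               phi = NULL, psi = NULL) {
  codes <- as_residue_codes(sequence)
  n <- length(codes)
  resids <- seq.int(start_resid, length.out = n)
  span_res <- unlist(spans)
  if (!all(span_res %in% resids)) {
    stop("helix span outside the sequence residue range")
  }
  helical <- resids %in% span_res
  if (is.null(phi)) phi <- ifelse(helical, HELIX_PHI, COIL_PHI)
  if (is.null(psi)) psi <- ifelse(helical, HELIX_PSI, COIL_PSI)
  g <- BB_GEOM
  n_xyz <- ca_xyz <- c_xyz <- vector("list", n)
  n_xyz[[1]] <- c(0, 0, 0)
  ca_xyz[[1]] <- c(g$b_n_ca, 0, 0)
  dir_c <- c(-cos(g$a_n_ca_c * pi / 180), sin(g$a_n_ca_c * pi / 180), 0)
  c_xyz[[1]] <- ca_xyz[[1]] + g$b_ca_c * dir_c
  for (i in seq_len(n)[-1]) {
    n_xyz[[i]] <- nerf_place(n_xyz[[i - 1]], ca_xyz[[i - 1]], c_xyz[[i - 1]],
                             g$b_c_n, g$a_ca_c_n, psi[i - 1])
    ca_xyz[[i]] <- nerf_place(ca_xyz[[i - 1]], c_xyz[[i - 1]], n_xyz[[i]],
                              g$b_n_ca, g$a_c_n_ca, g$omega)
    c_xyz[[i]] <- nerf_place(c_xyz[[i - 1]], n_xyz[[i]], ca_xyz[[i]],
                             g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  name <- character(0); resid <- integer(0); resname <- character(0)
  element <- character(0); charge <- numeric(0)
  xyz <- matrix(numeric(0), 0, 3)
  add <- function(nm, el, q, pos) {
    name <<- c(name, nm); element <<- c(element, el)
    charge <<- c(charge, q); xyz <<- rbind(xyz, pos)
    resid <<- c(resid, resids[i]); resname <<- c(resname, codes[i])
  }
  for (i in seq_len(n)) {
    o_pos <- nerf_place(n_xyz[[i]], ca_xyz[[i]], c_xyz[[i]],
                        g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    add("N", "N", if (i == 1) 1 else 0, n_xyz[[i]])
    add("CA", "C", 0, ca_xyz[[i]])
    add("C", "C", 0, c_xyz[[i]])
    add("O", "O", if (i == n) -1 else 0, o_pos)
    n_side <- SIDECHAIN_HEAVY[[codes[i]]]
    if (n_side >= 1) {
      q_side <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)[codes[i]]
      if (is.na(q_side)) q_side <- 0
      cb <- nerf_place(c_xyz[[i]], n_xyz[[i]], ca_xyz[[i]],
                       g$b_ca_cb, g$a_n_ca_cb, 122.6)
      add("CB", "C", if (n_side == 1) q_side else 0, cb)
      if (n_side > 1) {
        # Pseudo cluster: march outward from CB along CA->CB with a small
        # deterministic spiral so atoms are distinct and non-collinear.
        u <- cb - ca_xyz[[i]]; u <- u / sqrt(sum(u^2))
        ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        v1 <- cross3(u, ref); v1 <- v1 / sqrt(sum(v1^2))
        v2 <- cross3(u, v1)
        for (k in seq_len(n_side - 1L)) {
          pos <- cb + 0.13 * k * u +
            0.05 * (cos(2.4 * k) * v1 + sin(2.4 * k) * v2)
          add(sprintf("CP%d", k), "C",
              if (k == n_side - 1L) q_side else 0, pos)
        }
      }
    }
  }
  top <- topology(name = name, resid = resid, resname = resname,
                  chain = "A", element = element, charge = charge)
  list(topology = top, frame = make_frame(xyz))
}

# ---------------------------------------------------------------------------
# Backbone dihedral manipulation

# Atom indices of residue `r` moved by a phi/psi rotation of residue `r`:
# phi (about N-CA): everything past CA, i.e. C, O and the sidechain, plus
# all later residues; psi (about CA-C): O plus all later residues.
moved_set <- function(topology, r, which_angle) {
  later <- which(topology$protein & topology$resid > r)
  own <- which(topology$protein & topology$resid == r)
  nm <- topology$name[own]
  if (which_angle == "phi") {
    c(own[!nm %in% c("N", "CA")], later)
  } else {
    c(own[nm == "O"], later)
  }
}

#' Set backbone dihedrals by rotating downstream atoms
#'
#' Rotates the moved set about the N-CA (phi) or CA-C (psi) axis so the
#' dihedral reaches the requested value; every other residue's internal
#' geometry is untouched (the downstream block moves rigidly).
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param resid residue id.
#' @param phi,psi target angles in degrees (NULL leaves an angle alone).
#' @return the modified frame.
#' @export
set_backbone_dihedrals <- function(frame, topology, resid, phi = NULL,
                                   psi = NULL) {
  xyz <- frame$xyz
  bb <- function(nm, r = resid) {
    i <- which(topology$protein & topology$resid == r & topology$name == nm)
    if (length(i) != 1) {
      stop(sprintf("residue %d lacks backbone atom %s", r, nm))
    }
    i
  }
  if (!is.null(phi)) {
    prev_c <- which(topology$protein & topology$resid == resid - 1L &
                      topology$name == "C")
    if (length(prev_c) != 1) {
      stop(sprintf("residue %d has no preceding residue: phi undefined", resid))
    }
    i_n <- bb("N"); i_ca <- bb("CA"); i_c <- bb("C")
    cur <- dihedral_angle(xyz[prev_c, ], xyz[i_n, ], xyz[i_ca, ], xyz[i_c, ])
    # rotating the downstream block by +d about the bond decreases the
    # dihedral by d under this sign convention
    delta <- (cur - phi) * pi / 180
    mv <- moved_set(topology, resid, "phi")
    xyz[mv, ] <- rotate_about_axis(xyz[mv, , drop = FALSE], xyz[i_n, ],
                                   xyz[i_ca, ] - xyz[i_n, ], delta)
  }
  if (!is.null(psi)) {
    next_n <- which(topology$protein & topology$resid == resid + 1L &
                      topology$name == "N")
    if (length(next_n) != 1) {
      stop(sprintf("residue %d has no following residue: psi undefined", resid))
    }
    i_n <- bb("N"); i_ca <- bb("CA"); i_c <- bb("C")
    cur <- dihedral_angle(xyz[i_n, ], xyz[i_ca, ], xyz[i_c, ], xyz[next_n, ])
    delta <- (cur - psi) * pi / 180
    mv <- moved_set(topology, resid, "psi")
    xyz[mv, ] <- rotate_about_axis(xyz[mv, , drop = FALSE], xyz[i_ca, ],
                                   xyz[i_c, ] - xyz[i_ca, ], delta)
  }
  make_frame(xyz, time_ps = frame$time_ps, box = frame$box)
}

#' Melt residues to coil
#'
#' Sets the listed residues' backbone dihedrals to the coil state
#' (phi -120, psi +120) by downstream rotation; an empty list is the
#' identity.
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param residues residue ids to melt.
#' @param to_state only `"coil"` is defined.
#' @return the modified frame.
#' @export
melt_residues <- function(frame, topology, residues, to_state = "coil") {
  to_state <- match.arg(to_state, "coil")
  for (r in sort(as.integer(residues))) {
    frame <- set_backbone_dihedrals(frame, topology, r,
                                    phi = COIL_PHI, psi = COIL_PSI)
  }
  frame
}

#' Residues to melt for a global melt fraction
#'
#' Deterministic order emulating helix-by-helix unfolding: helix 2 first,
#' then helix 3, then helix 1, each consumed from its C-terminal end, with
#' `round(m * n_span)` residues in total. Partial helices are left with
#' contiguous N-terminal remainders, so the run-length helix assignment
#' tracks `1 - m` closely.
#'
#' @param spans a [helix_spans()] list.
#' @param m melt fraction in [0, 1].
#' @return integer residue ids.
#' @export
melt_residues_for_fraction <- function(spans, m) {
  if (m < 0 || m > 1) stop("melt fraction must be in [0, 1]")
  order_res <- c(rev(spans$helix2), rev(spans$helix3), rev(spans$helix1))
  k <- round(m * length(order_res))
  sort(utils::head(order_res, k))
}

# ---------------------------------------------------------------------------
# Scenario generator

#' Synthetic adsorption scenario recipe
#'
#' Defines everything the generator needs; the defaults are the package's
#' desk-scale rendition of the adsorption phenomenology: a 20 ns window in
#' which the bundle approaches the sheet from the 0.8 nm starting gap,
#' helix 2 anchors first (Asn-60 at 2 ns, then Leu-61 and Arg-55),
#' helix 1 follows (Ser-43, Phe-47), helix 3 last (Leu-63, Trp-64), helix 2
#' melts before helix 3 while helix 1 stays intact, and the two tracked
#' residues dewet late in the window (18 shell waters dropping to 6 around
#' the aromatic, to 12 around the basic residue).
#'
#' @param sequence,start_resid,spans as in [build_ideal_bundle()].
#' @param n_frames number of frames.
#' @param dt_ps frame spacing (ps).
#' @param gap_start,gap_end rigid-body approach: the minimum protein-sheet
#'   heavy-atom gap descends linearly from `gap_start` to `gap_end` over
#'   `approach_ns`, then holds. `gap_end` must exceed the 0.6 nm contact
#'   cutoff so only programmed onsets create contacts.
#' @param approach_ns approach duration (ns).
#' @param onsets_ns named numeric, residue id -> first-contact time (ns);
#'   times are snapped to the frame grid (snapped values are the ground
#'   truth).
#' @param melt_ns named numeric, `"helix1"`/`"helix2"`/`"helix3"` -> melt
#'   time (ns); omitted helices never melt.
#' @param shell_waters data.frame with columns `resid`, `count`, `radius`
#'   and optional `count_final`, `dewet_ns` (count drops to `count_final`
#'   at `dewet_ns`).
#' @param contact_z height above the top S plane to which an onset
#'   residue's sidechain is pinned (nm; < 0.5 guarantees a 0.6 nm contact).
#' @param seed integer; fixes all randomness (water placement).
#' @return validated list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(sequence = hp35_sequence(),
                          start_resid = hp35_start_resid(),
                          spans = helix_spans(),
                          n_frames = 101L, dt_ps = 200,
                          gap_start = 0.8, gap_end = 0.65,
                          approach_ns = 2,
                          onsets_ns = c("60" = 2, "61" = 9, "55" = 9,
                                        "43" = 15, "47" = 15,
                                        "63" = 17, "64" = 17),
                          melt_ns = c(helix2 = 10, helix3 = 16),
                          shell_waters = data.frame(
                            resid = c(64L, 55L), count = c(18L, 18L),
                            radius = 0.42, count_final = c(6L, 12L),
                            dewet_ns = c(17, 16)),
                          contact_z = 0.35, seed = 1L) {
  codes <- as_residue_codes(sequence)
  resids <- seq.int(start_resid, length.out = length(codes))
  times_ns <- (seq_len(n_frames) - 1) * dt_ps / 1000
  t_end <- max(times_ns)
  if (gap_end <= 0.6) {
    stop("gap_end must stay above the 0.6 nm contact cutoff")
  }
  if (length(onsets_ns) > 0) {
    if (is.null(names(onsets_ns)) || !all(as.integer(names(onsets_ns)) %in%
                                          resids)) {
      stop("onsets_ns must be named by residue ids within the sequence")
    }
    if (any(onsets_ns > t_end)) {
      stop("contact onset after the end of the trajectory")
    }
    # Snap to the frame grid; the snapped values are the ground truth.
    onsets_ns <- vapply(onsets_ns,
                        function(t) times_ns[which.min(abs(times_ns - t))],
                        numeric(1))
  }
  if (length(melt_ns) > 0 &&
      !all(names(melt_ns) %in% names(spans))) {
    stop("melt_ns must be named helix1/helix2/helix3")
  }
  if (nrow(shell_waters) > 0) {
    stopifnot(all(c("resid", "count", "radius") %in% names(shell_waters)))
    if (any(shell_waters$count < 0) || any(shell_waters$radius <= 0)) {
      stop("shell water counts must be >= 0 and radii > 0")
    }
    gly <- codes[match(shell_waters$resid, resids)] == "GLY"
    if (any(gly)) stop("shell-water target residues must have sidechains")
    if (is.null(shell_waters$count_final)) shell_waters$count_final <- NA
    if (is.null(shell_waters$dewet_ns)) shell_waters$dewet_ns <- NA
  }
  structure(list(sequence = codes, start_resid = start_resid, spans = spans,
                 n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 gap_start = gap_start, gap_end = gap_end,
                 approach_ns = approach_ns, onsets_ns = onsets_ns,
                 melt_ns = melt_ns, shell_waters = shell_waters,
                 contact_z = contact_z, seed = as.integer(seed)),
            class = "scenario_spec")
}

# Deterministic per-frame stream seed (kept below 2^31 so it is a valid R
# integer); re-seeding per frame makes results independent of frame order.
frame_seed <- function(seed, frame) {
  as.integer((abs(seed) %% 100003L) * 20011 + frame * 7919) %% 2147483629L
}

#' Generate a synthetic adsorption trajectory with ground truth
#'
#' Every frame is constructed: the bundle (with the melt state scheduled
#' for that time) is rigidly placed at the scheduled gap over the sheet
#' centre, onset residues' sidechains are pinned `contact_z` above the top
#' sulfur plane from their onset time on, and each tracked residue's shell
#' waters are re-placed within the stated radius of its sidechain
#' (rejection-sampled outside a 0.25 nm core, clear of other targets'
#' shells and of the sheet), with exact counts. The returned ground truth
#' holds what every analysis stage must recover.
#'
#' @param spec a [scenario_spec()].
#' @param sheet a `"sheet_model"`; its extents should cover the bundle's
#'   footprint so pinned sidechains sit over the lattice.
#' @return list of class `"synthetic_run"`: `traj` (a [trajectory()]
#'   including sheet and water atoms), `reference` (the unplaced ideal
#'   bundle), `truth` (list: `times_ns`, `q`, `helix_fraction`,
#'   `melt_fraction`, `onsets`, `anchoring`, `fss_counts`,
#'   `contact_residue_count`), `spec`, `sheet`.
#' @export
generate_trajectory <- function(spec, sheet) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(sheet, "sheet_model"))
  bundle <- build_ideal_bundle(spec$sequence, spec$start_resid, spec$spans)
  times_ns <- (seq_len(spec$n_frames) - 1) * spec$dt_ps / 1000
  sheet_st <- sheet_as_structure(sheet)
  sheet_top_z <- max(sheet_st$frame$xyz[, 3])
  resids <- sort(unique(bundle$topology$resid))
  span_res <- lapply(spec$spans, identity)

  # Melt schedule: residue -> melt time from per-helix times.
  melt_time <- rep(Inf, length(resids))
  names(melt_time) <- resids
  for (hx in names(spec$melt_ns)) {
    melt_time[as.character(span_res[[hx]])] <- spec$melt_ns[[hx]]
  }

  onset_res <- as.integer(names(spec$onsets_ns))
  onset_t <- as.numeric(spec$onsets_ns)

  # Water block of the topology: one oxygen per shell water, constant count.
  sw <- spec$shell_waters
  n_w <- if (nrow(sw) > 0) sum(sw$count) else 0L
  water_top <- if (n_w > 0) {
    topology(name = rep("OW", n_w),
             resid = 9000L + seq_len(n_w),
             resname = "SOL", chain = "W", element = "O", charge = 0)
  } else NULL
  full_top <- rbind_topology(bundle$topology, sheet_st$topology, water_top)

  sidechain_idx <- function(r) {
    which(bundle$topology$resid == r & bundle$topology$sidechain &
            bundle$topology$heavy)
  }

  # Conformation cache keyed by the melted residue set.
  conf_cache <- new.env(parent = emptyenv())
  melted_conf <- function(melted) {
    key <- paste0("m:", paste(melted, collapse = ","))
    if (!is.null(conf_cache[[key]])) return(conf_cache[[key]])
    fr <- if (length(melted) == 0) bundle$frame else {
      melt_residues(bundle$frame, bundle$topology, melted)
    }
    conf_cache[[key]] <- fr
    fr
  }

  frames <- vector("list", spec$n_frames)
  fss_truth <- matrix(0L, spec$n_frames, nrow(sw),
                      dimnames = list(NULL, as.character(sw$resid)))
  contact_truth <- integer(spec$n_frames)
  melt_frac <- numeric(spec$n_frames)
  helix_frac <- numeric(spec$n_frames)
  span_all <- unlist(span_res)

  for (f in seq_len(spec$n_frames)) {
    t <- times_ns[f]
    gap_t <- if (t >= spec$approach_ns) spec$gap_end else {
      spec$gap_start + (spec$gap_end - spec$gap_start) * t / spec$approach_ns
    }
    melted <- resids[melt_time[as.character(resids)] <= t]
    conf <- melted_conf(melted)
    placed <- place_protein(list(topology = bundle$topology, frame = conf),
                            sheet, gap = gap_t, warn_overhang = FALSE)
    pxyz <- placed$protein$frame$xyz
    in_contact <- onset_res[onset_t <= t + 1e-9]
    for (r in in_contact) {
      sc <- sidechain_idx(r)
      # Pin the sidechain in a thin slab [contact_z, contact_z + 0.15]
      # above the top S plane (every atom then sits well inside the 0.6 nm
      # contact cutoff of the nearest lattice atom) ...
      z0 <- pxyz[sc, 3] - min(pxyz[sc, 3])
      pxyz[sc, 3] <- sheet_top_z + spec$contact_z +
        0.15 * z0 / max(max(z0), 1)
      # ... and keep it laterally over the lattice: clamp the cluster into
      # the sheet footprint (denatured conformations can overhang the edge).
      for (ax in 1:2) {
        lo <- min(sheet_st$frame$xyz[, ax]) + 0.2
        hi <- max(sheet_st$frame$xyz[, ax]) - 0.2
        mn <- min(pxyz[sc, ax]); mx <- max(pxyz[sc, ax])
        if (mn < lo) {
          pxyz[sc, ax] <- pxyz[sc, ax] + (lo - mn)
        } else if (mx > hi) {
          pxyz[sc, ax] <- pxyz[sc, ax] - (mx - hi)
        }
      }
    }
    contact_truth[f] <- length(in_contact)
    melt_frac[f] <- mean(span_all %in% melted)
    helix_frac[f] <- programmed_helix_fraction(span_res, melted)
    wxyz <- NULL
    if (n_w > 0) {
      set.seed(frame_seed(spec$seed, f))
      counts_f <- ifelse(!is.na(sw$dewet_ns) & t >= sw$dewet_ns,
                         sw$count_final, sw$count)
      fss_truth[f, ] <- as.integer(counts_f)
      wxyz <- place_shell_waters(pxyz, bundle$topology, sw, counts_f,
                                 sheet_top_z)
    }
    frames[[f]] <- rbind(pxyz, sheet_st$frame$xyz, wxyz)
  }

  traj <- trajectory(full_top, frames, times_ns * 1000)

  # Ground-truth Q by exhaustive recount against the unplaced reference.
  native <- brute_native_pairs(bundle, rc = 0.6, min_sep = 3L)
  pair_idx <- if (is.null(native)) list() else {
    lapply(seq_len(nrow(native)), function(k) {
      list(ia = which(full_top$resid == native[k, 1] & full_top$protein &
                        full_top$heavy),
           ib = which(full_top$resid == native[k, 2] & full_top$protein &
                        full_top$heavy))
    })
  }
  q_truth <- vapply(seq_len(spec$n_frames), function(f) {
    brute_q(frames[[f]], pair_idx, rc = 0.6)
  }, numeric(1))

  onset_order <- order(onset_res)
  truth <- list(
    times_ns = times_ns,
    q = q_truth,
    helix_fraction = helix_frac,
    melt_fraction = melt_frac,
    onsets = data.frame(resid = onset_res[onset_order],
                        onset_ns = onset_t[onset_order]),
    anchoring = programmed_anchoring(span_res, onset_res, onset_t),
    fss_counts = fss_truth,
    contact_residue_count = contact_truth
  )
  structure(list(traj = traj, reference = bundle, truth = truth,
                 spec = spec, sheet = sheet),
            class = "synthetic_run")
}

rbind_topology <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("nanotop", "data.frame")
  rownames(out) <- NULL
  out
}

# Helix fraction implied by the programmed melt state, using the same
# >= 4-residue-run rule as the analysis but driven by states, not dihedrals.
programmed_helix_fraction <- function(span_res, melted) {
  span_all <- sort(unlist(span_res))
  state <- !(span_all %in% melted)
  contiguous <- c(TRUE, diff(span_all) == 1L)
  helical <- helical_run_filter(state, contiguous, 4L)
  mean(helical)
}

programmed_anchoring <- function(span_res, onset_res, onset_t) {
  first <- vapply(span_res, function(rng) {
    v <- onset_t[onset_res %in% rng]
    if (length(v) == 0) NA_real_ else min(v)
  }, numeric(1))
  hx <- seq_along(span_res)
  ord <- order(is.na(first), first, hx)
  data.frame(helix = hx[ord], onset_ns = as.numeric(first[ord]))
}

# Place shell waters around each target residue's sidechain: distance to a
# chosen sidechain atom in [0.27, radius], outside a 0.25 nm core of every
# protein atom, > 0.5 nm from other targets' sidechains, clear of the sheet.
place_shell_waters <- function(pxyz, prot_top, sw, counts_f, sheet_top_z) {
  target_sc <- lapply(sw$resid, function(r) {
    which(prot_top$resid == r & prot_top$sidechain & prot_top$heavy)
  })
  out <- matrix(NA_real_, sum(sw$count), 3)
  row <- 0L
  for (ti in seq_len(nrow(sw))) {
    sc <- target_sc[[ti]]
    others <- unlist(target_sc[-ti])
    placed <- 0L
    attempts <- 0L
    while (placed < counts_f[ti]) {
      attempts <- attempts + 1L
      if (attempts > 20000L) {
        stop(sprintf("could not place shell waters for residue %d",
                     sw$resid[ti]))
      }
      anchor <- sc[(placed %% length(sc)) + 1L]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, 0.27, sw$radius[ti])
      pos <- pxyz[anchor, ] + r * u
      if (pos[3] <= sheet_top_z + 0.25) next
      d_all <- sqrt(colSums((t(pxyz) - pos)^2))
      if (min(d_all) < 0.25) next
      if (length(others) > 0 && min(d_all[others]) <= 0.5) next
      placed <- placed + 1L
      row <- row + 1L
      out[row, ] <- pos
    }
    # Unused slots (after dewetting) park far above the system, outside
    # every shell, so the topology's water count stays constant.
    extra <- sw$count[ti] - counts_f[ti]
    if (extra > 0) {
      for (k in seq_len(extra)) {
        row <- row + 1L
        out[row, ] <- c(pxyz[sc[1], 1] + 3 + ti, pxyz[sc[1], 2] + 3 + k,
                        max(pxyz[, 3]) + 5 + k)
      }
    }
  }
  out
}

# Exhaustive native-contact scan (independent of the metrics module's
# implementation; plain double loop used for ground truth).
brute_native_pairs <- function(bundle, rc = 0.6, min_sep = 3L) {
  top <- bundle$topology
  xyz <- bundle$frame$xyz
  resids <- sort(unique(top$resid))
  pairs <- NULL
  for (a in seq_along(resids)) {
    for (b in seq_along(resids)) {
      if (resids[b] - resids[a] < min_sep) next
      ia <- which(top$resid == resids[a] & top$heavy)
      ib <- which(top$resid == resids[b] & top$heavy)
      dmin <- Inf
      for (i in ia) for (j in ib) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin <= rc) pairs <- rbind(pairs, c(resids[a], resids[b]))
    }
  }
  pairs
}

# Exhaustive per-pair recount (independent reimplementation: per-axis outer
# differences, no shared distance helper).
brute_q <- function(xyz, pair_idx, rc = 0.6) {
  if (length(pair_idx) == 0) return(NA_real_)
  keep <- 0L
  for (p in pair_idx) {
    d2 <- outer(xyz[p$ia, 1], xyz[p$ib, 1], "-")^2 +
      outer(xyz[p$ia, 2], xyz[p$ib, 2], "-")^2 +
      outer(xyz[p$ia, 3], xyz[p$ib, 3], "-")^2
    if (min(d2) <= rc^2) keep <- keep + 1L
  }
  keep / length(pair_idx)
}
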