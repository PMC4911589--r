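# Interfacial water metrics (first-solvation-shell counts, dewetting-slab
# counts) and adsorption kinetics (first-contact times, helix anchoring
# order, adsorption-denaturation correlation).

#' First-solvation-shell water count of a residue
#'
#' Number of water molecules whose oxygen lies within `rc_fss` of any heavy
#' atom of the residue's selected part (minimum image when a box is
#' present). The cutoff default (0.45 nm) is the package's choice of FSS
#' radius — the quantity itself ("how many waters solvate this residue, and
#' how many leave on adsorption") is what dewetting analyses track.
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param resid residue id.
#' @param rc_fss shell radius (nm).
#' @param part `"sidechain"` (default) or `"all"` heavy atoms of the
#'   residue; a residue with no sidechain heavy atoms (glycine) raises an
#'   error suggesting `part = "all"`.
#' @return integer water count.
#' @export
fss_water_count <- function(frame, topology, resid, rc_fss = 0.45,
                            part = c("sidechain", "all")) {
  part <- match.arg(part)
  if (rc_fss <= 0) stop("rc_fss must be > 0")
  keep <- topology$resid == resid & topology$protein & topology$heavy
  if (part == "sidechain") keep <- keep & topology$sidechain
  idx <- which(keep)
  if (length(idx) == 0) {
    stop(sprintf("residue %d has no heavy atoms in part '%s'%s", resid, part,
                 if (part == "sidechain") "; use part = \"all\"" else ""))
  }
  ow <- which(topology$water & topology$heavy &
                toupper(topology$element) == "O")
  if (length(ow) == 0) return(0L)
  d <- pair_distances(frame$xyz[ow, , drop = FALSE],
                      frame$xyz[idx, , drop = FALSE], box = frame$box)
  sum(apply(d <= rc_fss, 1, any))
}

#' Water count in the residue-sheet interfacial slab
#'
#' Counts water oxygens inside the axis-aligned prism between the sheet's
#' top sulfur plane and the residue's lowest heavy atom, laterally bounded
#' by the residue's heavy-atom xy bounding box expanded by `pad_xy`. A
#' dropping count signals a drying (dewetting) zone forming under the
#' residue. The box prism is an axis-aligned approximation (deterministic
#' and simple, in place of a convex hull).
#'
#' @param frame a frame.
#' @param topology the matching topology.
#' @param resid residue id (needs at least one heavy atom).
#' @param sheet_top_z z of the top sulfur plane (nm); from a
#'   `"sheet_model"` use `max(sheet_xyz(sheet)[, 3])`.
#' @param pad_xy lateral expansion of the bounding box (nm).
#' @return integer water count.
#' @export
interfacial_water_count <- function(frame, topology, resid, sheet_top_z,
                                    pad_xy = 0.3) {
  idx <- which(topology$resid == resid & topology$protein & topology$heavy)
  if (length(idx) == 0) stop(sprintf("residue %d has no heavy atoms", resid))
  rxyz <- frame$xyz[idx, , drop = FALSE]
  z_low <- min(rxyz[, 3])
  if (z_low <= sheet_top_z) {
    stop(sprintf("residue %d lies at or below the top S plane (z %.3f <= %.3f)",
                 resid, z_low, sheet_top_z))
  }
  ow <- which(topology$water & topology$heavy &
                toupper(topology$element) == "O")
  if (length(ow) == 0) return(0L)
  w <- frame$xyz[ow, , drop = FALSE]
  xr <- range(rxyz[, 1]) + c(-pad_xy, pad_xy)
  yr <- range(rxyz[, 2]) + c(-pad_xy, pad_xy)
  sum(w[, 3] > sheet_top_z & w[, 3] < z_low &
        w[, 1] >= xr[1] & w[, 1] <= xr[2] &
        w[, 2] >= yr[1] & w[, 2] <= yr[2])
}

#' First persistent contact time per residue
#'
#' For each residue's contact-count series (uniform time grid), the
#' earliest time t such that the count is positive for at least
#' `persistence_k` consecutive frames starting at t; `NA` when never. The
#' persistence requirement keeps single-frame grazing contacts from
#' defining an onset.
#'
#' @param times_ns frame times (ns), uniform grid.
#' @param counts matrix frames x residues (columns named by residue id) or
#'   a single numeric series.
#' @param persistence_k required consecutive frames (>= 1).
#' @return data.frame `resid`, `onset_ns` (NA when no persistent contact).
#' @export
first_contact_time <- function(times_ns, counts, persistence_k = 5L) {
  if (length(times_ns) == 0) stop("empty contact series")
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1, dimnames = list(NULL, "1"))
  }
  stopifnot(nrow(counts) == length(times_ns), persistence_k >= 1)
  onset_one <- function(v) {
    pos <- v > 0
    run <- 0L
    for (i in seq_along(pos)) {
      run <- if (pos[i]) run + 1L else 0L
      if (run >= persistence_k) return(times_ns[i - persistence_k + 1L])
    }
    NA_real_
  }
  data.frame(resid = as.integer(colnames(counts)),
             onset_ns = apply(counts, 2, onset_one))
}

#' Helix anchoring order from per-residue onsets
#'
#' Helices sorted by the earliest onset among their residues; helices with
#' no onset come last; ties (including the all-tied case) break by helix
#' index.
#'
#' @param onsets data.frame from [first_contact_time()].
#' @param spans a [helix_spans()] grouping.
#' @return data.frame `helix` (index, sorted by anchoring), `onset_ns`
#'   (NA when the helix never contacts).
#' @export
anchoring_order <- function(onsets, spans = helix_spans()) {
  hx <- seq_along(spans)
  first <- vapply(spans, function(rng) {
    v <- onsets$onset_ns[onsets$resid %in% rng]
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(first))) stop("no helix has a contact onset")
  ord <- order(is.na(first), first, hx)
  data.frame(helix = hx[ord], onset_ns = as.numeric(first[ord]))
}

#' Correlation between surface adsorption and denaturation
#'
#' Pearson correlation between the sheet-contact count and the native-
#' contact loss (1 - Q) on a shared time grid (series resampled by nearest
#' time when grids differ). A value near +1 quantifies "denaturation is
#' directly proportional to adsorption".
#'
#' @param contact_times_ns,contacts contact-count series.
#' @param q_times_ns,q native-contact-fraction series.
#' @return Pearson correlation, or `NA` with a warning when either series
#'   is constant (undefined correlation).
#' @export
adsorption_denaturation_correlation <- function(contact_times_ns, contacts,
                                                q_times_ns = contact_times_ns,
                                                q) {
  stopifnot(length(contact_times_ns) == length(contacts),
            length(q_times_ns) == length(q))
  if (!isTRUE(all.equal(contact_times_ns, q_times_ns))) {
    nearest <- vapply(contact_times_ns,
                      function(t) which.min(abs(q_times_ns - t)), 1L)
    q <- q[nearest]
  }
  loss <- 1 - q
  if (stats::sd(contacts) == 0 || stats::sd(loss) == 0) {
    warning("constant series: adsorption-denaturation correlation undefined")
    return(NA_real_)
  }
  stats::cor(contacts, loss, method = "pearson")
}
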