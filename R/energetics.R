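# Protein-sheet nonbonded interaction energies: truncated Lennard-Jones and
# Coulomb pair sums with per-residue decomposition, tail averaging and the
# favorable-residue filter. Sign convention: negative = attractive. External
# unit kcal/mol (kJ/mol converted with the exact factor 4.184).

KJ_PER_KCAL <- 4.184
# Coulomb prefactor 1/(4 pi eps0) = 138.935458 kJ nm / (mol e^2).
COULOMB_KCAL <- 138.935458 / KJ_PER_KCAL  # kcal nm / (mol e^2)

#' Lennard-Jones 12-6 pair energy
#'
#' 4 eps [ (sigma/r)^12 - (sigma/r)^6 ]: zero at r = sigma, minimum -eps at
#' r = 2^(1/6) sigma. Vectorized over `r`.
#'
#' @param r distance (nm), > 0.
#' @param sigma_ij combined sigma (nm).
#' @param eps_ij combined epsilon (kcal/mol).
#' @return energy (kcal/mol).
#' @export
lj_pair_energy <- function(r, sigma_ij, eps_ij) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (sigma_ij / r)^6
  4 * eps_ij * (sr6 * sr6 - sr6)
}

#' Coulomb pair energy (truncated, no mean-field correction)
#'
#' k q_i q_j / r with k = 138.935458 kJ nm / (mol e^2) converted to
#' kcal/mol; unit charges at 1 nm give 33.206 kcal/mol.
#'
#' @param r distance (nm), > 0.
#' @param qi,qj charges (e).
#' @return energy (kcal/mol).
#' @export
coulomb_pair_energy <- function(r, qi, qj) {
  if (any(r <= 0)) stop("r must be > 0")
  COULOMB_KCAL * qi * qj / r
}

# Combined LJ parameters for two parameter vectors under a combination rule.
combine_lj <- function(sig_a, sig_b, eps_a, eps_b,
                       rule = c("lorentz-berthelot", "geometric")) {
  rule <- match.arg(rule)
  if (rule == "lorentz-berthelot") {
    list(sigma = outer(sig_a, sig_b, function(x, y) (x + y) / 2),
         eps = sqrt(outer(eps_a, eps_b)))
  } else {
    list(sigma = sqrt(outer(sig_a, sig_b)), eps = sqrt(outer(eps_a, eps_b)))
  }
}

# Look up sigma/epsilon for atoms by lj_type in a nonbonded_params object.
lookup_lj <- function(topology, idx, params) {
  types <- topology$lj_type[idx]
  known <- names(params$species)
  bad <- setdiff(unique(types), known)
  if (length(bad) > 0) {
    stop(sprintf("no nonbonded parameters for type(s): %s",
                 paste(bad, collapse = ", ")))
  }
  list(sigma = vapply(types, function(t) params$species[[t]]$sigma, 1),
       eps = vapply(types, function(t) params$species[[t]]$epsilon, 1))
}

#' Group-group nonbonded interaction energy with per-residue decomposition
#'
#' Sums truncated LJ and Coulomb pair terms over all cross pairs within the
#' cutoff (default 1.0 nm, the vdW cutoff of the simulations this mirrors;
#' minimum image when the frame carries a box). Cross parameters follow the
#' stored combination rule (default Lorentz-Berthelot). Electrostatics are
#' plain truncated Coulomb — interaction energies on stored frames, not
#' forces for dynamics — with an optional reaction-field correction
#' (`rf_epsilon`) for the dielectric beyond the cutoff. Per-residue maps
#' (keyed by `group_a` residue ids) partition the totals exactly.
#'
#' @param frame a frame.
#' @param topology the matching topology (charges and `lj_type` required).
#' @param group_a,group_b disjoint atom index sets; per-residue terms are
#'   attributed to `group_a` residues.
#' @param params a [nonbonded_params()].
#' @param rc cutoff (nm).
#' @param rf_epsilon reaction-field dielectric (e.g. 78.5 for water), or
#'   `NULL` for plain truncation.
#' @return list of class `"energy_breakdown"`: `E_vdw`, `E_elec` (kcal/mol),
#'   `per_residue_vdw`, `per_residue_elec` (named numeric vectors), `rc`,
#'   `time_ps`.
#' @export
interaction_energy <- function(frame, topology, group_a, group_b,
                               params = read_nonbonded_params(), rc = 1.0,
                               rf_epsilon = NULL) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("groups must be non-empty")
  }
  lj_a <- lookup_lj(topology, group_a, params)
  lj_b <- lookup_lj(topology, group_b, params)
  comb <- combine_lj(lj_a$sigma, lj_b$sigma, lj_a$eps, lj_b$eps,
                     rule = params$combination_rule)
  d <- pair_distances(frame$xyz[group_a, , drop = FALSE],
                      frame$xyz[group_b, , drop = FALSE], box = frame$box)
  within <- d <= rc & d > 0
  sr6 <- matrix(0, nrow(d), ncol(d))
  sr6[within] <- (comb$sigma[within] / d[within])^6
  e_vdw_mat <- 4 * comb$eps * (sr6 * sr6 - sr6)
  qq <- outer(topology$charge[group_a], topology$charge[group_b])
  e_elec_mat <- matrix(0, nrow(d), ncol(d))
  if (is.null(rf_epsilon)) {
    e_elec_mat[within] <- COULOMB_KCAL * qq[within] / d[within]
  } else {
    # Reaction field: E = k q q (1/r + k_rf r^2 - c_rf), zero at r = rc.
    k_rf <- (rf_epsilon - 1) / ((2 * rf_epsilon + 1) * rc^3)
    c_rf <- 1 / rc + k_rf * rc^2
    e_elec_mat[within] <- COULOMB_KCAL * qq[within] *
      (1 / d[within] + k_rf * d[within]^2 - c_rf)
  }
  res_a <- topology$resid[group_a]
  per_vdw <- tapply(rowSums(e_vdw_mat), res_a, sum)
  per_elec <- tapply(rowSums(e_elec_mat), res_a, sum)
  structure(list(E_vdw = sum(e_vdw_mat), E_elec = sum(e_elec_mat),
                 per_residue_vdw = per_vdw[order(as.integer(names(per_vdw)))],
                 per_residue_elec = per_elec[order(as.integer(names(per_elec)))],
                 rc = rc, time_ps = frame$time_ps),
            class = "energy_breakdown")
}

#' Interaction-energy time series over a trajectory
#'
#' One [interaction_energy()] evaluation per frame.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b,params,rc,rf_epsilon as in [interaction_energy()].
#' @return list of class `"energy_series"`: `summary` data.frame (time_ns,
#'   E_vdw, E_elec) and `per_residue_vdw` / `per_residue_elec` matrices
#'   (frames x residues, columns named by residue id).
#' @export
energy_series <- function(traj, group_a, group_b,
                          params = read_nonbonded_params(), rc = 1.0,
                          rf_epsilon = NULL) {
  per_frame <- lapply(seq_len(n_frames(traj)), function(i) {
    interaction_energy(traj_frame(traj, i), traj$topology, group_a, group_b,
                       params = params, rc = rc, rf_epsilon = rf_epsilon)
  })
  summary <- data.frame(
    time_ns = traj$times_ps / 1000,
    E_vdw = vapply(per_frame, `[[`, 1, "E_vdw"),
    E_elec = vapply(per_frame, `[[`, 1, "E_elec")
  )
  res_ids <- names(per_frame[[1]]$per_residue_vdw)
  stack <- function(field) {
    m <- do.call(rbind, lapply(per_frame, function(e) as.numeric(e[[field]])))
    colnames(m) <- res_ids
    m
  }
  structure(list(summary = summary, per_residue_vdw = stack("per_residue_vdw"),
                 per_residue_elec = stack("per_residue_elec"), rc = rc),
            class = "energy_series")
}

#' Tail average of a time series with block-averaged uncertainty
#'
#' Mean over the trailing `window_ns` of the series (the convention for
#' quoting converged interaction energies, e.g. "averaged over the last
#' 100 ns"); the uncertainty is the standard error of `n_blocks` block
#' means over that window, recorded in the estimator tag.
#'
#' @param time_ns frame times (ns).
#' @param values series values.
#' @param window_ns trailing window length (ns).
#' @param n_blocks number of blocks for the error estimate.
#' @return list of class `"tail_average"`: `mean`, `uncertainty`,
#'   `window_ns`, `n`, `estimator`.
#' @export
tail_average <- function(time_ns, values, window_ns = 100, n_blocks = 5L) {
  stopifnot(length(time_ns) == length(values))
  span <- max(time_ns) - min(time_ns)
  if (window_ns > span + 1e-9) {
    stop(sprintf("window (%g ns) exceeds trajectory span (%g ns)",
                 window_ns, span))
  }
  keep <- which(time_ns >= max(time_ns) - window_ns - 1e-9)
  v <- values[keep]
  blocks <- split(v, cut(seq_along(v), breaks = n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, 1)
  unc <- if (length(bm) > 1) stats::sd(bm) / sqrt(length(bm)) else 0
  structure(list(mean = mean(v), uncertainty = unc, window_ns = window_ns,
                 n = length(v),
                 estimator = sprintf("block-averaged standard error (%d blocks)",
                                     n_blocks)),
            class = "tail_average")
}

#' Residues with tail-averaged energies below a threshold
#'
#' The favorable-residue filter: residues whose mean interaction energy is
#' below `threshold` (default -20 kcal/mol, negative = attractive), sorted
#' ascending (most favorable first).
#'
#' @param per_residue_means named numeric vector (residue id -> kcal/mol).
#' @param threshold energy threshold (kcal/mol).
#' @return data.frame `resid`, `energy`, sorted ascending by energy.
#' @export
favorable_residues <- function(per_residue_means, threshold = -20) {
  sel <- per_residue_means[!is.na(per_residue_means) &
                             per_residue_means < threshold]
  sel <- sort(sel)
  data.frame(resid = as.integer(names(sel)), energy = as.numeric(sel))
}
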