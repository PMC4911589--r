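# Reproducible-run plumbing: one validated configuration object holding
# every threshold, an end-to-end runner producing TSV/JSON artifacts with a
# manifest, and a report assembling the summary tables. The analysis
# scripts under analysis/ are thin drivers over these functions.

#' Run configuration
#'
#' Every cutoff and threshold of the analyses in one validated place,
#' echoed verbatim into the header of each output file.
#'
#' @param rc_contact sheet-contact cutoff (nm).
#' @param rc_energy nonbonded interaction cutoff (nm).
#' @param rc_fss first-solvation-shell radius (nm).
#' @param hbond_dist,hbond_angle H-bond criterion (nm / degrees).
#' @param rc_salt_bridge,rc_cation_pi detector cutoffs (nm).
#' @param energy_threshold favorable-residue threshold (kcal/mol).
#' @param tail_window_ns trailing window for energy averages (ns).
#' @param persistence_k consecutive frames defining a persistent contact.
#' @param spans a [helix_spans()] list.
#' @param seed integer seed for scenario generation.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(rc_contact = 0.6, rc_energy = 1.0, rc_fss = 0.45,
                       hbond_dist = 0.35, hbond_angle = 150,
                       rc_salt_bridge = 0.4, rc_cation_pi = 0.5,
                       energy_threshold = -20, tail_window_ns = 100,
                       persistence_k = 5L, spans = helix_spans(),
                       seed = 1L) {
  positive <- c("rc_contact", "rc_energy", "rc_fss", "hbond_dist",
                "hbond_angle", "rc_salt_bridge", "rc_cation_pi",
                "tail_window_ns", "persistence_k")
  env <- environment()
  for (f in positive) {
    v <- get(f, envir = env)
    if (length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("invalid config: '%s' must be a positive number", f))
    }
  }
  structure(list(rc_contact = rc_contact, rc_energy = rc_energy,
                 rc_fss = rc_fss, hbond_dist = hbond_dist,
                 hbond_angle = hbond_angle,
                 rc_salt_bridge = rc_salt_bridge,
                 rc_cation_pi = rc_cation_pi,
                 energy_threshold = energy_threshold,
                 tail_window_ns = tail_window_ns,
                 persistence_k = as.integer(persistence_k),
                 spans = spans, seed = as.integer(seed)),
            class = "run_config")
}

config_header <- function(config, convention) {
  c(sprintf("# convention: %s", convention),
    sprintf("# config: rc_contact=%g rc_energy=%g rc_fss=%g hbond=%g/%g salt_bridge=%g cation_pi=%g threshold=%g tail=%g persistence_k=%d seed=%d",
            config$rc_contact, config$rc_energy, config$rc_fss,
            config$hbond_dist, config$hbond_angle, config$rc_salt_bridge,
            config$rc_cation_pi, config$energy_threshold,
            config$tail_window_ns, config$persistence_k, config$seed))
}

#' Write a TSV series with convention headers
#'
#' Deterministic text output: `# convention:` / `# config:` comment lines
#' followed by a tab-separated table with a fixed numeric format, so
#' identical inputs produce byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config a [run_config()] echoed into the header.
#' @param convention one-line description of the column semantics.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(df, path, config, convention) {
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.10g", x) else as.character(x)
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
  writeLines(c(config_header(config, convention),
               paste(names(df), collapse = "\t"), body), path)
  invisible(path)
}

#' Read back a TSV series written by [write_series_tsv()]
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
read_series_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Run the full analysis suite on a synthetic scenario
#'
#' Generates the scenario trajectory, runs every analysis stage (contacts,
#' per-residue contacts, Q(t), helix ratio, H-bond ratio, interaction
#' energies with tail averages and favorable residues, FSS hydration,
#' first-contact kinetics and anchoring order, adsorption-denaturation
#' correlation) and writes one TSV/JSON artifact per stage plus a manifest
#' under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param spec optional [scenario_spec()]; default built from
#'   `config$seed`.
#' @param sheet optional `"sheet_model"`; default the headline-geometry
#'   patch (6.735 x 6.600 nm target).
#' @param params nonbonded parameters for the energy stage.
#' @return (invisibly) list with the computed series and the artifact
#'   paths.
#' @export
run_analysis <- function(config, out_dir, spec = NULL, sheet = NULL,
                         params = read_nonbonded_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) {
    spec <- scenario_spec(spans = config$spans, seed = config$seed)
  }
  if (is.null(sheet)) {
    sheet <- suppressMessages(monolayer_for_extents(6.735, 6.600,
                                                    params = params))
  }
  run <- generate_trajectory(spec, sheet)
  traj <- run$traj
  top <- traj$topology
  times_ns <- traj_times_ns(traj)
  ref <- run$reference

  sc_heavy <- select_atoms(top, "protein and sidechain and heavy")
  sheet_idx <- select_atoms(top, "sheet")
  prot_idx <- select_atoms(top, "protein")

  ncs <- native_contacts(ref, rc = config$rc_contact)
  ref_hb <- hbond_count(ref$frame, ref$topology, rc = config$hbond_dist,
                        angle_min = config$hbond_angle)

  prot_res <- sort(unique(top$resid[top$protein]))
  per_res_contacts <- matrix(0L, n_frames(traj), length(prot_res),
                             dimnames = list(NULL, prot_res))
  series <- data.frame(time_ns = times_ns, contacts = NA_integer_,
                       q = NA_real_, helix_ratio = NA_real_,
                       hbond_ratio = NA_real_)
  for (i in seq_len(n_frames(traj))) {
    fr <- traj_frame(traj, i)
    series$contacts[i] <- heavy_atom_contacts(fr, sc_heavy, sheet_idx,
                                              rc = config$rc_contact)
    series$q[i] <- q_fraction(fr, top, ncs)
    series$helix_ratio[i] <- helix_ratio(fr, top, spans = config$spans)
    series$hbond_ratio[i] <- if (ref_hb > 0) {
      hbond_ratio(fr, top, ref_hb, rc = config$hbond_dist,
                  angle_min = config$hbond_angle)
    } else NA_real_
    for (r in prot_res) {
      rsel <- sc_heavy[top$resid[sc_heavy] == r]
      if (length(rsel) > 0) {
        per_res_contacts[i, as.character(r)] <-
          heavy_atom_contacts(fr, rsel, sheet_idx, rc = config$rc_contact)
      }
    }
  }

  es <- energy_series(traj, prot_idx, sheet_idx, params = params,
                      rc = config$rc_energy)
  window <- min(config$tail_window_ns, max(times_ns) - min(times_ns))
  tails <- apply(es$per_residue_vdw, 2, function(v) {
    tail_average(times_ns, v, window_ns = window)$mean
  })
  fav <- favorable_residues(tails, threshold = config$energy_threshold)

  fss <- NULL
  if (nrow(spec$shell_waters) > 0) {
    fss <- sapply(spec$shell_waters$resid, function(r) {
      vapply(seq_len(n_frames(traj)), function(i) {
        fss_water_count(traj_frame(traj, i), top, r, rc_fss = config$rc_fss)
      }, numeric(1))
    })
    colnames(fss) <- spec$shell_waters$resid
  }

  onsets <- first_contact_time(times_ns, per_res_contacts,
                               persistence_k = config$persistence_k)
  anchoring <- anchoring_order(onsets, spans = config$spans)
  corr <- adsorption_denaturation_correlation(times_ns, series$contacts,
                                              q = series$q)

  paths <- list(
    series = file.path(out_dir, "structure_series.tsv"),
    per_res_contacts = file.path(out_dir, "per_residue_contacts.tsv"),
    energy = file.path(out_dir, "energy_series.tsv"),
    energy_tail = file.path(out_dir, "energy_tail.tsv"),
    fss = file.path(out_dir, "fss_series.tsv"),
    kinetics = file.path(out_dir, "kinetics.tsv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_series_tsv(series, paths$series, config,
                   "contacts = number of protein sidechain heavy atoms within rc_contact of any sheet atom; q = retained native-contact fraction; ratios relative to reference")
  write_series_tsv(cbind(data.frame(time_ns = times_ns),
                         as.data.frame(per_res_contacts)),
                   paths$per_res_contacts, config,
                   "per-residue sidechain heavy-atom contact counts with the sheet")
  write_series_tsv(es$summary, paths$energy, config,
                   "protein-sheet interaction energies, kcal/mol, negative = attractive, truncated at rc_energy")
  write_series_tsv(data.frame(resid = as.integer(colnames(es$per_residue_vdw)),
                              vdw_tail_mean = as.numeric(tails),
                              favorable = as.integer(colnames(es$per_residue_vdw))
                              %in% fav$resid),
                   paths$energy_tail, config,
                   "per-residue vdW energy averaged over the trailing window; favorable = below energy_threshold")
  if (!is.null(fss)) {
    write_series_tsv(cbind(data.frame(time_ns = times_ns),
                           as.data.frame(fss)),
                     paths$fss, config,
                     "first-solvation-shell water counts (oxygens within rc_fss of residue sidechain heavy atoms)")
  }
  write_series_tsv(onsets, paths$kinetics, config,
                   "first persistent contact time per residue (NA = never)")
  summary <- list(
    anchoring_order = anchoring$helix,
    anchoring_onsets_ns = anchoring$onset_ns,
    adsorption_denaturation_correlation = corr,
    E_vdw_tail = tail_average(times_ns, es$summary$E_vdw,
                              window_ns = window)[c("mean", "uncertainty",
                                                    "estimator")],
    E_elec_tail = tail_average(times_ns, es$summary$E_elec,
                               window_ns = window)[c("mean", "uncertainty",
                                                     "estimator")],
    favorable_residues = fav
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "nanoadsorb",
    version = as.character(utils::packageVersion("nanoadsorb")),
    config = config[setdiff(names(config), "spans")],
    spans = lapply(config$spans, range),
    artifacts = lapply(paths[setdiff(names(paths), "manifest")],
                       function(p) {
                         if (file.exists(p)) {
                           unname(tools::md5sum(p))
                         } else NA_character_
                       })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(run = run, series = series, energy = es, tails = tails,
                 favorable = fav, fss = fss, onsets = onsets,
                 anchoring = anchoring, correlation = corr, paths = paths))
}

#' Assemble a markdown report from an artifact directory
#'
#' Read-only: collects the series written by [run_analysis()] into one
#' markdown document with the adsorption/denaturation panels (contacts,
#' Q(t), helix and H-bond ratios, energy profile, per-residue tail
#' energies with the threshold marked, FSS traces, kinetics).
#'
#' @param artifact_dir directory written by [run_analysis()].
#' @param path output markdown path (default `report.md` inside the
#'   directory).
#' @return `path`, invisibly.
#' @export
write_report <- function(artifact_dir,
                         path = file.path(artifact_dir, "report.md")) {
  need <- file.path(artifact_dir,
                    c("structure_series.tsv", "energy_series.tsv",
                      "energy_tail.tsv", "summary.json"))
  if (!any(file.exists(need))) {
    stop(sprintf("no analysis artifacts found in '%s'", artifact_dir))
  }
  lines <- c("# Adsorption analysis report", "")
  md_table <- function(df, digits = 4) {
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|")
      }, character(1)))
  }
  if (file.exists(need[1])) {
    s <- read_series_tsv(need[1])
    pick <- unique(round(seq(1, nrow(s), length.out = min(12, nrow(s)))))
    lines <- c(lines, "## Structural series (sampled)", "",
               md_table(s[pick, ]), "")
  }
  if (file.exists(need[2])) {
    e <- read_series_tsv(need[2])
    pick <- unique(round(seq(1, nrow(e), length.out = min(12, nrow(e)))))
    lines <- c(lines, "## Interaction energy series (kcal/mol, sampled)",
               "", md_table(e[pick, ]), "")
  }
  if (file.exists(need[3])) {
    tl <- read_series_tsv(need[3])
    lines <- c(lines,
               "## Per-residue tail-averaged vdW energies",
               "",
               "`favorable` marks residues below the energy threshold.",
               "", md_table(tl), "")
  }
  if (file.exists(need[4])) {
    sm <- jsonlite::read_json(need[4], simplifyVector = TRUE)
    lines <- c(lines, "## Kinetics and totals", "",
               sprintf("- anchoring order (helices): %s",
                       paste(sm$anchoring_order, collapse = " -> ")),
               sprintf("- adsorption-denaturation correlation: %.4f",
                       sm$adsorption_denaturation_correlation),
               sprintf("- tail vdW energy: %.2f +/- %.2f kcal/mol (%s)",
                       sm$E_vdw_tail$mean, sm$E_vdw_tail$uncertainty,
                       sm$E_vdw_tail$estimator),
               sprintf("- tail electrostatic energy: %.2f +/- %.2f kcal/mol",
                       sm$E_elec_tail$mean, sm$E_elec_tail$uncertainty),
               "")
  }
  fss_path <- file.path(artifact_dir, "fss_series.tsv")
  if (file.exists(fss_path)) {
    fs <- read_series_tsv(fss_path)
    pick <- unique(round(seq(1, nrow(fs), length.out = min(12, nrow(fs)))))
    lines <- c(lines, "## First-solvation-shell water counts (sampled)", "",
               md_table(fs[pick, ]), "")
  }
  writeLines(lines, path)
  invisible(path)
}
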