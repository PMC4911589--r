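#!/usr/bin/env Rscript
# Step 6: interfacial hydration and adsorption kinetics: per-residue
# first-solvation-shell water counts, first persistent contact times,
# helix anchoring order, and the adsorption-denaturation correlation.
#
# Finding: shell waters around the tracked aromatic drop 18 -> 6 on
# face-down adsorption (nanoscale drying) while the basic residue retains
# more of its shell (18 -> 12); helices anchor in the programmed order
# 2 -> 1 -> 3; the contact count correlates strongly (> 0.9) with
# native-contact loss.

suppressPackageStartupMessages(library(nanoadsorb))
dir.create("results", showWarnings = FALSE)
seed <- 42L

cfg <- run_config(seed = seed, tail_window_ns = 5)
sheet <- monolayer_for_extents(6.735, 6.600)
run <- generate_trajectory(scenario_spec(seed = seed), sheet)
traj <- run$traj; top <- traj$topology
times_ns <- traj_times_ns(traj)

# FSS traces for the tracked residues
targets <- run$spec$shell_waters$resid
fss <- sapply(targets, function(r) {
  vapply(seq_len(n_frames(traj)), function(i) {
    fss_water_count(traj_frame(traj, i), top, r, rc_fss = cfg$rc_fss)
  }, integer(1))
})
colnames(fss) <- targets
write_series_tsv(cbind(data.frame(time_ns = times_ns), as.data.frame(fss)),
                 "results/fss_series.tsv", cfg,
                 "first-solvation-shell water counts (oxygens within rc_fss of residue sidechain heavy atoms)")
for (r in targets) {
  cat(sprintf("residue %d: %d shell waters in bulk -> %d after adsorption\n",
              r, fss[1, as.character(r)],
              fss[nrow(fss), as.character(r)]))
}

# kinetics: per-residue contact series -> onsets -> anchoring order
sc <- select_atoms(top, "protein and sidechain and heavy")
sh <- select_atoms(top, "sheet")
prot_res <- sort(unique(top$resid[top$protein]))
cm <- sapply(prot_res, function(r) {
  rs <- sc[top$resid[sc] == r]
  if (length(rs) == 0) return(integer(n_frames(traj)))
  vapply(seq_len(n_frames(traj)), function(i) {
    heavy_atom_contacts(traj_frame(traj, i), rs, sh, rc = cfg$rc_contact)
  }, integer(1))
})
colnames(cm) <- prot_res
onsets <- first_contact_time(times_ns, cm, persistence_k = cfg$persistence_k)
write_series_tsv(onsets, "results/kinetics.tsv", cfg,
                 "first persistent contact time per residue (NA = never)")
anch <- anchoring_order(onsets, spans = cfg$spans)
cat(sprintf("anchoring order: %s\n", paste(anch$helix, collapse = " -> ")))

# adsorption vs denaturation
ncs <- native_contacts(run$reference, rc = cfg$rc_contact)
qv <- vapply(seq_len(n_frames(traj)), function(i) {
  q_fraction(traj_frame(traj, i), top, ncs)
}, 1)
contacts <- vapply(seq_len(n_frames(traj)), function(i) {
  heavy_atom_contacts(traj_frame(traj, i), sc, sh, rc = cfg$rc_contact)
}, integer(1))
corr <- adsorption_denaturation_correlation(times_ns, contacts, q = qv)
cat(sprintf("adsorption-denaturation correlation: %.3f\n", corr))
jsonlite::write_json(list(anchoring = anch, correlation = corr),
                     "results/kinetics_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/fss_series.tsv, results/kinetics.tsv, results/kinetics_summary.json\n")
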