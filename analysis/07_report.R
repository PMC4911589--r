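#!/usr/bin/env Rscript
# Step 7: run the packaged end-to-end pipeline (same config and seed as
# steps 3-6) into one artifact directory with a manifest, and assemble the
# markdown report.

suppressPackageStartupMessages(library(nanoadsorb))
seed <- 42L

cfg <- run_config(seed = seed, tail_window_ns = 5)
sheet <- monolayer_for_extents(6.735, 6.600)
res <- run_analysis(cfg, "results/pipeline", spec = scenario_spec(seed = seed),
                    sheet = sheet)
path <- write_report("results/pipeline")
cat(sprintf("report: %s\n", path))
cat(readLines(file.path("results/pipeline", "summary.json")), sep = "\n")
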