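#!/usr/bin/env Rscript
# Stage 5: one-shot report bundle.
#
# Re-runs the whole pipeline through run_pipeline() at the same master seed
# the staged scripts use, and writes every machine table plus the
# human-readable report into results/report/. This is the single-command
# equivalent of stages 1-4 and doubles as a determinism check: the tables
# it emits match the staged outputs.

suppressPackageStartupMessages(library(mangroveBiomass))

cfg <- pipeline_config(seed = 20230701L, n_sites = 3L)
bundle <- run_pipeline(cfg)
write_report_bundle(bundle, "results/report")

print(bundle)
cat("\nFull tables written under results/report/\n")
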