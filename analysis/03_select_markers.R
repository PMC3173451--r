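#!/usr/bin/env Rscript
# Marker selection: dual-monophyly coherence (mitochondria monophyletic and
# the alphaproteobacterial clade monophyletic) on per-marker reference
# trees, plus FYMINK/GARP composition-bias diagnostics.
source("analysis/00_common.R")

run_stage("select-markers", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
rep <- read.delim(file.path(ANALYSIS_OUT, "marker_report.tsv"),
                  comment.char = "#")
print(rep)
message(sprintf("%d of %d markers pass the coherence criterion",
                sum(rep$pass), nrow(rep)))
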