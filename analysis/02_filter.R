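#!/usr/bin/env Rscript
# Staged homology filtering: seed->orthologous-group assignment, candidate
# retrieval (E-value < 1e-10, overlap > 50%), reciprocal same-group
# confirmation (overlap > 70%), and the >500-sequence dataset gate.
source("analysis/00_common.R")

run_stage("filter", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
rep <- read.delim(file.path(ANALYSIS_OUT, "filter_report.tsv"),
                  comment.char = "#")
print(rep)
message(sprintf("retained %d of %d candidate sequences across %d markers",
                sum(rep$n_retained), sum(rep$n_candidates), nrow(rep)))
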