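#!/usr/bin/env Rscript
# Diversity pruning: greedy maximum-PD selection (k = 150 by default,
# reference taxa as must-keep) on per-marker guide trees, reducing each
# environmental pool to a tractable, maximally diverse subset.
source("analysis/00_common.R")

run_stage("prune", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
rep <- read.delim(file.path(ANALYSIS_OUT, "prune_report.tsv"),
                  comment.char = "#")
print(rep)
message(sprintf("pruned selections retain %.1f%% of total tree length on average",
                mean(100 * rep$pd / rep$total_bl)))
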