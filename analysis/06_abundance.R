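#!/usr/bin/env Rscript
# Clade abundance: assign environmental leaves to reference orders on a
# rooted marker tree, report clade fractions, the rare-clade fraction of
# the screen's flagged set, and overall abundance under the 32.5%
# alphaproteobacterial-cells assumption.
source("analysis/00_common.R")

run_stage("abundance", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
rep <- read.delim(file.path(ANALYSIS_OUT, "abundance_report.tsv"),
                  comment.char = "#")
print(rep)
message("dominant-clade and rare-clade fractions written to abundance_report.tsv")
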