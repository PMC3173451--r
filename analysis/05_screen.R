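#!/usr/bin/env Rscript
# The jack-knife neighbour screen: per marker, 20 replicates of 100
# sequences drawn with replacement, NJ trees over sample + reference,
# extraction of environmental sequences inside or sister to the
# mitochondrial clade, then scaffold-based concatenation of flagged
# sequences with >= 2 genes.
source("analysis/00_common.R")

run_stage("screen", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
rep <- read.delim(file.path(ANALYSIS_OUT, "screen_report.tsv"),
                  comment.char = "#")
print(rep)
flagged <- readLines(file.path(ANALYSIS_OUT, "flagged_ids.txt"))
truth <- read.delim(file.path(ANALYSIS_OUT, "truth.tsv"), comment.char = "#")
tp <- sum(flagged %in% truth$seqid[truth$planted])
message(sprintf("flagged %d sequences; %d/%d planted recovered (precision %.2f)",
                length(flagged), tp, sum(truth$planted),
                tp / max(1, length(flagged))))
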