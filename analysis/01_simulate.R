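#!/usr/bin/env Rscript
# Generate the labelled synthetic metagenome: reference phylogeny with the
# mitochondrial clade sister to the Rickettsiales, a rare planted clade on
# the mitochondrial stem, a SAR11-dominated environmental pool of 1000 gene
# sequences on 1-3 gene scaffolds, and emulated hit tables.
source("analysis/00_common.R")

run_stage("simulate", analysis_config(), out_dir = ANALYSIS_OUT,
          seed = ANALYSIS_SEED)
truth <- read.delim(file.path(ANALYSIS_OUT, "truth.tsv"), comment.char = "#")
message(sprintf("simulated %d environmental gene sequences (%d planted) on %d scaffolds",
                nrow(truth), sum(truth$planted),
                length(unique(truth$organism))))
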