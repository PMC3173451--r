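# Shared setup for the numbered analysis drivers. Every driver is a thin
# wrapper over the package's run_stage(); all computation lives in the
# package so it is exercised by the test suite.
suppressMessages(library(mitoscreen))

ANALYSIS_SEED <- as.integer(Sys.getenv("MS_SEED", "1"))
ANALYSIS_OUT <- Sys.getenv("MS_OUT", "results/run")

analysis_config <- function() {
  pipeline_config(
    sim = sim_config(),                       # default study conditions
    screen = screen_config(sample_size = 100L, replicates = 20L))
}
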