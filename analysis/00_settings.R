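# Shared settings for the analysis scripts: one configuration, one seed.
# Every script regenerates what it needs from this configuration (the
# simulator is deterministic given the seed), so each stage can be re-run
# on its own.
library(mqtlsmoke)

config <- sim_config()   # two-panel cohort at the study scale (581 / 368)
results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
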