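#!/usr/bin/env Rscript
# Thin command-line wrapper around the package pipeline: simulate a
# paired dry/gel cohort and run the complete comparison, writing result
# tables and a run manifest.
#
# Usage:
#   Rscript scripts/run_pipeline.R [--seed <int>] [--out <dir>]
#                                  [--n-subjects <int>] [--reduced]
#
# --reduced lowers the sample rate, trial counts and grid resolution for
# a fast desk-scale run; without it the study-scale defaults are used.

suppressPackageStartupMessages(library(eegcompare))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1, out = "results/pipeline", n_subjects = 15,
            reduced = FALSE)
i <- 1
while (i <= length(args)) {
  switch(args[i],
         "--seed" = { opt$seed <- as.integer(args[i + 1]); i <- i + 2 },
         "--out" = { opt$out <- args[i + 1]; i <- i + 2 },
         "--n-subjects" = { opt$n_subjects <- as.integer(args[i + 1]); i <- i + 2 },
         "--reduced" = { opt$reduced <- TRUE; i <- i + 1 },
         { message("unknown argument: ", args[i]); quit(status = 2) })
}

sim <- if (opt$reduced) {
  sim_config(n_subjects = opt$n_subjects, sample_rate = 256,
             check_n_reversals = 60, assr_n_trials = 6, eoec_n_cycles = 6,
             seed = opt$seed)
} else {
  sim_config(n_subjects = opt$n_subjects, seed = opt$seed)
}
cfg <- pipeline_config(sim = sim,
                       grid_resolution = if (opt$reduced) 24 else 66,
                       out_dir = opt$out, seed = opt$seed)
bundle <- tryCatch(run_pipeline(cfg), error = function(e) {
  message("pipeline failed: ", conditionMessage(e)); quit(status = 3)
})
generate_report(bundle)
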