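# Shared settings for the analysis scripts: one master seed, one output tree.
# Each numbered script is a thin driver over the kinsub package; all
# computation lives in the package and is covered by its test suite.

suppressPackageStartupMessages(library(kinsub))

MASTER_SEED <- 42
OUT <- "results"
dir.create(file.path(OUT, "sim"), recursive = TRUE, showWarnings = FALSE)

# study conditions: the default simulated experiment used throughout the
# workflow (5 + 5 replicates, two starvation timepoints, planted targets
# with mixed kinetics, MNAR + MCAR missingness, planted consensus motifs)
study_config <- function(seed = MASTER_SEED) {
  sim_config(n_proteins = 500, sites_per_protein = 4, n_targets = 200,
             effect_size_mean = 2, effect_size_sd = 0.5,
             inhibitor_attenuation = 0.1,
             kinetic_mix = c(early = 0.2, sustained = 0.6, late = 0.2),
             noise_sd = 0.5, replicate_tau = 0.3,
             prop_direct = 0.8, motif_fidelity = c(0.9, 0.9, 0.8),
             seed = seed)
}
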