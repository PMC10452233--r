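# Shared configuration for the numbered analysis scripts. Each script runs
# one or more pipeline stages against the same run directory, so cached
# stages carry over from script to script.

library(pecnet)

RUN_DIR <- "scratch/pipeline_run"
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# Desk-scale study: three groups of six subjects, 12 cortical ROIs with two
# dipoles each seen by 24 sensors, beta-band task epochs. Four planted
# envelope couplings (rho = 0.7) are strongly reduced in the CS group and
# moderately reduced in SS, emulating lesion-dependent network breakdown.
study_config <- function(seed = 42L) {
  pipeline_config(
    sim = list(
      n_subjects_per_group = 6L, groups = c("HC", "CS", "SS"),
      n_sensors = 24L, n_rois = 12L, dipoles_per_roi = 2L,
      fs = 256, n_epochs = 30L, band = c(13, 30),
      coupling_spec = data.frame(roi_i = c(1, 3, 5, 7),
                                 roi_j = c(2, 4, 6, 8),
                                 rho = 0.7),
      group_effects = list(CS = list(edges = 1:4, rho_scale = 0.3),
                           SS = list(edges = 1:4, rho_scale = 0.6)),
      snr = 5),
    band = c(13, 30), density = 0.25, n_random = 50L,
    classify_groups = c("HC", "CS"),
    fs_methods = c("Corr", "Fisher", "Relief", "LARS"),
    classifiers = c("LR", "Boost", "Tree", "RF"),
    feature_grid = c(1, 2, 4, 8, 16, 32, 66),
    seed = seed)
}
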