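# Shared fixture builders; everything generated in code, fully seeded.

# Simulate a cohort and run it through normalization to fold changes.
sim_fc <- function(seed, n_features = 60, planted = TRUE) {
  cfg <- sim_config(
    n_features = n_features,
    planted = if (planted) default_planted_truth(n_features) else NULL,
    seed = seed
  )
  cohort <- simulate_cohort(cfg)
  kept <- prefilter_features(cohort$counts)
  fc <- log2fc_baseline(cpm_matrix(kept, tmm_factors(kept)), cohort$metadata)
  list(cohort = cohort, kept = kept, fc = fc, truth = cohort$planted)
}

# Minimal balanced two-group metadata for direct ANOVA checks: n_per
# animals per dose group x sex x survival cell, three post timepoints.
toy_meta <- function(doses = c(6, 7), n_per = 2) {
  grid <- expand.grid(dose_gy = doses, sex = c("M", "F"),
                      survived = c(TRUE, FALSE), rep = seq_len(n_per),
                      stringsAsFactors = FALSE)
  grid$animal_id <- sprintf("T%02d", seq_len(nrow(grid)))
  meta <- merge(grid, data.frame(timepoint = c("d1", "d2", "d6"),
                                 day = c(1, 2, 6)), by = NULL)
  meta$sample_id <- paste(meta$animal_id, meta$timepoint, sep = "_")
  meta[order(meta$animal_id, meta$day),
       c("sample_id", "animal_id", "dose_gy", "timepoint", "day", "sex",
         "survived")]
}
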