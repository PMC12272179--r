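#!/usr/bin/env Rscript
# Generate the synthetic cohort and write it to disk: per-run TSV tables, a
# JSON manifest, and the ground-truth archive (couplings, support graph,
# shared responses, coordinates). Prints a short summary of what was made.

source(file.path("analysis", "00_setup.R"))

cohort <- generate_cohort(cohort_cfg)
write_cohort(cohort, COHORT_DIR)

subjects <- unique(vapply(cohort$runs, function(r) r$subject, character(1)))
radii <- vapply(cohort$truth$couplings, companion_spectral_radius, numeric(1))

cat(sprintf("cohort written to %s\n", COHORT_DIR))
cat(sprintf("  %d runs (%d subjects x %d conditions), %d x %d each\n",
            length(cohort$runs), length(subjects),
            length(cohort_cfg$n_runs_per_condition),
            cohort_cfg$run_length, cohort_cfg$n_parcels))
cat(sprintf("  coupling support: %d edges (density %.3f)\n",
            sum(cohort$truth$support_graph) / 2,
            sum(cohort$truth$support_graph) /
              (cohort_cfg$n_parcels * (cohort_cfg$n_parcels - 1))))
cat(sprintf("  companion spectral radii: %s (target %.2f)\n",
            paste(sprintf("%.4f", radii), collapse = ", "),
            cohort_cfg$spectral_radius))
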