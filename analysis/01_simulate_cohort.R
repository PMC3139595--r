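#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 25 subjects x 3 scans x 30 ROIs in matrix mode, with equal between- and
# within-subject standard deviation (0.3 z-units) around a shared mean
# connectivity of 0.2 z-units -- so every connection has a known true ICC
# of 0.5. Writes one TSV per subject-scan plus a manifest.

library(trtnet)

out_dir <- "results/cohort"
cfg <- cohort_config(n_subjects = 25, n_scans = 3, n_rois = 30,
                     mu = 0.2, sigma_b = 0.3, sigma_w = 0.3, seed = 1L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out_dir)

truth <- ground_truth_icc(cfg)
cat(sprintf("wrote %d matrices to %s\n",
            cfg$n_subjects * cfg$n_scans, out_dir))
cat(sprintf("true connection ICC (all edges): %.3f\n",
            truth[1, 2]))
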