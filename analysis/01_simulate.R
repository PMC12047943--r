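#!/usr/bin/env Rscript
# Stage 1: simulate the two-arm consortium.
#
# Builds the sequencing-scale site universe with its array subset, the two
# platform reference panels, the gene catalog, and twelve cohorts (seven cord,
# five peripheral, one of them sequencing-based) with planted cell
# type-specific effects. Reports what was planted and how clean the generated
# matrices are.

source("analysis/00_common.R")

cons <- get_consortium()
cfg <- analysis_config()

say("Simulated %d cohorts over a %d-site universe (%d-site array subset).",
    length(cons$studies), cfg$panel$n_sites_seq, cfg$panel$n_sites_array)

cohort_tab <- do.call(rbind, lapply(names(cons$studies), function(id) {
  st <- cons$studies[[id]]
  data.frame(study_id = id, tissue = st$tissue, platform = st$platform,
             n_samples = st$sample_n, n_sites = nrow(st$sites),
             clip_fraction = signif(cons$truth[[id]]$clip_fraction, 3),
             mean_phenotype = signif(mean(st$phenotype_raw), 3))
}))
print(cohort_tab, row.names = FALSE)
say("Max clipped fraction across cohorts: %.3g (target < 0.01).",
    max(cohort_tab$clip_fraction))

n_rare <- sum(cons$panels$seq_like$sites$is_rare)
say("Planted %d rarely methylated sites (%.0f%% of the sequencing universe).",
    n_rare, 100 * n_rare / cfg$panel$n_sites_seq)
say("Planted %d cell type-specific effects:", nrow(cons$effects))
print(cons$effects[, c("site_id", "cell_type", "beta", "tissues")],
      row.names = FALSE)

write_result(cohort_tab, "01_cohorts.tsv", "# simulated cohort inventory")
write_result(cons$effects, "01_planted_effects.tsv",
             "# generator truth: planted effects")
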