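#!/usr/bin/env Rscript
# Stage 4: per-tissue Stouffer meta-analysis.
#
# Combines the per-cohort z-scores with sample-size weights separately for
# peripheral and cord blood, mapping the sequencing cohort's pooled CD3T
# T-cell results into both the CD4T and CD8T streams, with per-cell-type FDR
# control, heterogeneity tests, QQ/lambda diagnostics, and a leave-one-out
# check that peripheral findings survive removal of the sequencing cohort.

source("analysis/00_common.R")

cons <- get_consortium()
cfg <- analysis_config()
mw <- get_mwas()
meta <- get_meta()

for (ts in names(meta)) {
  tab <- meta[[ts]]$table
  sig <- tab[tab$q < 0.05, ]
  say("%s: %d records, %d significant at q<0.05; lambda by cell type:", ts,
      nrow(tab), nrow(sig))
  print(signif(meta[[ts]]$lambda, 3))
  planted_here <- cons$effects$site_id[
    grepl(ts, cons$effects$tissues)]
  say("  planted sites recovered among q<0.05: %d of %d",
      sum(unique(planted_here) %in% sig$site_id),
      length(unique(planted_here)))
  ord <- sig[order(sig$p), ]
  write_result(ord, sprintf("04_meta_%s_significant.tsv", ts),
               sprintf("# %s meta-analysis, q<0.05", ts))
  qd <- qq_diagnostics(tab$p)
  keep <- unique(round(seq(1, nrow(qd$table), length.out = 300)))
  write_result(qd$table[keep, ], sprintf("04_qq_%s.tsv", ts),
               sprintf("# QQ table, lambda=%.4f", qd$lambda))
}

## leave-one-out: drop the sequencing cohort from the peripheral arm
tissues <- vapply(mw, `[[`, "", "tissue")
loo <- leave_one_out(mw[tissues == "peripheral"], "GSMS_P",
                     study_order = cfg$study_order$peripheral,
                     analysis_label = "peripheral_wo_GSMS")
sig_full <- meta$peripheral$table[meta$peripheral$table$q < 0.05, ]
key <- paste(sig_full$site_id, sig_full$cell_type)
loo_rows <- loo$table[paste(loo$table$site_id, loo$table$cell_type) %in% key, ]
say("Leave-one-out (no sequencing cohort): %d of %d peripheral findings keep p<1e-4.",
    sum(loo_rows$p < 1e-4), nrow(sig_full))
write_result(loo_rows, "04_meta_peripheral_leave_one_out.tsv",
             "# peripheral findings re-combined without the sequencing cohort")
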