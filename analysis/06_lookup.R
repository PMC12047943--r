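#!/usr/bin/env Rscript
# Stage 6: cross-tissue look-up replication.
#
# Takes each arm's q<0.05 findings into the other arm: Bonferroni-corrects
# the target p over the available look-ups (per cell type), checks direction
# concordance, and asks -- with the continuity-corrected one-sample
# proportions test -- whether the number of replications exceeds the
# independence-null expectation.

source("analysis/00_common.R")

cons <- get_consortium()
meta <- get_meta()

for (pair in list(c("peripheral", "cord"), c("cord", "peripheral"))) {
  lab <- paste(pair, collapse = "_to_")
  lk <- lookup_sites(meta[[pair[1]]], meta[[pair[2]]])
  if (nrow(lk) == 0L) { say("%s: no discovery-significant sites.", lab); next }
  say("%s: %d looked up, %d available in target, %d Bonferroni-significant, %d concordant.",
      lab, nrow(lk), sum(lk$available), sum(lk$significant, na.rm = TRUE),
      sum(lk$direction_concordant, na.rm = TRUE))
  shared <- cons$effects$site_id[cons$effects$tissues == "cord,peripheral"]
  say("  shared planted sites among replications: %d of %d",
      sum(shared %in% lk$site_id[which(lk$significant)]), length(unique(shared)))

  p0 <- replication_null_p0(meta[[pair[1]]], meta[[pair[2]]])
  rt <- replication_proportion_test(sum(lk$significant, na.rm = TRUE),
                                    sum(lk$available), p0)
  say("  replication vs chance (p0=%.2g): chi^2=%.1f, p=%.3g",
      p0, rt$chi_square, rt$p)
  write_result(lk, sprintf("06_lookup_%s.tsv", lab),
               sprintf("# look-up %s; chance test chi^2=%.2f p=%.3g",
                       lab, rt$chi_square, rt$p))
}
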