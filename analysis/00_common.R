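# Shared setup for the analysis drivers: the study configuration, output
# locations, and a cache so later stages reuse earlier products instead of
# recomputing them. Every script can also run standalone: if the cache is
# missing it rebuilds deterministically from the same master seed.

library(ctmwas)

RESULTS_DIR <- "results/analysis"
SCRATCH_DIR <- "scratch/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(SCRATCH_DIR, recursive = TRUE, showWarnings = FALSE)

analysis_config <- function() default_consortium_config(master_seed = 20260925L)

cached <- function(name, build) {
  path <- file.path(SCRATCH_DIR, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  obj <- build()
  saveRDS(obj, path)
  obj
}

get_consortium <- function() cached("consortium", function()
  simulate_consortium(analysis_config()))

get_mwas <- function() cached("mwas", function() {
  cons <- get_consortium()
  lapply(cons$studies, function(study)
    run_celltype_mwas(study, cons$panels[[study$platform]],
                      seed = derive_seed(analysis_config()$master_seed, 7)))
})

get_meta <- function() cached("meta", function() {
  cfg <- analysis_config()
  mw <- get_mwas()
  tissues <- vapply(mw, `[[`, "", "tissue")
  lapply(c(peripheral = "peripheral", cord = "cord"), function(ts)
    meta_analyze(mw[tissues == ts], study_order = cfg$study_order[[ts]],
                 analysis_label = ts))
})

say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))

write_result <- function(df, name, comment = "# analysis output") {
  path <- file.path(RESULTS_DIR, name)
  ctmwas:::write_tsv_commented(df, path, comment = comment)
  say("  wrote %s (%d rows)", path, nrow(df))
}
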