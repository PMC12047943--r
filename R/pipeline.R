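## Cheap content fingerprint used in stage-failure messages and the manifest.
fingerprint <- function(x) {
  if (is.matrix(x))
    sprintf("matrix[%dx%d] sum=%.6g", nrow(x), ncol(x), sum(x))
  else if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    sprintf("table[%dx%d] sum=%.6g", nrow(x), ncol(x),
            sum(vapply(x[num], sum, numeric(1))))
  } else sprintf("%s[%d]", class(x)[1], length(x))
}

run_stage <- function(name, input_fp, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed (input %s): %s", name, input_fp,
          conditionMessage(e)))
}

#' Run the full cell type-specific MWAS pipeline on a configuration
#'
#' Chains simulate -> deconvolve/mwas (per cohort) -> per-tissue meta-analysis
#' -> circular-permutation enrichment -> cross-tissue look-up, writing compact
#' result tables and a run manifest to `out_dir`. Fully deterministic under
#' the configuration's master seed: reruns produce byte-identical tables (the
#' manifest carries no timestamps).
#'
#' @param config consortium configuration, see [default_consortium_config()];
#'   alternatively a path to a YAML file with the same structure.
#' @param out_dir output directory (created if absent).
#' @param thresholds named list overriding `fdr_alpha` (0.05), `suggestive_q`
#'   (0.5), `flank` (1e5), `n_perm` (999), `rare_mean` (0.01), `rare_frac`
#'   (0.05).
#' @param top_n number of top records written per result table.
#' @return invisibly, a list with every in-memory stage product
#'   (`consortium`, `mwas`, `meta`, `enrichment`, `lookup`, `manifest`).
#' @export
run_pipeline <- function(config = default_consortium_config(),
                         out_dir = "results/pipeline",
                         thresholds = list(), top_n = 200L) {
  if (is.character(config)) config <- read_pipeline_config(config)
  th <- utils::modifyList(
    list(fdr_alpha = 0.05, suggestive_q = 0.5, flank = 1e5, n_perm = 999L,
         rare_mean = 0.01, rare_frac = 0.05),
    thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage <- function(fmt, ...) message(sprintf(paste0("[ctmwas] ", fmt), ...))

  ## --- simulate -------------------------------------------------------------
  cons <- run_stage("simulate", fingerprint(config$cohorts %||% list()),
                    simulate_consortium(config))
  log_stage("simulate: %d cohorts, %d-site sequencing universe (%d array subset)",
            length(cons$studies), config$panel$n_sites_seq,
            config$panel$n_sites_array)
  write_tsv_commented(cons$effects, file.path(out_dir, "planted_effects.tsv"),
                      comment = "# generator truth: planted effects")

  ## --- per-cohort deconvolution + MWAS -------------------------------------
  mwas <- list()
  prop_summaries <- list()
  for (id in names(cons$studies)) {
    study <- cons$studies[[id]]
    panel <- cons$panels[[study$platform]]
    res <- run_stage(paste0("mwas:", id), fingerprint(study$values),
                     run_celltype_mwas(study, panel,
                                       rare_threshold_mean = th$rare_mean,
                                       rare_threshold_frac = th$rare_frac,
                                       seed = derive_seed(config$master_seed, 7)))
    mwas[[id]] <- res
    ps <- proportion_summary(res$proportions)
    ps$study_id <- id
    prop_summaries[[id]] <- ps
    log_stage("mwas %s: %d sites tested, %d filtered, lambda %.2f",
              id, res$diagnostics$n_sites_tested,
              res$diagnostics$n_sites_filtered,
              res$diagnostics$lambda_overall)
  }
  write_tsv_commented(do.call(rbind, prop_summaries),
                      file.path(out_dir, "proportions_summary.tsv"),
                      comment = "# per-study cell-type proportion summaries")
  for (id in names(mwas)) {
    d <- mwas[[id]]$results
    d <- d[order(d$p), ][seq_len(min(top_n, nrow(d))), ]
    write_tsv_commented(d, file.path(out_dir, sprintf("mwas_%s_top.tsv", id)))
  }

  ## --- per-tissue meta-analysis ---------------------------------------------
  meta <- list()
  qq <- list()
  for (ts in c("peripheral", "cord")) {
    ids <- names(mwas)[vapply(mwas, `[[`, "", "tissue") == ts]
    order_ts <- config$study_order[[ts]] %||% ids
    meta[[ts]] <- run_stage(paste0("meta:", ts), fingerprint(data.frame(n = 1)),
                            meta_analyze(mwas[ids], study_order = order_ts,
                                         analysis_label = ts))
    tab <- meta[[ts]]$table
    top <- tab[order(tab$p), ][seq_len(min(top_n, nrow(tab))), ]
    write_tsv_commented(top, file.path(out_dir, sprintf("meta_%s_top.tsv", ts)))
    qd <- qq_diagnostics(tab$p)
    keep <- unique(round(seq(1, nrow(qd$table), length.out = 500)))
    qq[[ts]] <- list(lambda = qd$lambda, table = qd$table[keep, ])
    write_tsv_commented(qq[[ts]]$table,
                        file.path(out_dir, sprintf("qq_%s.tsv", ts)),
                        comment = sprintf("# QQ table, lambda=%.4f", qd$lambda))
    log_stage("meta %s: %d records, %d with q<%.2f, lambda %.2f", ts,
              nrow(tab), sum(tab$q < th$fdr_alpha), th$fdr_alpha, qd$lambda)
  }

  ## --- enrichment -----------------------------------------------------------
  enr <- list()
  for (ts in names(meta)) {
    enr[[ts]] <- run_stage(paste0("enrich:", ts), fingerprint(meta[[ts]]$table),
                           suppressWarnings(run_enrichment(
                             meta[[ts]], cons$catalog, flank = th$flank,
                             q_threshold = th$suggestive_q, n_perm = th$n_perm,
                             seed = derive_seed(config$master_seed, 11))))
    if (nrow(enr[[ts]]) > 0L) enr[[ts]]$analysis <- ts
  }
  enr_all <- do.call(rbind, enr)
  write_tsv_commented(enr_all, file.path(out_dir, "enrichment.tsv"),
                      comment = "# circular-permutation gene-set enrichment")
  log_stage("enrichment: %d (cell type, set) tests, %d with p<0.05",
            nrow(enr_all), sum(enr_all$p_empirical < 0.05))

  ## --- cross-tissue look-up -------------------------------------------------
  lk <- list()
  for (pair in list(c("peripheral", "cord"), c("cord", "peripheral"))) {
    lab <- paste(pair, collapse = "_to_")
    tab <- run_stage(paste0("lookup:", lab), fingerprint(meta[[pair[1]]]$table),
                     lookup_sites(meta[[pair[1]]], meta[[pair[2]]],
                                  q_threshold = th$fdr_alpha,
                                  alpha = th$fdr_alpha))
    rep_test <- if (nrow(tab) > 0L && any(tab$available)) {
      p0 <- replication_null_p0(meta[[pair[1]]], meta[[pair[2]]],
                                alpha = th$fdr_alpha)
      k <- sum(tab$significant, na.rm = TRUE)
      m <- sum(tab$available)
      c(replication_proportion_test(k, m, p0), list(k = k, m = m, p0 = p0))
    } else NULL
    lk[[lab]] <- list(table = tab, replication_test = rep_test)
    if (nrow(tab) > 0L)
      write_tsv_commented(tab, file.path(out_dir, sprintf("lookup_%s.tsv", lab)))
    log_stage("lookup %s: %d looked up, %d replicated", lab, nrow(tab),
              if (nrow(tab) > 0L) sum(tab$significant, na.rm = TRUE) else 0L)
  }

  ## --- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctmwas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$master_seed,
    derived_seeds = list(panel = derive_seed(config$master_seed, 1),
                         subsetting = derive_seed(config$master_seed, 2),
                         effects = derive_seed(config$master_seed, 3),
                         catalog = derive_seed(config$master_seed, 4),
                         pc1 = derive_seed(config$master_seed, 7),
                         enrichment = derive_seed(config$master_seed, 11),
                         cohorts = vapply(seq_along(config$cohorts), function(i)
                           derive_seed(config$master_seed, 100 + i), integer(1))),
    thresholds = th,
    cohorts = lapply(config$cohorts, function(co)
      co[c("study_id", "tissue", "platform", "n_samples")]),
    lambda = lapply(meta, function(m) as.list(m$lambda)),
    fingerprints = c(
      lapply(mwas, function(r) fingerprint(r$results)),
      lapply(meta, function(m) fingerprint(m$table))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(consortium = cons, mwas = mwas, meta = meta,
                 enrichment = enr_all, lookup = lk, manifest = manifest))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the list structure of [default_consortium_config()];
#' effect rows are given as a list of mappings with fields `cell_type`,
#' `beta`, `tissues`, `site_class` (and optionally `site_id`).
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$effects))
    cfg$effects <- do.call(rbind, lapply(cfg$effects, function(e)
      effect_spec(e$site_id %||% NA, e$cell_type, e$beta,
                  unlist(e$tissues), e$site_class %||% "array")))
  for (i in seq_along(cfg$cohorts))
    cfg$cohorts[[i]]$instrument <- unlist(cfg$cohorts[[i]]$instrument)
  if (is.null(cfg$covariates)) cfg$covariates <- covariate_spec()
  else cfg$covariates <- do.call(covariate_spec, cfg$covariates)
  cfg
}
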