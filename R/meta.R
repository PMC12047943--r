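#' Sample-size-weighted Stouffer combination of z-scores
#'
#' `z_meta = sum(sqrt(n_k) * z_k) / sqrt(sum(n_k))`, the METAL-style
#' fixed-effects combination. Non-finite z contributions are dropped with a
#' warning and k decremented.
#'
#' @param z per-study signed z-scores.
#' @param n per-study sample sizes (all > 0).
#' @return `z_meta`.
#' @export
stouffer_meta <- function(z, n) {
  stopifnot(length(z) == length(n), length(z) >= 1L, all(n > 0))
  bad <- !is.finite(z)
  if (any(bad)) {
    warnf("dropping %d non-finite z contribution(s) from Stouffer combination",
          sum(bad))
    z <- z[!bad]; n <- n[!bad]
    if (length(z) == 0L) return(NA_real_)
  }
  sum(sqrt(n) * z) / sqrt(sum(n))
}

#' Between-study heterogeneity under sample-size weighting
#'
#' Under the homogeneity model `z_k ~ Normal(delta * sqrt(n_k), 1)`, the
#' weighted common effect is `delta_hat = sum(sqrt(n_k) z_k) / sum(n_k)` and
#' `het_q = sum((z_k - delta_hat * sqrt(n_k))^2)` is exactly chi-square with
#' k - 1 degrees of freedom when the studies agree; a small p indicates
#' heterogeneity.
#'
#' @param z per-study signed z-scores.
#' @param n per-study sample sizes.
#' @return list with `het_q` and `het_p`; both `NA` when k = 1.
#' @export
heterogeneity_test <- function(z, n) {
  keep <- is.finite(z)
  z <- z[keep]; n <- n[keep]
  k <- length(z)
  if (k < 2L) return(list(het_q = NA_real_, het_p = NA_real_))
  delta_hat <- sum(sqrt(n) * z) / sum(n)
  het_q <- sum((z - delta_hat * sqrt(n))^2)
  list(het_q = het_q, het_p = pchisq(het_q, df = k - 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' The step-up procedure: with p sorted ascending,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Align per-cohort MWAS results into per-(site, cell type) study streams
#'
#' Sites are matched across studies on exact (chromosome, position). When the
#' cell-type map says so (default: CD3T feeds both CD4T and CD8T), a pooled
#' cell type's results are duplicated verbatim into each mapped stream. A
#' study missing a site contributes `"?"` to the direction string.
#'
#' @param results list of `CellTypeMWASResult` objects.
#' @param study_order character vector fixing the direction-string order; must
#'   cover all supplied studies.
#' @param celltype_map named list mapping a pooled label to the labels it
#'   feeds, e.g. `list(CD3T = c("CD4T", "CD8T"))`.
#' @return list with `long` (one row per study x site x cell type),
#'   `study_order`, and the union site table.
#' @export
align_studies <- function(results, study_order = NULL,
                          celltype_map = list(CD3T = c("CD4T", "CD8T"))) {
  stopifnot(length(results) >= 1L)
  ids <- vapply(results, `[[`, "", "study_id")
  if (is.null(study_order)) study_order <- ids
  if (!all(ids %in% study_order))
    stopf("study_order must cover all studies; missing: %s",
          paste(setdiff(ids, study_order), collapse = ", "))

  long <- do.call(rbind, lapply(results, function(r) {
    df <- r$results
    key <- paste(df$chrom, df$pos, df$cell_type)
    if (anyDuplicated(key))
      stopf("study %s has duplicated (site, cell type) records", r$study_id)
    ## expand pooled cell types into the streams they feed
    for (src in names(celltype_map)) {
      hit <- df$cell_type == src
      if (any(hit)) {
        expanded <- do.call(rbind, lapply(celltype_map[[src]], function(dst) {
          d <- df[hit, , drop = FALSE]; d$cell_type <- dst; d
        }))
        df <- rbind(df[!hit, , drop = FALSE], expanded)
      }
    }
    df$study_id <- r$study_id
    df
  }))
  rownames(long) <- NULL

  sites <- unique(long[, c("chrom", "pos", "site_id")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  if (nrow(sites) == 0L)
    stopf("no sites shared across studies")
  list(long = long, study_order = study_order, sites = sites)
}

#' Meta-analyze per-cohort cell type-specific MWAS results
#'
#' For every (site, cell type) combines contributing studies by
#' [stouffer_meta()], tests heterogeneity, and controls the FDR with
#' [bh_fdr()] separately per cell type. The direction string reports the
#' per-study effect sign (`+`/`-`) in the fixed `study_order`, with `?` for
#' studies not covering the site.
#'
#' @param results list of `CellTypeMWASResult` objects.
#' @param study_order,celltype_map see [align_studies()].
#' @param analysis_label label stored with the result (e.g. "peripheral").
#' @return object of class `MetaResult`: data.frame `table` with columns
#'   `chrom`, `pos`, `site_id`, `cell_type`, `k`, `z_meta`, `p`, `q`,
#'   `direction`, `het_q`, `het_p`; plus per-cell-type `lambda`.
#' @export
meta_analyze <- function(results, study_order = NULL,
                         celltype_map = list(CD3T = c("CD4T", "CD8T")),
                         analysis_label = "meta") {
  al <- align_studies(results, study_order, celltype_map)
  long <- al$long
  study_order <- al$study_order

  out <- do.call(rbind, lapply(split(long, long$cell_type), function(d) {
    key <- paste(d$chrom, d$pos)
    usite <- unique(d[, c("chrom", "pos", "site_id")])
    usite <- usite[order(usite$chrom, usite$pos), ]
    ukey <- paste(usite$chrom, usite$pos)

    zmat <- matrix(NA_real_, nrow(usite), length(study_order),
                   dimnames = list(ukey, study_order))
    nmat <- zmat
    zmat[cbind(match(key, ukey), match(d$study_id, study_order))] <- d$z
    nmat[cbind(match(key, ukey), match(d$study_id, study_order))] <- d$n

    res <- t(vapply(seq_len(nrow(usite)), function(i) {
      zi <- zmat[i, ]; ni <- nmat[i, ]
      ok <- is.finite(zi) & is.finite(ni)
      zm <- stouffer_meta(zi[ok], ni[ok])
      het <- heterogeneity_test(zi[ok], ni[ok])
      c(k = sum(ok), z_meta = zm, het_q = het$het_q, het_p = het$het_p)
    }, numeric(4)))

    direction <- apply(zmat, 1, function(zi)
      paste(ifelse(is.na(zi), "?", ifelse(zi >= 0, "+", "-")), collapse = ""))

    df <- data.frame(usite, cell_type = d$cell_type[1],
                     k = as.integer(res[, "k"]), z_meta = res[, "z_meta"],
                     p = z_to_p(res[, "z_meta"]),
                     direction = direction,
                     het_q = res[, "het_q"], het_p = res[, "het_p"],
                     row.names = NULL, stringsAsFactors = FALSE)
    df$q <- bh_fdr(df$p)   # FDR universe: per cell type within the analysis
    df
  }))
  rownames(out) <- NULL
  out <- out[, c("chrom", "pos", "site_id", "cell_type", "k", "z_meta",
                 "p", "q", "direction", "het_q", "het_p")]

  lam <- vapply(split(out$z_meta, out$cell_type),
                function(z) if (sum(is.finite(z)) >= 100L)
                  genomic_inflation(z) else NA_real_,
                numeric(1))
  structure(list(table = out, lambda = lam, study_order = study_order,
                 analysis = analysis_label),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("MetaResult '%s': %d records (%d sites), studies: %s\n",
              x$analysis, nrow(x$table),
              length(unique(x$table$site_id)),
              paste(x$study_order, collapse = ", ")))
  lam <- x$lambda[is.finite(x$lambda)]
  if (length(lam) > 0L)
    cat(sprintf("  lambda %s\n",
                paste(sprintf("%s=%.2f", names(lam), lam), collapse = " ")))
  invisible(x)
}

#' Leave-one-out sensitivity meta-analysis
#'
#' Recomputes the meta-analysis with one study excluded; used to check that
#' findings are not driven by a single cohort.
#'
#' @param results list of `CellTypeMWASResult` objects (>= 2).
#' @param excluded_study study_id to drop.
#' @param ... passed to [meta_analyze()].
#' @return a `MetaResult` on the reduced study set.
#' @export
leave_one_out <- function(results, excluded_study, ...) {
  ids <- vapply(results, `[[`, "", "study_id")
  if (!excluded_study %in% ids)
    stopf("study '%s' not among: %s", excluded_study,
          paste(ids, collapse = ", "))
  if (length(results) < 2L)
    stopf("need >= 2 studies before exclusion")
  keep <- results[ids != excluded_study]
  args <- list(...)
  if (!is.null(args$study_order))
    args$study_order <- setdiff(args$study_order, excluded_study)
  do.call(meta_analyze, c(list(results = keep), args))
}

#' QQ diagnostics for a vector of p-values
#'
#' Expected -log10 p at ranks (i - 0.5)/m against observed, with a 95%
#' order-statistic band (beta quantiles), plus the genomic inflation factor of
#' the back-transformed z-scores.
#'
#' @param p p-values (>= 100).
#' @return list with `table` (`expected`, `observed`, `lower`, `upper` on the
#'   -log10 scale) and `lambda`.
#' @export
qq_diagnostics <- function(p) {
  p <- p[is.finite(p)]
  m <- length(p)
  if (m < 100L) stopf("QQ diagnostics need >= 100 p-values, got %d", m)
  o <- sort(p)
  i <- seq_len(m)
  expected <- (i - 0.5) / m
  tab <- data.frame(
    expected = -log10(expected),
    observed = -log10(o),
    lower = -log10(qbeta(0.975, i, m - i + 1)),
    upper = -log10(qbeta(0.025, i, m - i + 1))
  )
  z <- qnorm(pmin(1 - 1e-16, pmax(1e-300, o)) / 2)  # |z| up to sign
  list(table = tab, lambda = genomic_inflation(z))
}
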