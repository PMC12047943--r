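#' Flag suggestive association findings
#'
#' A site is suggestive when its FDR q-value is strictly below `q_threshold`
#' (default 0.5). Computed per cell type.
#'
#' @param meta a `MetaResult`.
#' @param q_threshold strict upper bound on q.
#' @return the meta table with an added 0/1 `suggestive` column.
#' @export
select_suggestive <- function(meta, q_threshold = 0.5) {
  tab <- meta$table
  tab$suggestive <- as.integer(tab$q < q_threshold)
  tab
}

#' Map CpG sites to genes with a flanking window
#'
#' A site maps to a gene when `gene_start - flank <= pos <= gene_end + flank`
#' (1-based inclusive bounds). Overlap is computed with interval trees
#' per chromosome; a site may map to zero, one or many genes.
#'
#' @param sites site table with `chrom`, `pos`, `site_id`.
#' @param catalog a `GeneCatalog`.
#' @param flank flanking window in bp (default 100 kb).
#' @return list keyed by `site_id`, each element the character vector of
#'   overlapping gene ids (possibly empty).
#' @export
map_sites_to_genes <- function(sites, catalog, flank = 100000) {
  genes <- catalog$genes
  out <- rep(list(character(0)), nrow(sites))
  names(out) <- sites$site_id
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    q <- IRanges::IRanges(start = sites$pos[si], width = 1L)
    s <- IRanges::IRanges(start = pmax(1L, genes$start[gi] - as.integer(flank)),
                          end = genes$end[gi] + as.integer(flank))
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(si)) {
      hit_genes <- sh[qh == k]
      if (length(hit_genes) > 0L)
        out[[si[k]]] <- sort(genes$gene_id[gi[hit_genes]])
    }
  }
  out
}

#' Circular permutation test for gene-set enrichment
#'
#' The observed statistic is the number of suggestive sites falling in the
#' set's territory, `sum(indicator * membership)`, with both vectors aligned
#' to the genome-ordered site list (chromosomes concatenated into a single
#' circle). The null rotates the indicator by an offset d (membership fixed),
#' preserving the indicator's autocorrelation and the gene-size bias;
#' `p = (1 + #\{d : stat_d >= observed\}) / (n_perm + 1)`. Offsets are all
#' `m - 1` nontrivial rotations (exhaustive mode) or a seeded uniform draw
#' without replacement (sampled mode). Rotation statistics for every offset
#' are evaluated at once through the FFT circular cross-correlation.
#'
#' @param indicator 0/1 vector of suggestive sites, genome order.
#' @param membership 0/1 vector of set territory, same order.
#' @param n_perm number of rotations in sampled mode; if `> m - 1` the test
#'   switches to exhaustive with a notice.
#' @param seed seed for sampled offsets.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @return object of class `EnrichmentResult`: `observed_stat`, `n_perm`,
#'   `p_empirical`, `enrichment_ratio` (observed over mean rotation-null
#'   statistic), `mode`.
#' @export
circular_permutation_test <- function(indicator, membership, n_perm = 999L,
                                      seed = 1L,
                                      mode = c("sampled", "exhaustive")) {
  mode <- match.arg(mode)
  m <- length(indicator)
  stopifnot(length(membership) == m, m >= 2L)
  indicator <- as.numeric(indicator); membership <- as.numeric(membership)

  observed <- sum(indicator * membership)
  null_stats <- rotation_null_stats(indicator, membership)

  if (mode == "sampled" && n_perm > m - 1L) {
    message(sprintf(
      "n_perm=%d exceeds the %d distinct rotations; switching to exhaustive",
      n_perm, m - 1L))
    mode <- "exhaustive"
  }
  if (mode == "exhaustive") {
    used <- null_stats
  } else {
    set.seed(seed)
    used <- null_stats[sample.int(m - 1L, n_perm)]
  }
  p <- (1 + sum(used >= observed)) / (length(used) + 1)
  structure(list(observed_stat = observed, n_perm = length(used),
                 p_empirical = p,
                 enrichment_ratio = observed / max(mean(used), .Machine$double.eps),
                 mode = mode),
            class = "EnrichmentResult")
}

## Overlap statistic of every nontrivial rotation offset d = 1..m-1, evaluated
## at once through the FFT circular cross-correlation; exact for 0/1 vectors.
rotation_null_stats <- function(indicator, membership) {
  m <- length(indicator)
  stats_all <- round(Re(fft(Conj(fft(as.numeric(membership))) *
                              fft(as.numeric(indicator)),
                            inverse = TRUE)) / m)
  stats_all[-1L]
}

#' Run gene-set enrichment over a meta-analysis result
#'
#' Per cell type, the suggestive indicator (q below `q_threshold`) is laid on
#' the genome-ordered site circle; each gene set's territory (sites within
#' `flank` of a member gene) is tested with [circular_permutation_test()].
#' Sets with no member genes or no covered sites are skipped with a warning.
#' No cross-set multiplicity correction is applied.
#'
#' @param meta a `MetaResult`.
#' @param catalog a `GeneCatalog`.
#' @param flank flanking window in bp.
#' @param q_threshold suggestive threshold (strict).
#' @param n_perm rotations per test.
#' @param seed master seed (per-set seeds derived by counter).
#' @param mode `"sampled"` or `"exhaustive"`.
#' @return data.frame with one row per (cell type, set): `cell_type`,
#'   `set_id`, `n_set_sites`, `observed_stat`, `n_perm`, `p_empirical`,
#'   `enrichment_ratio`.
#' @export
run_enrichment <- function(meta, catalog, flank = 100000, q_threshold = 0.5,
                           n_perm = 999L, seed = 1L,
                           mode = c("sampled", "exhaustive")) {
  mode <- match.arg(mode)
  tab <- select_suggestive(meta, q_threshold)

  rows <- list()
  for (ct in unique(tab$cell_type)) {
    d <- tab[tab$cell_type == ct, ]
    d <- d[order(d$chrom, d$pos), ]
    site_genes <- map_sites_to_genes(d, catalog, flank)
    for (set_id in names(catalog$gene_sets)) {
      set_genes <- catalog$gene_sets[[set_id]]
      if (length(set_genes) == 0L) {
        warnf("gene set '%s' is empty; skipped", set_id)
        next
      }
      membership <- vapply(site_genes,
                           function(g) any(g %in% set_genes), logical(1))
      if (!any(membership)) {
        warnf("gene set '%s' covers no sites for %s; skipped", set_id, ct)
        next
      }
      r <- circular_permutation_test(d$suggestive, as.integer(membership),
                                     n_perm = n_perm,
                                     seed = derive_seed(seed, length(rows)),
                                     mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, set_id = set_id, n_set_sites = sum(membership),
        observed_stat = r$observed_stat, n_perm = r$n_perm,
        p_empirical = r$p_empirical, enrichment_ratio = r$enrichment_ratio,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
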