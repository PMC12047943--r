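#' Look up discovery-significant sites in another tissue's meta-analysis
#'
#' For every discovery record with `q < q_threshold`, finds the matching
#' (chromosome, position, cell type) record in the target meta-analysis.
#' Bonferroni correction multiplies the target p by the number of looked-up
#' sites with available target data, counted per cell type; sites missing
#' from the target are marked unavailable and excluded from that denominator.
#' Direction concordance compares the signs of the discovery and target
#' z-scores.
#'
#' @param discovery a `MetaResult` (the tissue that made the findings).
#' @param target a `MetaResult` (the tissue looked up in).
#' @param q_threshold discovery significance threshold on q (default 0.05).
#' @param alpha significance level applied to the Bonferroni-corrected p.
#' @return data.frame with one row per looked-up record: discovery
#'   (`cell_type`, `z_disc`, `q_disc`), target (`z_target`, `p_target`,
#'   `k_target`, `p_bonferroni`), `available`, `direction_concordant`,
#'   `significant`. Empty discovery set gives an empty data.frame.
#' @export
lookup_sites <- function(discovery, target, q_threshold = 0.05,
                         alpha = 0.05) {
  disc <- discovery$table[discovery$table$q < q_threshold, , drop = FALSE]
  if (nrow(disc) == 0L)
    return(data.frame())
  tgt <- target$table
  tkey <- paste(tgt$chrom, tgt$pos, tgt$cell_type)
  ix <- match(paste(disc$chrom, disc$pos, disc$cell_type), tkey)

  out <- data.frame(
    chrom = disc$chrom, pos = disc$pos, site_id = disc$site_id,
    cell_type = disc$cell_type,
    z_disc = disc$z_meta, q_disc = disc$q,
    available = !is.na(ix),
    z_target = ifelse(is.na(ix), NA_real_, tgt$z_meta[ix]),
    p_target = ifelse(is.na(ix), NA_real_, tgt$p[ix]),
    k_target = ifelse(is.na(ix), NA_integer_, tgt$k[ix]),
    stringsAsFactors = FALSE
  )
  ## Bonferroni denominator: available look-ups, per cell type
  denom <- tapply(out$available, out$cell_type, sum)
  out$n_lookups <- as.integer(denom[out$cell_type])
  out$p_bonferroni <- pmin(1, out$p_target * out$n_lookups)
  out$direction_concordant <- ifelse(out$available,
                                     sign(out$z_disc) == sign(out$z_target),
                                     NA)
  out$significant <- ifelse(out$available, out$p_bonferroni < alpha, NA)
  out
}

#' One-sample proportions test with continuity correction
#'
#' Tests whether `k` significant replications out of `m` look-ups exceed the
#' chance rate `p0`:
#' `chi^2 = (max(|k - m*p0| - 0.5, 0))^2 / (m * p0 * (1 - p0))`, with p the
#' upper chi-square(1) tail (two-sided).
#'
#' @param k_significant number of significant look-ups (0 <= k <= m).
#' @param m_lookups number of look-ups (> 0).
#' @param p0 null probability per look-up (0 < p0 < 1).
#' @return list with `chi_square` and `p`.
#' @export
replication_proportion_test <- function(k_significant, m_lookups, p0) {
  if (m_lookups == 0) stopf("m_lookups must be > 0")
  stopifnot(k_significant >= 0, k_significant <= m_lookups, p0 > 0, p0 < 1)
  num <- max(abs(k_significant - m_lookups * p0) - 0.5, 0)
  chi <- num^2 / (m_lookups * p0 * (1 - p0))
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Null probability of joint significance for the replication test
#'
#' The default chance rate of a site being significant in both analyses under
#' independence: the product of the fractions of tested records reaching
#' `q < alpha` in each meta-analysis.
#'
#' @param discovery,target `MetaResult` objects.
#' @param alpha the q threshold defining significance.
#' @return p0 in (0, 1), floored at 1/(records + 1) to stay positive.
#' @export
replication_null_p0 <- function(discovery, target, alpha = 0.05) {
  f1 <- mean(discovery$table$q < alpha)
  f2 <- mean(target$table$q < alpha)
  max(f1 * f2, 1 / (nrow(discovery$table) + nrow(target$table) + 1))
}
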