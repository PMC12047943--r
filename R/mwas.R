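#' Standardize a raw symptom score within a cohort
#'
#' Consortium cohorts measure symptoms on different instruments; scores are
#' therefore scaled within each cohort to mean 0 and standard deviation 1
#' (sample SD, denominator n - 1) before association testing.
#'
#' @param phenotype_raw numeric vector of per-sample scores.
#' @return z-scored vector.
#' @export
standardize_phenotype <- function(phenotype_raw) {
  x <- as.numeric(phenotype_raw)
  if (length(unique(x)) < 2L || sd(x) == 0)
    stopf("phenotype is constant; cannot standardize")
  (x - mean(x)) / sd(x)
}

#' Filter rarely methylated sites from sequencing-based studies
#'
#' Sequencing covers the full CpG universe, including sites that are almost
#' never methylated in blood; akin to a minor-allele-frequency filter, these
#' are removed before association. A site is removed when its mean normalized
#' value is below `threshold_mean` OR the fraction of samples with a nonzero
#' value is below `threshold_frac`. Array-like studies pass through unchanged.
#'
#' @param study a `MethylationStudy`.
#' @param threshold_mean mean-methylation threshold (default 0.01).
#' @param threshold_frac nonzero-fraction threshold (default 0.05).
#' @return list with `study` (filtered), `removed_site_ids`, `n_removed`.
#' @export
filter_rare_sites <- function(study, threshold_mean = 0.01,
                              threshold_frac = 0.05) {
  if (study$platform != "seq_like")
    return(list(study = study, removed_site_ids = character(0), n_removed = 0L))
  mu <- rowMeans(study$values)
  frac_pos <- rowMeans(study$values > 0)
  drop <- mu < threshold_mean | frac_pos < threshold_frac
  removed <- study$sites$site_id[drop]
  study$values <- study$values[!drop, , drop = FALSE]
  study$sites <- study$sites[!drop, , drop = FALSE]
  list(study = study, removed_site_ids = removed, n_removed = sum(drop))
}

## Build a full-rank design matrix (intercept + encoded covariates); errors
## name the collinear columns.
build_design <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0L)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("covariate design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  X
}

#' Regress measured covariates out of a methylation matrix
#'
#' Per site, returns ordinary least-squares residuals against an intercept
#' plus the encoded covariates. Residuals are orthogonal to every design
#' column. The phenotype must be residualized against the same design before
#' the interaction fit (symmetric partialling keeps confounding from leaking
#' through the interaction terms).
#'
#' @param mat numeric matrix, sites x samples (or a vector, treated as one
#'   variable over samples).
#' @param covariates data.frame of per-sample covariates (numeric and
#'   categorical), or `NULL` for intercept-only (per-site centering).
#' @return residual matrix of the same shape (or vector).
#' @export
residualize <- function(mat, covariates = NULL) {
  vec <- is.null(dim(mat))
  M <- if (vec) matrix(mat, ncol = 1) else t(mat)   # samples x sites
  n <- nrow(M)
  if (!is.null(covariates) && n <= NCOL(covariates) + 1L)
    stopf("need more samples (%d) than covariates (%d) + 1", n,
          NCOL(covariates))
  X <- build_design(covariates, n)
  res <- qr.resid(qr(X), M)
  if (vec) drop(res) else t(res)
}

#' Capture one remaining hidden confounder as a principal component
#'
#' After measured covariates are regressed out, the first principal component
#' of the residual methylation matrix (samples as observations, sites
#' standardized to unit variance) captures the dominant unmeasured source of
#' structure, e.g. an unrecorded batch. For tractability the PC is computed on
#' up to `max_sites` randomly sampled sites. The sign is fixed so the loading
#' with the largest magnitude is positive.
#'
#' @param residual_mat residualized methylation, sites x samples.
#' @param max_sites maximum number of sites used (sampled under `seed`).
#' @param seed seed for site sampling.
#' @return numeric vector of per-sample PC1 scores (unit norm times singular
#'   value).
#' @export
capture_hidden_confounder <- function(residual_mat, max_sites = 50000L,
                                      seed = 1L) {
  n <- ncol(residual_mat)
  if (n < 3L) stopf("need at least 3 samples for confounder capture")
  m <- nrow(residual_mat)
  if (m > max_sites) {
    set.seed(seed)
    residual_mat <- residual_mat[sort(sample.int(m, max_sites)), , drop = FALSE]
  }
  sds <- apply(residual_mat, 1, sd)
  keep <- sds > 1e-12
  Ms <- residual_mat[keep, , drop = FALSE] / sds[keep]
  ## Ms is sites x samples; the sample-space Gram matrix t(Ms) %*% Ms is
  ## n x n, so the leading sample scores come cheaply from its eigenvectors
  E <- eigen(crossprod(Ms), symmetric = TRUE)
  u1 <- E$vectors[, 1]
  d1 <- sqrt(max(E$values[1], 0))
  loadings <- as.numeric(Ms %*% u1) / max(d1, 1e-300)
  if (loadings[which.max(abs(loadings))] < 0) u1 <- -u1
  as.numeric(u1 * d1)
}

#' Convert a signed z-score to a two-sided normal p-value
#'
#' Computed through the log-space normal tail so p remains accurate far below
#' 1e-300.
#'
#' @param z numeric vector of signed z-scores.
#' @return two-sided p-values `2 * pnorm(-|z|)`, capped at 1.
#' @export
z_to_p <- function(z) {
  pmin(1, 2 * exp(pnorm(-abs(z), log.p = TRUE)))
}

## t-statistic with df degrees of freedom -> signed z with the identical
## two-sided p, via the log-space tail.
t_to_z <- function(tstat, df) {
  lp_half <- pt(-abs(tstat), df, log.p = TRUE)
  zabs <- -qnorm(lp_half, log.p = TRUE)
  sign(tstat) * zabs
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / 0.4549364231`, the observed over expected median of
#' a chi-square(1); values near 1 indicate calibrated tests.
#'
#' @param z numeric vector of z-scores (>= 100 finite values).
#' @return lambda.
#' @export
genomic_inflation <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 100L)
    stopf("genomic inflation needs >= 100 finite z values, got %d", length(z))
  median(z^2) / CHISQ1_MEDIAN
}

#' Cell type-specific association via the proportion-interaction model
#'
#' For residualized methylation r_ij at site i, sample j, fits per site the
#' no-intercept regression
#' `r_ij = sum_t a_it * p_jt + sum_t b_it * (p_jt * y_j) + e_ij`
#' where p_jt are the estimated cell-type proportions and y_j the
#' (residualized, standardized) phenotype. Because proportions sum to 1 their
#' main effects span the intercept. The null `b_it = 0` is tested per cell
#' type with a t-statistic on `n - 2T` degrees of freedom, converted to a
#' signed z carrying the identical two-sided p.
#'
#' Cell types flagged low-proportion by [proportion_summary()] stay in the
#' design but are excluded from the reported results (their statistics are
#' deflated, mirroring low-abundance B-cell behavior).
#'
#' @param resid_meth residualized methylation, sites x samples.
#' @param phenotype_z residualized, standardized phenotype vector.
#' @param props `CellProportions` for the same samples.
#' @param sites optional site annotation (`chrom`, `pos`, `site_id`).
#' @param exclude_low_proportion drop flagged cell types from the report.
#' @return data.frame with columns `site_id`, `chrom`, `pos`, `cell_type`,
#'   `n`, `df`, `effect`, `z`, `p`; attribute `excluded_cell_types` lists any
#'   excluded labels.
#' @export
celltype_association <- function(resid_meth, phenotype_z, props,
                                 sites = NULL,
                                 exclude_low_proportion = TRUE) {
  P <- props$values
  n <- length(phenotype_z)
  T_ <- ncol(P)
  stopifnot(nrow(P) == n, ncol(resid_meth) == n)
  if (n <= 2 * T_)
    stopf("need n > 2T samples (n=%d, T=%d)", n, T_)

  X <- cbind(P, P * phenotype_z)
  colnames(X) <- c(props$cell_types, paste0(props$cell_types, ":y"))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stopf("interaction design is rank deficient (rank %d < %d)",
          qx$rank, ncol(X))
  Y <- t(resid_meth)                       # samples x sites
  coefs <- qr.coef(qx, Y)                  # 2T x m
  res <- Y - X %*% coefs
  df <- n - 2L * T_
  sigma2 <- colSums(res^2) / df
  Rinv <- backsolve(qr.R(qx), diag(2L * T_))
  xtx_inv_diag <- numeric(2L * T_)
  xtx_inv_diag[qx$pivot] <- rowSums(Rinv^2)  # undo any column pivoting

  m <- ncol(Y)
  int_ix <- (T_ + 1L):(2L * T_)
  out <- vector("list", T_)
  site_id <- if (!is.null(sites)) sites$site_id else
    colnames(Y) %||% sprintf("site%06d", seq_len(m))
  for (t in seq_len(T_)) {
    b <- coefs[int_ix[t], ]
    se <- sqrt(xtx_inv_diag[int_ix[t]] * sigma2)
    tstat <- b / se
    z <- t_to_z(tstat, df)
    out[[t]] <- data.frame(
      site_id = site_id,
      chrom = if (!is.null(sites)) sites$chrom else NA_character_,
      pos = if (!is.null(sites)) sites$pos else NA_integer_,
      cell_type = props$cell_types[t],
      n = n, df = df, effect = b, z = z, p = z_to_p(z),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  res_df <- do.call(rbind, out)

  excluded <- character(0)
  if (exclude_low_proportion) {
    ps <- proportion_summary(props)
    excluded <- ps$cell_type[ps$low_proportion]
    if (length(excluded) > 0L)
      res_df <- res_df[!res_df$cell_type %in% excluded, , drop = FALSE]
  }
  attr(res_df, "excluded_cell_types") <- excluded
  res_df
}

#' Run the full single-cohort cell type-specific MWAS
#'
#' Chains the per-cohort stages: rare-site filtering (sequencing platforms),
#' panel matching, proportion estimation, phenotype standardization, covariate
#' residualization of methylation and phenotype, capture and removal of one
#' hidden-confounder principal component, and the proportion-by-phenotype
#' interaction association. Estimated (never true) proportions are used.
#'
#' @param study a `MethylationStudy`.
#' @param panel the platform-matched [reference_panel()].
#' @param rare_threshold_mean,rare_threshold_frac rare-site filter thresholds.
#' @param pc_max_sites site cap for the confounder principal component.
#' @param seed seed for the PC site subsample.
#' @param exclude_low_proportion see [celltype_association()].
#' @return object of class `CellTypeMWASResult`: `study_id`, `tissue`,
#'   `platform`, `results` (association table), `proportions`, `diagnostics`
#'   (per-cell-type and overall lambda, site counts, exclusions).
#' @export
run_celltype_mwas <- function(study, panel,
                              rare_threshold_mean = 0.01,
                              rare_threshold_frac = 0.05,
                              pc_max_sites = 50000L, seed = 1L,
                              exclude_low_proportion = TRUE) {
  filt <- filter_rare_sites(study, rare_threshold_mean, rare_threshold_frac)
  study <- filt$study

  idx <- match_panel_sites(study, panel)
  props <- estimate_proportions(study$values[idx$study_ix, , drop = FALSE],
                                panel$profile[idx$panel_ix, , drop = FALSE])

  y <- standardize_phenotype(study$phenotype_raw)
  covs <- if (NCOL(study$covariates) > 0L) study$covariates else NULL
  meth_res <- residualize(study$values, covs)
  y_res <- residualize(y, covs)

  pc1 <- capture_hidden_confounder(meth_res, max_sites = pc_max_sites,
                                   seed = seed)
  meth_res <- residualize(meth_res, data.frame(pc1 = pc1))
  y_res <- residualize(y_res, data.frame(pc1 = pc1))
  y_res <- y_res / sd(y_res)   # restore unit scale after partialling

  res <- celltype_association(meth_res, y_res, props, sites = study$sites,
                              exclude_low_proportion = exclude_low_proportion)

  lam <- vapply(split(res$z, res$cell_type), genomic_inflation, numeric(1))
  diagnostics <- list(
    lambda = lam,
    lambda_overall = genomic_inflation(res$z),
    n_sites_tested = nrow(study$sites),
    n_sites_filtered = filt$n_removed,
    n_panel_matched = idx$n_matched,
    excluded_cell_types = attr(res, "excluded_cell_types")
  )
  structure(
    list(study_id = study$study_id, tissue = study$tissue,
         platform = study$platform, n = study$sample_n,
         results = res, proportions = props, diagnostics = diagnostics),
    class = "CellTypeMWASResult"
  )
}

#' @export
print.CellTypeMWASResult <- function(x, ...) {
  cat(sprintf("CellTypeMWASResult %s (%s, %s): %d sites x %d cell types, n=%d\n",
              x$study_id, x$tissue, x$platform,
              length(unique(x$results$site_id)),
              length(unique(x$results$cell_type)), x$n))
  cat(sprintf("  lambda overall %.3f; filtered %d rare sites\n",
              x$diagnostics$lambda_overall, x$diagnostics$n_sites_filtered))
  invisible(x)
}
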