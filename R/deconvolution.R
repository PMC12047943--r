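#' Match study sites to reference panel sites
#'
#' Sites are matched on exact (chromosome, position); the paired index is
#' ordered by genome position. Used to restrict proportion estimation to the
#' sites the panel covers while keeping all study sites for association.
#'
#' @param study a `MethylationStudy`.
#' @param panel a [reference_panel()].
#' @return list with integer vectors `study_ix` and `panel_ix` (parallel,
#'   genome-ordered) and counts `n_matched`, `n_study_only`, `n_panel_only`.
#' @export
match_panel_sites <- function(study, panel) {
  for (obj in list(study$sites, panel$sites))
    if (!all(c("chrom", "pos") %in% names(obj)))
      stopf("both study and panel must carry (chromosome, position) annotation")
  key_s <- paste(study$sites$chrom, study$sites$pos)
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  if (anyDuplicated(key_p)) {
    d <- key_p[duplicated(key_p)][1]
    stopf("panel has duplicated position: %s", d)
  }
  if (anyDuplicated(key_s)) {
    d <- key_s[duplicated(key_s)][1]
    stopf("study has duplicated position: %s", d)
  }
  panel_ix <- match(key_s, key_p)
  study_ix <- which(!is.na(panel_ix))
  panel_ix <- panel_ix[study_ix]
  ord <- order(study$sites$chrom[study_ix], study$sites$pos[study_ix])
  study_ix <- study_ix[ord]; panel_ix <- panel_ix[ord]
  if (length(study_ix) < 10L)
    stopf("only %d sites shared between study and panel; proportion estimation is unidentifiable (need >= 10)",
          length(study_ix))
  list(study_ix = study_ix, panel_ix = panel_ix,
       n_matched = length(study_ix),
       n_study_only = nrow(study$sites) - length(study_ix),
       n_panel_only = nrow(panel$sites) - length(study_ix))
}

#' Estimate cell-type proportions by simplex-constrained least squares
#'
#' For each bulk sample j, solves the quadratic program
#' `min_p || bulk_j - panel %*% p ||^2` subject to `p >= 0` and `sum(p) = 1`.
#' With the small number of blood cell types the QP is solved exactly by
#' enumerating candidate support sets: for every nonempty subset of cell
#' types, the equality-constrained least-squares solution is computed from a
#' pre-factorized KKT system; among the feasible candidates the one with the
#' lowest objective wins (ties broken by minimum norm). This is the global
#' optimum, since the optimum's own support appears among the candidates.
#'
#' @param bulk numeric matrix, sites x samples, rows matched to
#'   `panel_profile` rows (see [match_panel_sites()]).
#' @param panel_profile numeric matrix, sites x cell types.
#' @return an object of class `CellProportions`: `cell_types`, `values`
#'   (samples x cell types, rows on the unit simplex) and `residual_norm`
#'   per sample.
#' @export
estimate_proportions <- function(bulk, panel_profile) {
  A <- as.matrix(panel_profile)
  bulk <- as.matrix(bulk)
  T_ <- ncol(A)
  if (T_ < 2L) stopf("need >= 2 cell types")
  if (nrow(A) < T_) stopf("need at least as many sites as cell types")
  if (nrow(bulk) != nrow(A))
    stopf("bulk rows (%d) must match panel rows (%d)", nrow(bulk), nrow(A))
  kappa_ <- kappa(A, exact = TRUE)
  if (!is.finite(kappa_) || kappa_ > 1e8)
    stopf(paste("reference panel is rank deficient (condition number %.3g);",
                "add cell type-discriminating sites"), kappa_)

  G <- crossprod(A)            # T x T
  Ct <- crossprod(A, bulk)     # T x n_samples
  bb <- colSums(bulk^2)
  n <- ncol(bulk)

  ## pre-factorize the KKT system of every support set
  subsets <- lapply(seq_len(2^T_ - 1L), function(code)
    which(bitwAnd(code, bitwShiftL(1L, seq_len(T_) - 1L)) != 0L))
  kkt_inv <- lapply(subsets, function(S) {
    k <- length(S)
    K <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, k), 0))
    inv <- tryCatch(solve(K), error = function(e) NULL)
    inv
  })

  P <- matrix(0, n, T_, dimnames = list(colnames(bulk), colnames(A)))
  rnorm_ <- numeric(n)
  for (j in seq_len(n)) {
    cvec <- Ct[, j]
    best_obj <- Inf; best_p <- NULL; best_norm <- Inf
    for (si in seq_along(subsets)) {
      inv <- kkt_inv[[si]]
      if (is.null(inv)) next
      S <- subsets[[si]]
      sol <- inv %*% c(cvec[S], 1)
      p_S <- sol[seq_along(S)]
      if (any(p_S < -1e-10)) next
      obj <- bb[j] - 2 * sum(p_S * cvec[S]) +
        sum(p_S * (G[S, S, drop = FALSE] %*% p_S))
      nrm <- sum(p_S^2)
      if (obj < best_obj - 1e-12 ||
          (obj < best_obj + 1e-12 && nrm < best_norm)) {
        best_obj <- obj; best_norm <- nrm
        best_p <- numeric(T_); best_p[S] <- pmax(p_S, 0)
      }
    }
    best_p <- best_p / sum(best_p)
    P[j, ] <- best_p
    rnorm_[j] <- sqrt(max(best_obj, 0))
  }
  cell_proportions(colnames(A) %||% paste0("ct", seq_len(T_)), P, rnorm_)
}

#' Construct and validate a CellProportions object
#'
#' @param cell_types ordered cell-type labels.
#' @param values samples x cell types matrix; nonnegative rows summing to 1.
#' @param residual_norm optional per-sample fit residual norm.
#' @return a `CellProportions` object.
#' @export
cell_proportions <- function(cell_types, values, residual_norm = NULL) {
  values <- as.matrix(values)
  colnames(values) <- cell_types
  if (any(values < 0))
    stopf("proportions must be nonnegative")
  if (any(abs(rowSums(values) - 1) > 1e-8))
    stopf("proportion rows must sum to 1 within 1e-8")
  structure(list(cell_types = cell_types, values = values,
                 residual_norm = residual_norm),
            class = "CellProportions")
}

#' @export
print.CellProportions <- function(x, ...) {
  cat(sprintf("CellProportions: %d samples x %d cell types\n",
              nrow(x$values), length(x$cell_types)))
  print(round(colMeans(x$values), 3))
  invisible(x)
}

#' Summarize estimated cell-type proportions
#'
#' Reports per cell type the mean, SD and the fraction of samples with an
#' estimated proportion below `low_threshold`. Cell types whose mean
#' proportion falls below `low_threshold` are flagged as low-proportion;
#' downstream association reporting excludes flagged cell types, since their
#' interaction terms are poorly identified (deflated test statistics).
#'
#' @param props a `CellProportions` object.
#' @param low_threshold mean-proportion threshold for the low flag.
#' @return data.frame with columns `cell_type`, `mean`, `sd`, `frac_below_1pct`,
#'   `low_proportion`.
#' @export
proportion_summary <- function(props, low_threshold = 0.01) {
  v <- props$values
  data.frame(
    cell_type = props$cell_types,
    mean = colMeans(v),
    sd = apply(v, 2, sd),
    frac_below_1pct = colMeans(v < 0.01),
    low_proportion = colMeans(v) < low_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Brute-force simplex grid search for proportion estimation (reference)
#'
#' Exhaustively evaluates the residual norm over a dense grid on the unit
#' simplex. Exponential in the number of cell types; intended as an
#' independent check of [estimate_proportions()] on <= 3 cell types.
#'
#' @param bulk_col one bulk sample (numeric vector over sites).
#' @param panel_profile sites x cell types matrix.
#' @param resolution grid step on the simplex.
#' @return the grid point (proportion vector) with minimal residual norm.
#' @export
grid_search_proportions <- function(bulk_col, panel_profile,
                                    resolution = 0.005) {
  A <- as.matrix(panel_profile)
  T_ <- ncol(A)
  stopifnot(T_ <= 3)
  steps <- round(1 / resolution)
  if (T_ == 2) {
    p1 <- seq(0, steps) / steps
    grid <- cbind(p1, 1 - p1)
  } else {
    g <- expand.grid(i = 0:steps, j = 0:steps)
    g <- g[g$i + g$j <= steps, ]
    grid <- cbind(g$i, g$j, steps - g$i - g$j) / steps
  }
  resid <- colSums((bulk_col - A %*% t(grid))^2)
  grid[which.min(resid), ]
}
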