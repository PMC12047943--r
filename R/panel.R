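#' Reference panel of cell type-specific methylation profiles
#'
#' A reference panel holds the mean methylation profile of each physically
#' sorted cell type over a common set of CpG sites. It is the regression basis
#' for per-sample proportion estimation: a bulk profile is modelled as a convex
#' mixture of the panel columns.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `site_id`; coordinates
#'   are 1-based and strictly increasing within chromosome.
#' @param profile numeric matrix, sites x cell types, values in `[0, 1]`.
#' @param cell_types character vector of unique cell-type labels, one per
#'   profile column.
#' @return an object of class `ReferencePanel`.
#' @export
reference_panel <- function(sites, profile, cell_types) {
  profile <- as.matrix(profile)
  colnames(profile) <- cell_types
  panel <- structure(
    list(cell_types = cell_types, sites = sites, profile = profile),
    class = "ReferencePanel"
  )
  validate_reference_panel(panel)
  panel
}

validate_reference_panel <- function(panel) {
  with(panel, {
    if (length(cell_types) < 2L)
      stopf("a reference panel needs at least 2 cell types, got %d",
            length(cell_types))
    if (anyDuplicated(cell_types))
      stopf("duplicated cell-type labels: %s",
            paste(unique(cell_types[duplicated(cell_types)]), collapse = ", "))
    if (!all(c("chrom", "pos", "site_id") %in% names(sites)))
      stopf("panel sites must have columns chrom, pos, site_id")
    if (nrow(sites) != nrow(profile))
      stopf("profile rows (%d) must match sites (%d)",
            nrow(profile), nrow(sites))
    if (any(profile < 0 | profile > 1))
      stopf("panel profile values must lie in [0, 1]")
    bad <- unlist(lapply(split(sites$pos, sites$chrom),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      stopf("site positions must be strictly increasing within chromosome %s",
            paste(names(bad)[bad], collapse = ", "))
  })
  invisible(panel)
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("ReferencePanel: %d sites x %d cell types (%s)\n",
              nrow(x$profile), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Simulate a reference panel with discriminating sites
#'
#' Baseline per-site methylation is drawn from a bimodal beta mixture (most
#' CpGs in blood are either strongly methylated or strongly unmethylated). At
#' `n_discriminating` randomly chosen sites, one randomly chosen cell type's
#' profile is shifted by 0.3-0.5 (direction chosen so the shifted value stays
#' inside `[0, 1]`), which makes cell-type proportions identifiable from bulk
#' mixtures. All other sites have identical columns.
#'
#' @param n_sites number of CpG sites.
#' @param cell_types character vector (>= 2) of cell-type labels.
#' @param n_discriminating number of cell type-discriminating sites
#'   (`<= n_sites`).
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @param chroms chromosome labels over which sites are spread (autosomes).
#' @return a [reference_panel()] object. The `sites` table carries a logical
#'   `discriminating` column recording the generator truth.
#' @export
make_reference_panel <- function(n_sites, cell_types, n_discriminating,
                                 seed, chroms = as.character(1:22)) {
  if (length(cell_types) < 2L)
    stopf("at least 2 cell types are required, got %d", length(cell_types))
  stopifnot(is_count(n_sites), is_count(n_discriminating),
            n_discriminating <= n_sites)
  set.seed(seed)
  T_ <- length(cell_types)

  sites <- tile_sites(n_sites, chroms)
  ## bimodal baseline: low- and high-methylation modes, compressed away from
  ## the boundaries so default measurement noise rarely clips (<1% of entries)
  mode_hi <- runif(n_sites) < 0.5
  baseline <- ifelse(mode_hi, rbeta(n_sites, 8, 1.5), rbeta(n_sites, 1.5, 8))
  baseline <- 0.05 + 0.90 * baseline
  profile <- matrix(baseline, nrow = n_sites, ncol = T_)

  disc <- sort(sample.int(n_sites, n_discriminating))
  if (n_discriminating > 0L) {
    ct <- sample.int(T_, n_discriminating, replace = TRUE)
    shift <- runif(n_discriminating, 0.3, 0.5) *
      sample(c(-1, 1), n_discriminating, replace = TRUE)
    ## flip direction when the shift would leave [0, 1]
    out <- baseline[disc] + shift < 0 | baseline[disc] + shift > 1
    shift[out] <- -shift[out]
    profile[cbind(disc, ct)] <- baseline[disc] + shift
  }
  profile[profile < 0] <- 0
  profile[profile > 1] <- 1

  sites$discriminating <- seq_len(n_sites) %in% disc
  reference_panel(sites, profile, cell_types)
}

## Evenly spread n sites over chromosomes with jittered, strictly increasing
## 1-based positions.
tile_sites <- function(n_sites, chroms, spacing = 1000L) {
  chrom <- sort(rep_len(seq_along(chroms), n_sites))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(ix) {
    k <- length(ix)
    cumsum(sample.int(spacing, k, replace = TRUE) + 50L)
  }), use.names = FALSE)
  data.frame(chrom = chroms[chrom], pos = as.integer(pos),
             site_id = sprintf("cg%08d", seq_len(n_sites)),
             stringsAsFactors = FALSE)
}

#' Default blood cell types for the two platforms
#'
#' Array-style panels resolve six leukocyte types (CD8+ T, CD4+ T, CD14+
#' monocytes, CD15+ granulocytes, CD19+ B cells, CD56+ NK cells). Sequencing
#' (MBD-seq) style panels resolve four, with a single CD3+ T-cell class that
#' pools CD4+ and CD8+ T cells.
#'
#' @param platform `"array_like"` or `"seq_like"`.
#' @return character vector of cell-type labels.
#' @export
default_cell_types <- function(platform = c("array_like", "seq_like")) {
  platform <- match.arg(platform)
  if (platform == "array_like")
    c("CD8T", "CD4T", "Mono", "Gran", "Bcell", "NK")
  else
    c("CD3T", "Mono", "Gran", "Bcell")
}

#' Default Dirichlet concentration for blood cell-type proportions
#'
#' Centered on typical leukocyte differentials (granulocytes dominant, B and
#' NK cells small) with total concentration 30, which gives realistic
#' between-sample variability.
#'
#' @param cell_types cell-type labels as produced by [default_cell_types()].
#' @return named numeric vector of Dirichlet alpha parameters.
#' @export
default_dirichlet_alpha <- function(cell_types) {
  means <- c(CD8T = 0.08, CD4T = 0.15, CD3T = 0.23,
             Mono = 0.08, Gran = 0.60, Bcell = 0.04, NK = 0.05)
  m <- means[cell_types]
  if (anyNA(m)) m[is.na(m)] <- 0.05
  alpha <- 30 * m / sum(m)
  names(alpha) <- cell_types
  alpha
}
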