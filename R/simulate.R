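#' Specify a planted cell type-specific phenotype effect
#'
#' An effect is the methylation change, in a single cell type at a single CpG
#' site, per 1 standard deviation of the latent phenotype score. Effects may be
#' planted in one tissue or shared between cord and peripheral arms.
#'
#' @param site_id site identifier (or `NA` with a `site_class` of `"array"` or
#'   `"seq_only"`, letting [simulate_consortium()] assign a concrete site
#'   deterministically).
#' @param cell_type panel cell-type label carrying the effect. Effects named
#'   for CD4T or CD8T are applied at half strength to CD3T in sequencing
#'   cohorts whose panel pools T cells.
#' @param beta methylation change per 1 SD of phenotype; `|beta| <= 0.5`.
#' @param tissues character subset of `c("cord", "peripheral")`.
#' @param site_class used only when `site_id` is `NA`; see above.
#' @return one-row data.frame; rows from several calls can be `rbind`-ed.
#' @export
effect_spec <- function(site_id, cell_type, beta,
                        tissues = c("cord", "peripheral"),
                        site_class = "array") {
  stopifnot(length(beta) == 1, is.numeric(beta))
  if (abs(beta) > 0.5)
    stopf("|beta| must be <= 0.5 to keep values in range, got %g", beta)
  if (!all(tissues %in% c("cord", "peripheral")))
    stopf("tissues must be a subset of {cord, peripheral}")
  data.frame(site_id = as.character(site_id), cell_type = cell_type,
             beta = beta, tissues = paste(tissues, collapse = ","),
             site_class = site_class, stringsAsFactors = FALSE)
}

effect_applies <- function(effects, tissue) {
  if (is.null(effects) || nrow(effects) == 0L) return(effects[0, ])
  keep <- vapply(strsplit(effects$tissues, ","),
                 function(ts) tissue %in% ts, logical(1))
  effects[keep, , drop = FALSE]
}

## Dirichlet draws via normalized gammas; rows sum to 1 exactly (up to fp).
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  p <- g / rowSums(g)
  colnames(p) <- names(alpha)
  p
}

#' Default measured/hidden covariate specification for simulated cohorts
#'
#' Measured covariates are sex, age and a technical batch; each shifts a
#' configurable fraction of sites linearly. One hidden binary confounder (an
#' unrecorded batch) shifts `hidden_frac` of sites by `hidden_shift` with
#' random sign; it is what the principal-component capture step is meant to
#' absorb.
#'
#' @param frac_sites fraction of sites carrying each measured-covariate effect.
#' @param effect_sd SD of per-site measured-covariate coefficients.
#' @param hidden_frac fraction of sites shifted by the hidden confounder.
#' @param hidden_shift absolute methylation shift of the hidden confounder.
#' @param age_mean,age_sd age distribution in years.
#' @param n_batches number of measured technical batches.
#' @return a list understood by [simulate_cohort()].
#' @export
covariate_spec <- function(frac_sites = 0.10, effect_sd = 0.03,
                           hidden_frac = 0.30, hidden_shift = 0.05,
                           age_mean = 8, age_sd = 1.5, n_batches = 2) {
  list(frac_sites = frac_sites, effect_sd = effect_sd,
       hidden_frac = hidden_frac, hidden_shift = hidden_shift,
       age_mean = age_mean, age_sd = age_sd, n_batches = n_batches)
}

#' Simulate one cohort of bulk methylation with planted cell-type effects
#'
#' The generator is the forward direction of the deconvolution model: for site
#' i, sample j and cell types t,
#' `bulk_ij = sum_t p_jt * (panel_it + beta_it * y_j) + covariate and hidden
#' confounder contributions + noise`, with `p_j ~ Dirichlet(alpha)`, latent
#' phenotype `y_j ~ Normal(0, 1)` and noise `Normal(0, noise_sd)`. Values are
#' clipped to `[0, 1]` (array-like) or `[0, Inf)` (sequencing-like); the
#' clipped fraction is recorded. The raw symptom score is
#' `round(max(0, instrument_mean + instrument_sd * y_j))`, emulating
#' instrument-specific count scales.
#'
#' @param panel a [reference_panel()].
#' @param n_samples number of samples.
#' @param tissue `"cord"` or `"peripheral"`.
#' @param platform `"array_like"` or `"seq_like"`.
#' @param dirichlet_alpha positive vector, one per panel cell type.
#' @param effects data.frame of [effect_spec()] rows (may be `NULL`).
#' @param covariates a [covariate_spec()] list, or `NULL` for none.
#' @param noise_sd nonnegative measurement noise SD.
#' @param instrument_scale numeric `c(mean, sd)` of the raw symptom scale.
#' @param seed integer seed.
#' @param study_id cohort label.
#' @param proportions optional fixed sample x cell type proportion matrix
#'   overriding the Dirichlet draw (used for exact-mixture checks).
#' @return list with `study` (class `MethylationStudy`) and `truth` (true
#'   proportions, latent phenotype, hidden confounder, clipped fraction).
#' @export
simulate_cohort <- function(panel, n_samples,
                            tissue = c("peripheral", "cord"),
                            platform = c("array_like", "seq_like"),
                            dirichlet_alpha = default_dirichlet_alpha(panel$cell_types),
                            effects = NULL,
                            covariates = covariate_spec(),
                            noise_sd = 0.02,
                            instrument_scale = c(mean = 3, sd = 3),
                            seed = 1L, study_id = "S1",
                            proportions = NULL) {
  tissue <- match.arg(tissue)
  platform <- match.arg(platform)
  if (noise_sd < 0) stopf("noise_sd must be nonnegative, got %g", noise_sd)
  if (length(dirichlet_alpha) != length(panel$cell_types))
    stopf("dirichlet_alpha must have one entry per panel cell type (%d), got %d",
          length(panel$cell_types), length(dirichlet_alpha))
  set.seed(seed)

  m <- nrow(panel$profile)
  T_ <- length(panel$cell_types)
  if (is.null(proportions)) {
    P <- rdirichlet(n_samples, dirichlet_alpha)
  } else {
    P <- as.matrix(proportions)
    stopifnot(nrow(P) == n_samples, ncol(P) == T_)
  }
  colnames(P) <- panel$cell_types
  y <- rnorm(n_samples)

  bulk <- panel$profile %*% t(P)

  ## planted cell type-specific effects: p_jt * beta * y_j at the named site
  eff <- effect_applies(effects, tissue)
  if (!is.null(eff) && nrow(eff) > 0L) {
    for (r in seq_len(nrow(eff))) {
      i <- match(eff$site_id[r], panel$sites$site_id)
      if (is.na(i)) next  # site outside this cohort's universe
      ct <- eff$cell_type[r]
      beta <- eff$beta[r]
      if (!ct %in% panel$cell_types) {
        if (ct %in% c("CD4T", "CD8T") && "CD3T" %in% panel$cell_types) {
          ct <- "CD3T"; beta <- beta / 2  # CD3T pools CD4T and CD8T
        } else {
          stopf("effect cell type '%s' not in panel (%s)", ct,
                paste(panel$cell_types, collapse = ", "))
        }
      }
      t_ix <- match(ct, panel$cell_types)
      bulk[i, ] <- bulk[i, ] + P[, t_ix] * beta * y
    }
  }

  ## measured covariates + one hidden confounder
  cov_df <- data.frame(row.names = sprintf("%s_s%03d", study_id,
                                           seq_len(n_samples)))
  hidden <- NULL
  if (!is.null(covariates)) {
    cs <- covariates
    sex <- sample(c(0L, 1L), n_samples, replace = TRUE)
    age <- rnorm(n_samples, cs$age_mean, cs$age_sd)
    batch <- sample.int(cs$n_batches, n_samples, replace = TRUE)
    cov_df$sex <- factor(ifelse(sex == 1L, "M", "F"), levels = c("F", "M"))
    cov_df$age <- age
    cov_df$batch <- factor(paste0("b", batch))
    C <- cbind(sex = sex, age = (age - cs$age_mean) / cs$age_sd,
               batch = batch - mean(batch))
    E <- matrix(0, m, ncol(C))
    for (q in seq_len(ncol(C))) {
      hit <- sample.int(m, round(cs$frac_sites * m))
      E[hit, q] <- rnorm(length(hit), 0, cs$effect_sd)
    }
    bulk <- bulk + E %*% t(C)

    hidden <- sample(c(0L, 1L), n_samples, replace = TRUE)
    hit <- sample.int(m, round(cs$hidden_frac * m))
    hshift <- sample(c(-1, 1), length(hit), replace = TRUE) * cs$hidden_shift
    bulk[hit, ] <- bulk[hit, ] + hshift %o% as.numeric(hidden)
  }

  if (noise_sd > 0)
    bulk <- bulk + matrix(rnorm(m * n_samples, 0, noise_sd), m, n_samples)

  ## rarely methylated sites (sequencing platforms): sporadically methylated,
  ## zero score in most samples -- the panel's rare baseline is the per-sample
  ## probability of a nonzero score, so these sites sit below the rare-site
  ## filter with high probability
  if (platform == "seq_like" && !is.null(panel$sites$is_rare) &&
      any(panel$sites$is_rare)) {
    ri <- which(panel$sites$is_rare)
    pi_ <- rowMeans(panel$profile[ri, , drop = FALSE])
    hitmat <- matrix(runif(length(ri) * n_samples), length(ri)) < pi_
    score <- matrix(0.3 + 0.4 * runif(length(ri) * n_samples), length(ri))
    bulk[ri, ] <- hitmat * score
  }

  bulk <- if (platform == "array_like") clip_range(bulk, 0, 1)
          else clip_range(bulk, 0, Inf)
  clip_frac <- attr(bulk, "clip_fraction")
  attr(bulk, "clip_fraction") <- NULL
  colnames(bulk) <- rownames(cov_df) %||%
    sprintf("%s_s%03d", study_id, seq_len(n_samples))

  phenotype_raw <- round(pmax(0, instrument_scale[[1]] +
                                 instrument_scale[[2]] * y))

  study <- structure(
    list(study_id = study_id, tissue = tissue, platform = platform,
         sites = panel$sites, values = bulk, covariates = cov_df,
         phenotype_raw = phenotype_raw, sample_n = n_samples),
    class = "MethylationStudy"
  )
  truth <- list(proportions = P, latent = y, hidden = hidden,
                clip_fraction = clip_frac)
  list(study = study, truth = truth)
}

#' @export
print.MethylationStudy <- function(x, ...) {
  cat(sprintf("MethylationStudy %s: %s %s, %d sites x %d samples\n",
              x$study_id, x$tissue, x$platform, nrow(x$values), x$sample_n))
  invisible(x)
}

#' Default consortium configuration
#'
#' Cohort identities, tissues, platforms, per-cohort sample sizes and raw
#' symptom-scale parameters mirror a two-arm consortium: five peripheral-blood
#' cohorts (one sequencing-based) totalling 2 934 samples and seven cord-blood
#' cohorts totalling 2 546. Site counts are set to a desk-scale universe
#' (see the methods vignette); planted effects echo the qualitative patterns of
#' interest: two CD8T effects shared between tissues, tissue-specific monocyte
#' and NK effects, and one sequencing-only site with opposite-direction effects
#' in monocytes and granulocytes.
#'
#' @param master_seed integer master seed.
#' @param n_sites_array size of the array-like site subset.
#' @param n_sites_seq size of the sequencing-like site universe
#'   (`>= n_sites_array`).
#' @param n_discriminating number of cell type-discriminating panel sites.
#' @param rare_frac fraction of the sequencing universe generated as rarely
#'   methylated (baseline `Beta(0.5, 50)`).
#' @param noise_sd measurement noise SD.
#' @return a config list for [simulate_consortium()].
#' @export
default_consortium_config <- function(master_seed = 20260925L,
                                      n_sites_array = 4000L,
                                      n_sites_seq = 8000L,
                                      n_discriminating = 300L,
                                      rare_frac = 0.2,
                                      noise_sd = 0.02) {
  cohort <- function(id, tissue, platform, n, mu, sd)
    list(study_id = id, tissue = tissue, platform = platform,
         n_samples = n, instrument = c(mean = mu, sd = sd))
  list(
    master_seed = master_seed,
    panel = list(n_sites_array = n_sites_array, n_sites_seq = n_sites_seq,
                 n_discriminating = n_discriminating, rare_frac = rare_frac),
    noise_sd = noise_sd,
    covariates = covariate_spec(),
    cohorts = list(
      cohort("ALSPAC_P",   "peripheral", "array_like", 694L,  4.41, 6.29),
      cohort("GenR_P",     "peripheral", "array_like", 424L,  2.45, 2.73),
      cohort("INMA_P",     "peripheral", "array_like", 168L,  3.61, 3.23),
      cohort("HELIX_P",    "peripheral", "array_like", 1065L, 3.09, 2.89),
      cohort("GSMS_P",     "peripheral", "seq_like",   583L,  0.57, 1.94),
      cohort("ALSPAC_C",   "cord", "array_like", 636L,  4.34, 6.24),
      cohort("DCHS_C",     "cord", "array_like", 75L,   1.27, 1.66),
      cohort("GECKO_C",    "cord", "array_like", 172L,  2.19, 2.67),
      cohort("GenR_C",     "cord", "array_like", 1029L, 2.58, 2.73),
      cohort("INMA_C",     "cord", "array_like", 281L,  3.51, 3.08),
      cohort("LiNA_C",     "cord", "array_like", 205L,  2.28, 3.05),
      cohort("POSEIDON_C", "cord", "array_like", 148L,  3.21, 2.54)
    ),
    study_order = list(
      peripheral = c("ALSPAC_P", "GenR_P", "INMA_P", "HELIX_P", "GSMS_P"),
      cord = c("ALSPAC_C", "DCHS_C", "GECKO_C", "GenR_C", "INMA_C",
               "LiNA_C", "POSEIDON_C")
    ),
    effects = rbind(
      effect_spec(NA, "CD8T", +0.12, c("cord", "peripheral"), "array"),
      effect_spec(NA, "CD8T", -0.12, c("cord", "peripheral"), "array"),
      effect_spec(NA, "Mono", +0.10, "cord", "array"),
      effect_spec(NA, "NK",   -0.10, "cord", "array"),
      effect_spec(NA, "Mono", +0.12, "peripheral", "seq_only"),
      effect_spec(NA, "Gran", -0.12, "peripheral", "seq_only")
    ),
    catalog = list(n_genes = 300L, n_sets = 40L)
  )
}

#' Simulate a multi-cohort consortium with a shared site universe
#'
#' Builds one sequencing-scale site universe containing an array-like subset,
#' derives platform-specific reference panels (the sequencing panel pools CD4T
#' and CD8T into CD3T), plants rarely methylated sites in the
#' sequencing-only portion, resolves planted effects to concrete sites, then
#' simulates every configured cohort with a seed derived from the master seed
#' by a fixed counter scheme (panel = master+1, site subsetting = master+2,
#' effect placement = master+3, catalog = master+4, cohort i = master+100+i),
#' so adding a cohort never perturbs existing ones.
#'
#' @param config a config list as from [default_consortium_config()].
#' @return an object of class `Consortium`: named list of studies, platform
#'   panels, gene catalog, resolved effects table and per-study truth.
#' @export
simulate_consortium <- function(config) {
  ids <- vapply(config$cohorts, `[[`, "", "study_id")
  if (anyDuplicated(ids))
    stopf("duplicate study_id: %s", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  tissues <- vapply(config$cohorts, `[[`, "", "tissue")
  for (ts in c("cord", "peripheral"))
    if (!any(tissues == ts))
      stopf("config must list at least 1 cohort per tissue; none for '%s'", ts)
  pc <- config$panel
  if (pc$n_sites_array > pc$n_sites_seq)
    stopf("array site subset cannot exceed the sequencing universe")

  master <- config$master_seed
  types_array <- default_cell_types("array_like")

  ## one universe; the array set is a subset of it
  seq_panel_full <- make_reference_panel(pc$n_sites_seq, types_array,
                                         pc$n_discriminating,
                                         seed = derive_seed(master, 1))
  m <- pc$n_sites_seq
  disc_ix <- which(seq_panel_full$sites$discriminating)
  set.seed(derive_seed(master, 2))
  pool <- setdiff(seq_len(m), disc_ix)
  array_ix <- sort(c(disc_ix, sample(pool, pc$n_sites_array - length(disc_ix))))
  seq_only <- setdiff(seq_len(m), array_ix)

  ## rarely methylated sites live in the sequencing-only portion
  n_rare <- round(pc$rare_frac * m)
  if (n_rare > length(seq_only))
    stopf("rare_frac %.2f needs %d sequencing-only sites but only %d exist",
          pc$rare_frac, n_rare, length(seq_only))
  rare_ix <- sort(sample(seq_only, n_rare))
  rare_baseline <- rbeta(n_rare, 0.5, 50)
  profile_seq6 <- seq_panel_full$profile
  profile_seq6[rare_ix, ] <- rare_baseline  # identical across cell types

  sites <- seq_panel_full$sites
  sites$is_rare <- seq_len(m) %in% rare_ix

  ## platform panels
  array_panel <- reference_panel(sites[array_ix, , drop = FALSE],
                                 profile_seq6[array_ix, , drop = FALSE],
                                 types_array)
  types_seq <- default_cell_types("seq_like")
  profile_seq <- cbind(
    CD3T = rowMeans(profile_seq6[, c("CD8T", "CD4T")]),
    Mono = profile_seq6[, "Mono"],
    Gran = profile_seq6[, "Gran"],
    Bcell = profile_seq6[, "Bcell"]
  )
  seq_panel <- reference_panel(sites, profile_seq, types_seq)

  effects <- resolve_effect_sites(config$effects, sites, array_ix, seq_only,
                                  rare_ix, seed = derive_seed(master, 3))

  catalog <- make_gene_catalog(sites,
                               n_genes = config$catalog$n_genes,
                               n_sets = config$catalog$n_sets,
                               seed = derive_seed(master, 4),
                               enriched_sites =
                                 sites[match(effects$site_id, sites$site_id), ])

  studies <- list()
  truth <- list()
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    panel <- if (co$platform == "array_like") array_panel else seq_panel
    sim <- simulate_cohort(
      panel, co$n_samples, tissue = co$tissue, platform = co$platform,
      effects = effects, covariates = config$covariates,
      noise_sd = config$noise_sd, instrument_scale = co$instrument,
      seed = derive_seed(master, 100 + i), study_id = co$study_id
    )
    studies[[co$study_id]] <- sim$study
    truth[[co$study_id]] <- sim$truth
  }

  structure(
    list(studies = studies,
         panels = list(array_like = array_panel, seq_like = seq_panel),
         catalog = catalog, effects = effects, truth = truth,
         config = config),
    class = "Consortium"
  )
}

## Assign concrete sites to effect specs whose site_id is NA: array-class
## effects go to non-rare sites in the array subset, seq_only-class effects to
## non-rare sequencing-only sites. Deterministic under seed.
resolve_effect_sites <- function(effects, sites, array_ix, seq_only, rare_ix,
                                 seed) {
  if (is.null(effects) || nrow(effects) == 0L) return(effects)
  set.seed(seed)
  pool_array <- setdiff(array_ix, rare_ix)
  pool_seq <- setdiff(seq_only, rare_ix)
  need <- is.na(effects$site_id)
  chosen_array <- sample(pool_array,
                         max(1, sum(need & effects$site_class == "array")))
  chosen_seq <- sample(pool_seq, max(1, nrow(effects)))
  ia <- 0L; is_ <- 0L
  for (r in seq_len(nrow(effects))) {
    if (!need[r]) next
    if (effects$site_class[r] == "array") {
      ia <- ia + 1L
      effects$site_id[r] <- sites$site_id[chosen_array[ia]]
    } else {
      ## opposite-direction pairs share a site: reuse the previous seq site
      ## when the preceding effect row was also seq_only
      if (r > 1L && effects$site_class[r - 1L] == "seq_only") {
        effects$site_id[r] <- effects$site_id[r - 1L]
      } else {
        is_ <- is_ + 1L
        effects$site_id[r] <- sites$site_id[chosen_seq[is_]]
      }
    }
  }
  effects
}

#' @export
print.Consortium <- function(x, ...) {
  cat(sprintf("Consortium: %d studies (%d cord, %d peripheral), %d planted effects\n",
              length(x$studies),
              sum(vapply(x$studies, `[[`, "", "tissue") == "cord"),
              sum(vapply(x$studies, `[[`, "", "tissue") == "peripheral"),
              nrow(x$effects %||% data.frame())))
  invisible(x)
}

#' Simulate a gene catalog and gene sets over a site universe
#'
#' Genes tile the simulated chromosomes with lognormal lengths, so larger
#' genes cover more CpG sites (the size bias the circular permutation must
#' absorb). Gene sets are random samples of genes with varying sizes. When
#' `enriched_sites` is given, a set named `"SET_ENRICHED"` is added whose
#' genes cover every one of those sites (a dedicated gene is created when no
#' tiled gene covers a site).
#'
#' @param sites site table with `chrom`, `pos` (defines the territory).
#' @param n_genes number of genes (>= 1).
#' @param n_sets number of random gene sets.
#' @param seed integer seed.
#' @param enriched_sites optional site table (rows of `sites`) that the
#'   enriched set must cover.
#' @param flank flank used when checking enriched-set coverage, in bp.
#' @return an object of class `GeneCatalog` with `genes` (1-based inclusive
#'   coordinates) and `gene_sets`.
#' @export
make_gene_catalog <- function(sites, n_genes, n_sets, seed,
                              enriched_sites = NULL, flank = 100000) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be >= 1")
  set.seed(seed)
  chroms <- unique(sites$chrom)
  per_chrom <- table(factor(sites$chrom, levels = chroms))
  alloc <- pmax(1L, round(n_genes * as.numeric(per_chrom) / nrow(sites)))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    ch <- chroms[ci]
    span <- range(sites$pos[sites$chrom == ch])
    k <- alloc[ci]
    len <- pmax(2000, round(rlnorm(k, log(2e4), 0.8)))
    start <- sort(sample.int(max(span[2] - span[1], k + 1), k) + span[1] - 1L)
    data.frame(chrom = ch, start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end")]

  sizes <- pmin(nrow(genes), pmax(3L, round(rlnorm(n_sets, log(10), 0.7))))
  gene_sets <- lapply(sizes, function(s) sort(sample(genes$gene_id, s)))
  names(gene_sets) <- sprintf("SET%03d", seq_len(n_sets))

  if (!is.null(enriched_sites) && nrow(enriched_sites) > 0L) {
    covered <- character(0)
    for (r in seq_len(nrow(enriched_sites))) {
      ch <- enriched_sites$chrom[r]; p <- enriched_sites$pos[r]
      hit <- genes$gene_id[genes$chrom == ch &
                             genes$start - flank <= p & p <= genes$end + flank]
      if (length(hit) == 0L) {
        g <- data.frame(gene_id = sprintf("GENE%04d", nrow(genes) + 1L),
                        chrom = ch, start = as.integer(max(1, p - 5000L)),
                        end = as.integer(p + 5000L))
        genes <- rbind(genes, g)
        hit <- g$gene_id
      }
      covered <- union(covered, hit)
    }
    gene_sets$SET_ENRICHED <- sort(covered)
  }

  catalog <- structure(list(genes = genes, gene_sets = gene_sets),
                       class = "GeneCatalog")
  validate_gene_catalog(catalog)
  catalog
}

validate_gene_catalog <- function(catalog) {
  g <- catalog$genes
  if (any(g$start >= g$end)) stopf("gene start must be < end")
  if (any(g$start < 1)) stopf("gene coordinates are 1-based; start must be >= 1")
  members <- unique(unlist(catalog$gene_sets, use.names = FALSE))
  missing <- setdiff(members, g$gene_id)
  if (length(missing) > 0L)
    stopf("gene-set members absent from gene table: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  invisible(catalog)
}

#' @export
print.GeneCatalog <- function(x, ...) {
  cat(sprintf("GeneCatalog: %d genes, %d gene sets\n",
              nrow(x$genes), length(x$gene_sets)))
  invisible(x)
}
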