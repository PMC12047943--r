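test_that("reference panel generator plants the requested discriminating sites", {
  p <- make_reference_panel(1000, default_cell_types("array_like"), 200,
                            seed = 1)
  rng <- apply(p$profile, 1, function(r) max(r) - min(r))
  expect_identical(sum(rng >= 0.3), 200L)
  expect_identical(which(rng >= 0.3), which(p$sites$discriminating))
  expect_true(all(p$profile >= 0 & p$profile <= 1))
  for (ch in unique(p$sites$chrom))
    expect_true(all(diff(p$sites$pos[p$sites$chrom == ch]) > 0))
})

test_that("panel generation is deterministic and validates its arguments", {
  a <- make_reference_panel(200, c("A", "B", "C"), 50, seed = 7)
  b <- make_reference_panel(200, c("A", "B", "C"), 50, seed = 7)
  expect_identical(a, b)
  expect_error(make_reference_panel(100, "onlyone", 10, seed = 1),
               "at least 2 cell types")
  expect_error(reference_panel(a$sites, a$profile, c("A", "A", "C")),
               "duplicated")
})

test_that("a panel without discriminating sites is reported as rank deficient", {
  p <- make_reference_panel(300, c("A", "B", "C"), 0, seed = 3)
  bulk <- p$profile %*% t(ctmwas:::rdirichlet(5, c(1, 1, 1)))
  expect_error(estimate_proportions(bulk, p$profile), "rank deficient")
})

test_that("bulk values are the exact panel mixture when noise and effects are off", {
  p <- fixture_panel(n_sites = 200L)
  onehot <- matrix(0, 1, 6); onehot[1, 1] <- 1
  sim <- simulate_cohort(p, 1, covariates = NULL, noise_sd = 0,
                         proportions = onehot, seed = 5)
  expect_equal(unname(drop(sim$study$values)), unname(p$profile[, "CD8T"]),
               tolerance = 0)

  P <- ctmwas:::rdirichlet(8, rep(1, 6))
  sim2 <- simulate_cohort(p, 8, covariates = NULL, noise_sd = 0,
                          proportions = P, seed = 6)
  expect_equal(unname(sim2$study$values), unname(p$profile %*% t(P)),
               tolerance = 1e-14)
})

test_that("true proportions lie on the unit simplex and phenotype follows the instrument map", {
  p <- fixture_panel()
  sim <- fixture_cohort(p, n = 150L, seed = 9,
                        instrument_scale = c(mean = 2.5, sd = 3))
  P <- sim$truth$proportions
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P >= 0))
  expect_identical(sim$study$phenotype_raw,
                   round(pmax(0, 2.5 + 3 * sim$truth$latent)))
  expect_error(simulate_cohort(p, 10, noise_sd = -0.1), "nonnegative")
})

test_that("cohort simulation is deterministic under its seed", {
  p <- fixture_panel(n_sites = 150L)
  a <- fixture_cohort(p, n = 40L, seed = 17)
  b <- fixture_cohort(p, n = 40L, seed = 17)
  expect_identical(a, b)
})

test_that("with no planted effects the phenotype-methylation association is null", {
  p <- fixture_panel(n_sites = 2000L)
  sim <- fixture_cohort(p, n = 250L, seed = 33, covariates = NULL)
  y <- standardize_phenotype(sim$study$phenotype_raw)
  meth <- residualize(sim$study$values, NULL)
  props <- estimate_proportions(sim$study$values, p$profile)
  res <- celltype_association(meth, y, props, sites = sim$study$sites)
  for (ct in unique(res$cell_type)) {
    ks <- ks.test(res$p[res$cell_type == ct], "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("consortium simulation validates config and keeps bookkeeping", {
  cfg <- fixture_config()
  cons <- simulate_consortium(cfg)
  n_per <- vapply(cons$studies, `[[`, 0L, "sample_n")
  tissues <- vapply(cons$studies, `[[`, "", "tissue")
  expect_identical(sum(n_per[tissues == "peripheral"]), 320L)
  expect_identical(sum(n_per[tissues == "cord"]), 220L)

  ## array site set is a subset of the sequencing universe
  arr <- cons$panels$array_like$sites
  seqs <- cons$panels$seq_like$sites
  expect_true(all(paste(arr$chrom, arr$pos) %in% paste(seqs$chrom, seqs$pos)))

  cfg_dup <- cfg
  cfg_dup$cohorts[[2]]$study_id <- "P1"
  expect_error(simulate_consortium(cfg_dup), "duplicate study_id")

  cfg_onearm <- cfg
  cfg_onearm$cohorts <- cfg$cohorts[1:3]
  expect_error(simulate_consortium(cfg_onearm), "per tissue")
})

test_that("adding a cohort at the end does not perturb the existing ones", {
  cfg <- fixture_config()
  cons_a <- simulate_consortium(cfg)
  cfg_b <- cfg
  cfg_b$cohorts <- c(cfg$cohorts, list(
    list(study_id = "EXTRA", tissue = "cord", platform = "array_like",
         n_samples = 80L, instrument = c(mean = 2, sd = 2))))
  cons_b <- simulate_consortium(cfg_b)
  expect_identical(cons_a$studies$P1$values, cons_b$studies$P1$values)
  expect_identical(cons_a$studies$C2$values, cons_b$studies$C2$values)
})

test_that("the planted rare-site fraction is removed by the default filter", {
  cfg <- fixture_config(n_array = 2000L, n_seq = 10000L)
  cfg$panel$rare_frac <- 0.2
  cons <- simulate_consortium(cfg)
  st <- cons$studies$PS
  f <- filter_rare_sites(st)
  expect_lt(abs(f$n_removed / nrow(st$sites) - 0.2), 0.02)
})

test_that("effect specs are validated and resolved to concrete eligible sites", {
  expect_error(effect_spec("cg1", "CD8T", 0.7), "0.5")
  expect_error(effect_spec("cg1", "CD8T", 0.1, tissues = "brain"), "subset")

  eff <- rbind(effect_spec(NA, "Mono", 0.1, "peripheral", "array"),
               effect_spec(NA, "Gran", -0.1, "peripheral", "seq_only"))
  cfg <- fixture_config(effects = eff)
  cons <- simulate_consortium(cfg)
  expect_false(anyNA(cons$effects$site_id))
  sites <- cons$panels$seq_like$sites
  expect_false(any(sites$is_rare[match(cons$effects$site_id, sites$site_id)]))
  arr_ids <- cons$panels$array_like$sites$site_id
  expect_true(cons$effects$site_id[1] %in% arr_ids)
  expect_false(cons$effects$site_id[2] %in% arr_ids)
})

test_that("gene catalogs are deterministic, valid, and cover enriched sites", {
  p <- fixture_panel(n_sites = 300L)
  a <- make_gene_catalog(p$sites, n_genes = 40L, n_sets = 6L, seed = 2,
                         enriched_sites = p$sites[c(5, 100), ])
  b <- make_gene_catalog(p$sites, n_genes = 40L, n_sets = 6L, seed = 2,
                         enriched_sites = p$sites[c(5, 100), ])
  expect_identical(a, b)
  expect_true(all(a$genes$start < a$genes$end))
  expect_true("SET_ENRICHED" %in% names(a$gene_sets))
  map <- map_sites_to_genes(p$sites[c(5, 100), ], a, flank = 100000)
  expect_true(all(vapply(map, function(g)
    any(g %in% a$gene_sets$SET_ENRICHED), logical(1))))
  expect_error(make_gene_catalog(p$sites, 0L, 2L, seed = 1), ">= 1")
})
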