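test_that("suggestive selection uses a strict threshold", {
  meta <- list(table = data.frame(chrom = "1", pos = 1:3,
                                  site_id = c("a", "b", "c"),
                                  cell_type = "CD8T",
                                  q = c(0.4, 0.5, 0.6)))
  tab <- select_suggestive(meta, 0.5)
  expect_identical(tab$suggestive, c(1L, 0L, 0L))
  expect_identical(select_suggestive(list(table = within(meta$table, q <- 1)),
                                     0.5)$suggestive, c(0L, 0L, 0L))
})

test_that("site-to-gene mapping has inclusive flank bounds and matches brute force", {
  catalog <- structure(list(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "1",
                       start = c(5000L, 40000L), end = c(9000L, 45000L)),
    gene_sets = list(S = c("g1", "g2"))), class = "GeneCatalog")
  flank <- 1000
  sites <- data.frame(chrom = "1",
                      pos = c(9000L + flank, 9000L + flank + 1L, 3999L, 4000L),
                      site_id = paste0("s", 1:4))
  map <- map_sites_to_genes(sites, catalog, flank)
  expect_identical(map$s1, "g1")       # exactly at end + flank
  expect_identical(map$s2, character(0))
  expect_identical(map$s3, character(0))
  expect_identical(map$s4, "g1")       # exactly at start - flank

  ## random instance vs all-pairs brute force
  p <- fixture_panel(n_sites = 300L)
  cat2 <- make_gene_catalog(p$sites, 50L, 4L, seed = 8)
  got <- map_sites_to_genes(p$sites, cat2, flank = 20000)
  brute <- lapply(seq_len(nrow(p$sites)), function(i) {
    g <- cat2$genes
    hit <- g$chrom == p$sites$chrom[i] &
      g$start - 20000 <= p$sites$pos[i] & p$sites$pos[i] <= g$end + 20000
    sort(g$gene_id[hit])
  })
  names(brute) <- p$sites$site_id
  expect_identical(got, brute)
})

test_that("exhaustive circular permutation equals brute-force enumeration", {
  ind <- c(1, 1, rep(0, 8))
  mem <- c(1, 1, rep(0, 8))
  r <- circular_permutation_test(ind, mem, mode = "exhaustive")
  ## brute force over all 9 rotations
  rot <- function(x, d) x[((seq_along(x) - 1 + d) %% length(x)) + 1]
  null_stats <- vapply(1:9, function(d) sum(rot(ind, d) * mem), numeric(1))
  p_brute <- (1 + sum(null_stats >= 2)) / 10
  expect_equal(r$p_empirical, p_brute)
  expect_identical(r$observed_stat, 2)
  expect_identical(r$n_perm, 9L)

  ## saturated membership: every rotation ties the observed statistic
  r2 <- circular_permutation_test(c(1, 0, 1, 0, 0), rep(1, 5),
                                  mode = "exhaustive")
  expect_equal(r2$p_empirical, 1)
})

test_that("sampled rotations are seed-deterministic, conservative floored, and auto-switch", {
  set.seed(9)
  ind <- rbinom(200, 1, 0.1); mem <- rbinom(200, 1, 0.2)
  a <- circular_permutation_test(ind, mem, n_perm = 99, seed = 5)
  b <- circular_permutation_test(ind, mem, n_perm = 99, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p_empirical, 1 / 100)

  expect_message(
    sw <- circular_permutation_test(ind, mem, n_perm = 10000, seed = 5),
    "exhaustive")
  expect_identical(sw$mode, "exhaustive")
  expect_identical(sw$n_perm, 199L)

  ## sampled p agrees with exhaustive within Monte-Carlo error
  ex <- circular_permutation_test(ind, mem, mode = "exhaustive")
  expect_lt(abs(a$p_empirical - ex$p_empirical),
            3 * sqrt(ex$p_empirical * (1 - ex$p_empirical) / 99) + 0.02)
})

test_that("rotation preserves indicator autocorrelation that iid shuffles destroy", {
  ## blockwise-correlated indicator: runs of suggestive sites
  set.seed(10)
  m <- 600
  ind <- rep(rbinom(60, 1, 0.2), each = 10)
  mem <- rep(rbinom(60, 1, 0.3), each = 10)
  rot_stats <- ctmwas:::rotation_null_stats(ind, mem)
  shuf_stats <- replicate(599, sum(sample(ind) * mem))
  expect_gt(var(rot_stats), var(shuf_stats))
})

test_that("enrichment over a planted signal flags the enriched set and skips empty ones", {
  p <- fixture_panel(n_sites = 500L)
  planted <- c(40L, 41L, 200L, 201L, 350L)
  catalog <- make_gene_catalog(p$sites, 60L, 5L, seed = 12,
                               enriched_sites = p$sites[planted, ],
                               flank = 2000)
  q <- rep(0.9, 500)
  q[planted] <- 0.01
  meta <- list(table = data.frame(chrom = p$sites$chrom, pos = p$sites$pos,
                                  site_id = p$sites$site_id,
                                  cell_type = "CD8T", q = q))
  res <- suppressWarnings(
    run_enrichment(meta, catalog, flank = 2000, n_perm = 499, seed = 3))
  enr <- res[res$set_id == "SET_ENRICHED", ]
  expect_lte(enr$p_empirical, 0.05)
  expect_identical(enr$observed_stat, 5)

  res2 <- suppressWarnings(
    run_enrichment(meta, catalog, flank = 2000, n_perm = 499, seed = 3))
  expect_identical(res, res2)

  catalog$gene_sets$EMPTY <- character(0)
  expect_warning(run_enrichment(meta, catalog, flank = 2000, n_perm = 99,
                                seed = 3), "empty")
})
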