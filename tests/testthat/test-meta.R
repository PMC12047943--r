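test_that("Stouffer combination matches its closed forms and an independent oracle", {
  expect_equal(stouffer_meta(1.7, 100), 1.7)
  expect_equal(stouffer_meta(c(1, 1), c(50, 50)), sqrt(2))
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    z <- rnorm(k); n <- sample(50:2000, k)
    oracle <- sum(sqrt(n) * z) / sqrt(sum(n))   # independent evaluation
    expect_equal(stouffer_meta(z, n), oracle, tolerance = 1e-12)
  }
  expect_warning(out <- stouffer_meta(c(1, NaN), c(10, 10)), "non-finite")
  expect_equal(out, 1)
})

test_that("heterogeneity statistic has its closed forms and null chi-square law", {
  h <- heterogeneity_test(c(1.3, 1.3, 1.3), c(70, 70, 70))
  expect_equal(h$het_q, 0, tolerance = 1e-12)
  expect_equal(h$het_p, 1)

  h2 <- heterogeneity_test(c(2, -2), c(100, 100))
  expect_equal(h2$het_q, 8, tolerance = 1e-12)
  expect_equal(h2$het_p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(h2$het_p, 0.004678, tolerance = 1e-3)

  expect_true(is.na(heterogeneity_test(1.2, 50)$het_q))

  ## under homogeneity z_k ~ N(delta*sqrt(n_k), 1), het_q ~ chi2(k-1)
  set.seed(2)
  k <- 4; n <- c(100, 400, 900, 250); delta <- 0.05
  qs <- replicate(4000, {
    z <- rnorm(k, delta * sqrt(n), 1)
    heterogeneity_test(z, n)$het_q
  })
  expect_gt(ks.test(qs, pchisq, df = k - 1)$p.value, 0.01)
})

test_that("BH step-up matches hand evaluation and the reference implementation", {
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(1000)^2
  expect_lt(max(abs(bh_fdr(p) - p.adjust(p, "BH"))), 1e-12)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

## Build minimal CellTypeMWASResult-like objects for alignment tests.
mock_mwas <- function(study_id, tissue, platform, sites, cell_types, z, n) {
  grid <- expand.grid(site = seq_len(nrow(sites)), ct = cell_types,
                      stringsAsFactors = FALSE)
  res <- data.frame(site_id = sites$site_id[grid$site],
                    chrom = sites$chrom[grid$site], pos = sites$pos[grid$site],
                    cell_type = grid$ct, n = n, df = n - 2,
                    effect = z[cbind(grid$site, match(grid$ct, cell_types))],
                    z = z[cbind(grid$site, match(grid$ct, cell_types))],
                    stringsAsFactors = FALSE)
  res$p <- z_to_p(res$z)
  structure(list(study_id = study_id, tissue = tissue, platform = platform,
                 n = n, results = res),
            class = "CellTypeMWASResult")
}

sites3 <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                     site_id = c("s1", "s2", "s3"))

test_that("alignment duplicates pooled T-cell results into both mapped streams", {
  za <- matrix(rnorm(6), 3, 2); zb <- matrix(rnorm(6), 3, 2)
  zs <- matrix(rnorm(3), 3, 1)
  a <- mock_mwas("A", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), za, 100)
  b <- mock_mwas("B", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), zb, 150)
  s <- mock_mwas("S", "peripheral", "seq_like", sites3, "CD3T", zs, 80)
  al <- align_studies(list(a, b, s))
  long <- al$long
  for (ct in c("CD8T", "CD4T"))
    expect_identical(sum(long$cell_type == ct & long$study_id == "S"), 3L)
  expect_equal(long$z[long$study_id == "S" & long$cell_type == "CD8T"],
               long$z[long$study_id == "S" & long$cell_type == "CD4T"])
  expect_false("CD3T" %in% long$cell_type)

  dup <- a
  dup$results <- rbind(dup$results, dup$results[1, ])
  expect_error(align_studies(list(dup)), "duplicated")
})

test_that("meta-analysis records coverage, direction order, and per-cell-type FDR", {
  za <- matrix(c(2, 1, -1, 0.5, 0.2, -0.4), 3, 2)
  zb <- matrix(c(1.5, 0.8, -2, 0.1, -0.3, 0.2), 3, 2)
  a <- mock_mwas("A", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), za, 100)
  b <- mock_mwas("B", "peripheral", "array_like", sites3[1:2, ],
                 c("CD8T", "CD4T"), zb[1:2, , drop = FALSE], 150)
  m <- meta_analyze(list(a, b), study_order = c("A", "B"))
  tab <- m$table
  row3 <- tab[tab$site_id == "s3" & tab$cell_type == "CD8T", ]
  expect_identical(row3$k, 1L)
  expect_identical(substr(row3$direction, 2, 2), "?")
  row1 <- tab[tab$site_id == "s1" & tab$cell_type == "CD8T", ]
  expect_identical(row1$direction, "++")
  expect_equal(row1$z_meta,
               (sqrt(100) * 2 + sqrt(150) * 1.5) / sqrt(250), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p))

  ## permutation invariance: study order affects only the direction string
  m2 <- meta_analyze(list(b, a), study_order = c("B", "A"))
  t1 <- m$table[order(m$table$site_id, m$table$cell_type), ]
  t2 <- m2$table[order(m2$table$site_id, m2$table$cell_type), ]
  expect_equal(t1$z_meta, t2$z_meta, tolerance = 1e-12)
  expect_equal(t1$het_q, t2$het_q, tolerance = 1e-12)
  expect_identical(t2[t2$site_id == "s1" & t2$cell_type == "CD8T", ]$direction,
                   "++")
})

test_that("Stouffer z is standard normal under the per-study null", {
  set.seed(4)
  n <- c(120, 400, 800)
  zm <- replicate(10000, stouffer_meta(rnorm(3), n))
  expect_lt(abs(mean(zm)), 0.03)
  expect_lt(abs(var(zm) - 1), 0.05)
})

test_that("leave-one-out recomputes the reduced combination", {
  za <- matrix(rnorm(6), 3, 2); zb <- matrix(rnorm(6), 3, 2)
  zc <- matrix(rnorm(6), 3, 2)
  studies <- list(
    mock_mwas("A", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), za, 100),
    mock_mwas("B", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), zb, 150),
    mock_mwas("C", "peripheral", "array_like", sites3, c("CD8T", "CD4T"), zc, 80))
  loo <- leave_one_out(studies, "C", study_order = c("A", "B", "C"))
  direct <- meta_analyze(studies[1:2], study_order = c("A", "B"))
  expect_equal(loo$table$z_meta, direct$table$z_meta, tolerance = 1e-12)
  expect_error(leave_one_out(studies, "NOPE"), "not among")

  ## removing the only pooled-T-cell study collapses CD4T/CD8T to array-only
  s <- mock_mwas("S", "peripheral", "seq_like", sites3, "CD3T",
                 matrix(rnorm(3), 3, 1), 90)
  with_s <- list(studies[[1]], studies[[2]], s)
  loo_s <- leave_one_out(with_s, "S", study_order = c("A", "B", "S"))
  arr_only <- meta_analyze(studies[1:2], study_order = c("A", "B"))
  expect_equal(loo_s$table$z_meta, arr_only$table$z_meta, tolerance = 1e-12)
})

test_that("QQ diagnostics are calibrated on uniform p-values", {
  p <- (seq_len(2000) - 0.5) / 2000
  qd <- qq_diagnostics(p)
  expect_equal(qd$lambda, 1, tolerance = 0.02)
  inside <- with(qd$table, observed >= lower & observed <= upper)
  expect_gte(mean(inside), 0.95)

  ## planted signal lifts the extreme tail above the band
  p2 <- p
  p2[1:20] <- p2[1:20] * 1e-8
  qd2 <- qq_diagnostics(p2)
  expect_true(any(qd2$table$observed > qd2$table$upper))
})
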