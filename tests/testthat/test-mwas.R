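test_that("phenotype standardization is exact and affine invariant", {
  expect_equal(standardize_phenotype(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(0, 1, 1, 3, 7, 2)
  expect_equal(standardize_phenotype(x), standardize_phenotype(5 * x - 11))
  z <- standardize_phenotype(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_error(standardize_phenotype(rep(2, 10)), "constant")

  ## low-mean high-skew count instrument still standardizes cleanly
  set.seed(1)
  raw <- round(pmax(0, 0.57 + 1.94 * rnorm(500)))
  zz <- standardize_phenotype(raw)
  expect_lt(abs(mean(zz)), 1e-12)
  expect_equal(sd(zz), 1)
})

test_that("rare-site filtering removes silent sites and spares arrays", {
  p <- fixture_panel(n_sites = 60L)
  sim <- simulate_cohort(p, 30, platform = "seq_like", seed = 3,
                         covariates = NULL)
  st <- sim$study
  st$values[5, ] <- 0
  f <- filter_rare_sites(st)
  expect_true("cg00000005" %in% f$removed_site_ids)
  expect_identical(nrow(f$study$values), nrow(st$values) - f$n_removed)

  arr <- sim$study
  arr$platform <- "array_like"
  arr$values[5, ] <- 0
  f2 <- filter_rare_sites(arr)
  expect_identical(f2$n_removed, 0L)
  expect_identical(f2$study, arr)
})

test_that("residualization is exact OLS with orthogonal residuals", {
  set.seed(5)
  n <- 50; m <- 30
  covs <- data.frame(age = rnorm(n), sex = factor(sample(c("F", "M"), n, TRUE)))
  M <- matrix(rnorm(m * n), m, n)

  ## intercept only = centering
  cen <- residualize(M, NULL)
  expect_equal(cen, M - rowMeans(M), tolerance = 1e-12)

  ## exactly linear signal vanishes
  lin <- outer(rnorm(m), covs$age) + 2
  expect_lt(max(abs(residualize(lin, data.frame(age = covs$age)))), 1e-10)

  res <- residualize(M, covs)
  X <- model.matrix(~ ., covs)
  expect_lt(max(abs(t(X) %*% t(res))), 1e-8)
  expect_equal(t(res), pinv_residuals(t(M), X), tolerance = 1e-10)

  covs$age2 <- 2 * covs$age
  expect_error(residualize(M, covs), "age2")
})

test_that("the confounder principal component recovers a hidden batch", {
  p <- fixture_panel(n_sites = 1000L)
  cs <- covariate_spec(hidden_frac = 0.3, hidden_shift = 0.1)
  sim <- fixture_cohort(p, n = 150L, seed = 7, covariates = cs)
  meth <- residualize(sim$study$values, sim$study$covariates)
  pc1 <- capture_hidden_confounder(meth)
  expect_gte(abs(cor(pc1, sim$truth$hidden)), 0.9)

  ## duplicated samples get identical scores
  dup <- cbind(meth, meth[, 1:3])
  pc_dup <- capture_hidden_confounder(dup)
  expect_equal(pc_dup[151:153], pc_dup[1:3], tolerance = 1e-8)

  expect_error(capture_hidden_confounder(meth[, 1:2, drop = FALSE]),
               "3 samples")
})

test_that("interaction-model coefficients match the normal-equations oracle", {
  p <- fixture_panel(n_sites = 80L)
  sim <- fixture_cohort(p, n = 100L, seed = 9, covariates = NULL)
  y <- standardize_phenotype(sim$study$phenotype_raw)
  props <- estimate_proportions(sim$study$values, p$profile)
  meth <- residualize(sim$study$values, NULL)
  res <- celltype_association(meth, y, props, sites = sim$study$sites,
                              exclude_low_proportion = FALSE)

  X <- cbind(props$values, props$values * y)
  B <- solve(t(X) %*% X, t(X) %*% t(meth))   # brute-force normal equations
  for (t in seq_len(6)) {
    got <- res$effect[res$cell_type == p$cell_types[t]]
    expect_equal(got, unname(B[6 + t, ]), tolerance = 1e-8)
  }
  ## p is exactly the two-sided normal tail of z
  expect_lt(max(abs(res$p - 2 * pnorm(-abs(res$z)))), 1e-12)
  expect_true(all(sign(res$z) == sign(res$effect) | res$z == 0))
  expect_true(all(res$df == 100 - 12))
})

test_that("two-stage residualization agrees with the joint fit on orthogonalized covariates", {
  p <- fixture_panel(n_sites = 40L)
  sim <- fixture_cohort(p, n = 90L, seed = 10, covariates = NULL)
  y <- standardize_phenotype(sim$study$phenotype_raw)
  props <- estimate_proportions(sim$study$values, p$profile)
  X_int <- cbind(props$values, props$values * y)

  set.seed(11)
  raw_cov <- cbind(rnorm(90), rnorm(90))
  C <- qr.resid(qr(X_int), raw_cov)   # covariates orthogonal to interactions

  meth <- sim$study$values
  two_stage <- celltype_association(
    residualize(meth, as.data.frame(C)), y, props,
    exclude_low_proportion = FALSE)

  X_joint <- cbind(X_int, C)
  B <- qr.coef(qr(X_joint), t(meth))
  for (t in seq_len(6)) {
    got <- two_stage$effect[two_stage$cell_type == p$cell_types[t]]
    expect_equal(got, unname(B[6 + t, ]), tolerance = 1e-6)
  }
})

test_that("low-proportion cell types are excluded from reports with a record", {
  p <- fixture_panel(n_sites = 150L)
  alpha <- default_dirichlet_alpha(p$cell_types)
  alpha["Bcell"] <- 0.03
  sim <- simulate_cohort(p, 130, dirichlet_alpha = alpha, seed = 13,
                         covariates = NULL)
  y <- standardize_phenotype(sim$study$phenotype_raw)
  props <- estimate_proportions(sim$study$values, p$profile)
  res <- celltype_association(residualize(sim$study$values, NULL), y, props)
  expect_true("Bcell" %in% attr(res, "excluded_cell_types"))
  expect_false("Bcell" %in% res$cell_type)
})

test_that("z-to-p uses an accurate two-sided normal tail", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(7.875), 3.41e-15, tolerance = 0.005)
  expect_equal(z_to_p(-5.614), 1.98e-8, tolerance = 0.005)
  ## far tail stays positive and finite
  expect_gt(z_to_p(38), 0)
  expect_lt(z_to_p(38), 1e-300)
  ## symmetric in sign
  expect_identical(z_to_p(3.2), z_to_p(-3.2))
})

test_that("t-to-z conversion preserves the two-sided p-value", {
  for (df in c(10, 100, 2000)) {
    tstat <- c(-8.5, -1.2, 0, 0.7, 4.4, 12)
    z <- ctmwas:::t_to_z(tstat, df)
    expect_equal(z_to_p(z), 2 * pt(-abs(tstat), df), tolerance = 1e-12)
    expect_identical(sign(z), sign(tstat))
  }
})

test_that("genomic inflation is calibrated on exact quantiles and scales as z^2", {
  z <- qnorm((seq_len(10001) - 0.5) / 10001)
  expect_equal(genomic_inflation(z), 1, tolerance = 1e-3)
  expect_equal(genomic_inflation(2 * z), 4 * genomic_inflation(z),
               tolerance = 1e-12)
  expect_error(genomic_inflation(rnorm(50)), ">= 100")
})

test_that("planted effects are detected in the right cell type with the right sign", {
  p <- fixture_panel(n_sites = 400L)
  eff <- effect_spec("cg00000050", "Mono", 0.1, "peripheral")
  sim <- fixture_cohort(p, n = 500L, seed = 15, effects = eff,
                        covariates = NULL)
  r <- run_celltype_mwas(sim$study, p)
  at_site <- r$results[r$results$site_id == "cg00000050", ]
  mono <- at_site[at_site$cell_type == "Mono", ]
  expect_gt(mono$z, 0)
  expect_lt(mono$p, 1e-4)
})
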