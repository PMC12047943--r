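# Fixtures are built in code; sizes are kept small so the default run stays
# fast while still exercising every stage.

fixture_panel <- function(n_sites = 400L, cell_types = default_cell_types(),
                          n_discriminating = min(150L, n_sites %/% 2L),
                          seed = 11L) {
  make_reference_panel(n_sites, cell_types, n_discriminating, seed = seed)
}

fixture_cohort <- function(panel = fixture_panel(), n = 120L, seed = 21L,
                           effects = NULL, tissue = "peripheral",
                           noise_sd = 0.02, covariates = covariate_spec(),
                           study_id = "FIX1", ...) {
  simulate_cohort(panel, n, tissue = tissue, platform = "array_like",
                  effects = effects, covariates = covariates,
                  noise_sd = noise_sd, seed = seed, study_id = study_id, ...)
}

# Small two-tissue consortium config used by pipeline-level tests.
fixture_config <- function(master_seed = 31L, n_array = 600L, n_seq = 1200L,
                           effects = NULL) {
  cfg <- default_consortium_config(master_seed = master_seed,
                                   n_sites_array = n_array,
                                   n_sites_seq = n_seq,
                                   n_discriminating = 120L)
  cfg$cohorts <- list(
    list(study_id = "P1", tissue = "peripheral", platform = "array_like",
         n_samples = 120L, instrument = c(mean = 3, sd = 3)),
    list(study_id = "P2", tissue = "peripheral", platform = "array_like",
         n_samples = 100L, instrument = c(mean = 2.5, sd = 2.7)),
    list(study_id = "PS", tissue = "peripheral", platform = "seq_like",
         n_samples = 100L, instrument = c(mean = 0.57, sd = 1.94)),
    list(study_id = "C1", tissue = "cord", platform = "array_like",
         n_samples = 120L, instrument = c(mean = 4.3, sd = 6.2)),
    list(study_id = "C2", tissue = "cord", platform = "array_like",
         n_samples = 100L, instrument = c(mean = 2.6, sd = 2.7))
  )
  cfg$study_order <- list(peripheral = c("P1", "P2", "PS"),
                          cord = c("C1", "C2"))
  cfg$effects <- effects
  cfg$catalog <- list(n_genes = 60L, n_sets = 10L)
  cfg
}

# Independent OLS oracle: residuals via the explicit pseudoinverse.
pinv_residuals <- function(M_samples_by_vars, X) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  unname(M_samples_by_vars - H %*% M_samples_by_vars)
}
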