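test_that("simulation is deterministic given the seed", {
  cfg <- small_config(seed = 91)
  s1 <- simulate_section(cfg)
  s2 <- simulate_section(cfg)
  expect_identical(s1$dataset$specimens, s2$dataset$specimens)
  expect_identical(s1$truth$proxies, s2$truth$proxies)
  s3 <- simulate_section(small_config(seed = 92))
  expect_false(identical(s1$dataset$specimens, s3$dataset$specimens))
})

test_that("occupancy limits species ranges", {
  sim <- simulate_section(small_config(seed = 93))
  sp <- sim$dataset$specimens
  expect_false(any(sp$taxon == "Bsp" & sp$bed_id %in% c("B4", "B5")))
  expect_false(any(sp$taxon == "Csp" & sp$bed_id %in% c("B1", "B2")))
})

test_that("drawn measurement triples reproduce the drawn GM exactly", {
  sim <- simulate_section(small_config(seed = 94))
  obs <- suppressMessages(size_observations(sim$dataset))
  sp <- sim$dataset$specimens[match(obs$specimen_id,
                                    sim$dataset$specimens$specimen_id), ]
  expect_equal(obs$gm_mm,
               geometric_mean(sp$dv_mm, sp$dl_mm, sp$length_mm))
})

test_that("zero beta_temp yields zero true within components under fixed composition", {
  cfg <- small_config(seed = 95, beta_a = 0)
  td <- truth_decomposition(cfg)
  # beds B3 -> B4 share taxa A and Csp; all betas are zero so crosser medians
  # are bed-invariant
  row <- td[td$bed_from == "B3", ]
  expect_equal(row$within_mm, 0, tolerance = 1e-9)
})

test_that("single-species truth puts the whole shift in the within component", {
  cfg <- synthetic_config(
    seed = 96, n_beds = 2,
    species = list(synthetic_species("A", log_mu = log(20), beta_temp = 0.2,
                                     occupancy = c(TRUE, TRUE),
                                     lambda_per_m2 = 10)),
    proxies = list(d18O = list(mean = c(-1, -2), phi = 0.1,
                               innovation_sd = 0.01),
                   d13C = list(mean = 1, phi = 0.1, innovation_sd = 0.01),
                   hg_toc = list(mean = 0.05, phi = 0.1,
                                 innovation_sd = 0.005)),
    lithology_sequence = c("marl", "limestone"))
  td <- truth_decomposition(cfg)
  expect_equal(td$disappearance_mm, 0)
  expect_equal(td$appearance_mm, 0)
  expect_equal(td$within_mm, td$total_shift_mm)
  expect_lt(td$within_mm, 0)  # warming excursion shrinks the species
})

test_that("pipeline decomposition recovers the mixture-quantile truth", {
  # large per-bed samples so empirical medians approach population medians
  cfg <- synthetic_config(
    seed = 97, n_beds = 3,
    species = list(
      synthetic_species("A", log_mu = log(20), beta_temp = 0.25,
                        occupancy = rep(TRUE, 3), lambda_per_m2 = 250),
      synthetic_species("Bsp", log_mu = log(30),
                        occupancy = c(TRUE, TRUE, FALSE),
                        lambda_per_m2 = 120)),
    proxies = list(d18O = list(mean = c(-1, -1.8, -1.4), phi = 0.2,
                               innovation_sd = 0.02),
                   d13C = list(mean = 1, phi = 0.2, innovation_sd = 0.05),
                   hg_toc = list(mean = 0.05, phi = 0.2,
                                 innovation_sd = 0.005)),
    lithology_sequence = c("marl", "limestone", "marl"),
    n_quadrats_per_bed = 2, fragment_fraction = 0,
    n_offquadrat_per_bed = 0)
  sim <- simulate_section(cfg)
  obs <- suppressMessages(size_observations(sim$dataset))
  truth <- sim$truth$decomposition
  med1 <- sim$truth$assemblage_median$median_mm[1]
  for (i in seq_len(nrow(truth))) {
    d <- decompose_shift(obs, truth$bed_from[i], truth$bed_to[i])
    expect_lt(abs(d$total_shift_mm - truth$total_shift_mm[i]), 0.05 * med1)
    expect_lt(abs(d$within_mm - truth$within_mm[i]), 0.05 * med1)
    expect_lt(abs(d$disappearance_mm - truth$disappearance_mm[i]),
              0.05 * med1)
  }
})

test_that("empirical juvenile fractions track the configured value", {
  sim <- simulate_section(small_config(seed = 98))
  obs <- suppressMessages(size_observations(sim$dataset))
  st <- suppressWarnings(stage_proportions(obs, sim$dataset$beds))
  covered <- mapply(function(lo, hi) lo <= 0.35 & 0.35 <= hi,
                    st$ci_low, st$ci_high)
  expect_gte(mean(covered), 0.6)  # a few beds may miss at small n
})

test_that("YAML config round-trips through write/read", {
  skip_if_not_installed("yaml")
  cfg <- small_config(seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$species, cfg$species, tolerance = 1e-12)
  expect_equal(cfg2$proxies, cfg$proxies, tolerance = 1e-12)
  s1 <- simulate_section(cfg)$dataset$specimens
  s2 <- simulate_section(cfg2)$dataset$specimens
  expect_identical(s2[c("specimen_id", "bed_id", "taxon", "stage",
                        "completeness", "quadrat_id")],
                   s1[c("specimen_id", "bed_id", "taxon", "stage",
                        "completeness", "quadrat_id")])
  expect_equal(s2$dv_mm, s1$dv_mm, tolerance = 1e-12)
})

test_that("invalid configuration fields are named in the error", {
  cfg <- small_config(seed = 1)
  cfg$species[[1]]$occupancy <- TRUE
  expect_error(simulate_section(cfg), "occupancy",
               class = "belem_validation_error")
  cfg2 <- small_config(seed = 1)
  cfg2$fragment_fraction <- 1.4
  expect_error(simulate_section(cfg2), "fragment_fraction",
               class = "belem_validation_error")
})
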