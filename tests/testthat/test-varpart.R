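# helper: observation table with controllable factor structure
vp_obs <- function(n = 240, seed = 51, effects = c(taxon = 1, stage = 0,
                                                   bed = 0), sigma = 1) {
  set.seed(seed)
  taxon <- sample(c("A", "Bsp", "Csp"), n, replace = TRUE)
  stage <- sample(c("adult", "juvenile"), n, replace = TRUE)
  bed <- sample(paste0("P", 1:4), n, replace = TRUE)
  y <- 20 + effects[["taxon"]] * as.numeric(factor(taxon)) +
    effects[["stage"]] * as.numeric(factor(stage)) +
    effects[["bed"]] * as.numeric(factor(bed)) + rnorm(n, 0, sigma)
  data.frame(specimen_id = sprintf("s%04d", seq_len(n)), bed_id = bed,
             taxon = taxon, stage = stage, gm_mm = y,
             volume_proxy_mm3 = y^3, stringsAsFactors = FALSE)
}

test_that("factor encoding is full-rank with most-frequent reference", {
  obs <- data.frame(specimen_id = letters[1:6], bed_id = rep(c("P1", "P2"), 3),
                    taxon = c("A", "A", "A", "Bsp", "Bsp", "Csp"),
                    stage = rep(c("adult", "juvenile"), 3),
                    gm_mm = 1:6, stringsAsFactors = FALSE)
  f <- encode_factors(obs)
  expect_equal(ncol(f$taxon), 2)        # 3 taxa -> 2 indicators
  expect_equal(ncol(f$ontogeny), 1)     # 2 stages -> 1 indicator
  # reference level "A" (most frequent) never appears as a column
  expect_false(any(grepl("taxon.A", colnames(f$taxon), fixed = TRUE)))
  obs$bed_id <- "P1"
  expect_error(encode_factors(obs), "bed", class = "belem_validation_error")
})

test_that("adjusted R2 matches the Ezekiel formula and guards its domain", {
  # R^2 = 0.5, n = 11, p = 1  ->  0.4444...
  set.seed(52)
  x <- rnorm(11)
  # construct y with exact sample R^2 = 0.5 via orthogonal residual
  e <- resid(lm(rnorm(11) ~ x))
  xs <- resid(lm(x ~ 1))
  y <- xs / sqrt(sum(xs^2)) + e / sqrt(sum(e^2))
  expect_equal(summary(lm(y ~ x))$r.squared, 0.5, tolerance = 1e-12)
  expect_equal(adjusted_r2(y, cbind(x)), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(y, cbind(x)), summary(lm(y ~ x))$adj.r.squared)
  expect_error(adjusted_r2(y, cbind(x, x)), class = "belem_domain_error")
  expect_error(adjusted_r2(y[1:3], cbind(x[1:3], rnorm(3))),
               class = "belem_domain_error")
})

test_that("partition matches the brute-force inclusion-exclusion oracle", {
  obs <- vp_obs(effects = c(taxon = 1.5, stage = 0.8, bed = 0.4), sigma = 1)
  vp <- partition_size_variation(obs, n_perm = 49, seed = 1)

  f <- encode_factors(obs[order(obs$specimen_id), ])
  A <- function(...) bf_adj_r2(obs$gm_mm[order(obs$specimen_id)],
                               do.call(cbind, list(...)))
  aT <- A(f$taxon); aO <- A(f$ontogeny); aB <- A(f$bed)
  aTO <- A(f$taxon, f$ontogeny); aTB <- A(f$taxon, f$bed)
  aOB <- A(f$ontogeny, f$bed); aTOB <- A(f$taxon, f$ontogeny, f$bed)
  expect_equal(vp$fraction_taxon, aTOB - aOB, tolerance = 1e-10)
  expect_equal(vp$fraction_ontogeny, aTOB - aTB, tolerance = 1e-10)
  expect_equal(vp$fraction_bed, aTOB - aTO, tolerance = 1e-10)
  expect_equal(vp$joint_taxon_ontogeny, aTB + aOB - aTOB - aB,
               tolerance = 1e-10)
  expect_equal(vp$joint_taxon_bed, aTO + aOB - aTOB - aO, tolerance = 1e-10)
  expect_equal(vp$joint_ontogeny_bed, aTO + aTB - aTOB - aT,
               tolerance = 1e-10)
  # all seven fractions + residual sum to one exactly
  total <- vp$fraction_taxon + vp$fraction_ontogeny + vp$fraction_bed +
    vp$joint_taxon_ontogeny + vp$joint_taxon_bed + vp$joint_ontogeny_bed +
    vp$joint_all + vp$residual
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("partition agrees with vegan::varpart on the same design", {
  skip_if_not_installed("vegan")
  obs <- vp_obs(n = 200, seed = 53,
                effects = c(taxon = 1, stage = 0.5, bed = 0.3))
  vp <- partition_size_variation(obs, n_perm = 9, seed = 1)
  o <- obs[order(obs$specimen_id), ]
  vv <- vegan::varpart(o$gm_mm, ~taxon, ~stage, ~bed_id, data = o)
  ind <- vv$part$indfract$Adj.R.square  # a, b, c, d, e, f, g, residual
  expect_equal(vp$fraction_taxon, ind[1], tolerance = 1e-8)
  expect_equal(vp$fraction_ontogeny, ind[2], tolerance = 1e-8)
  expect_equal(vp$fraction_bed, ind[3], tolerance = 1e-8)
  expect_equal(vp$joint_all, ind[7], tolerance = 1e-8)
  expect_equal(vp$residual, ind[8], tolerance = 1e-8)
})

test_that("a taxon-only signal loads on the taxon fraction", {
  obs <- vp_obs(n = 400, seed = 54, effects = c(taxon = 3, stage = 0, bed = 0),
                sigma = 0.05)
  vp <- partition_size_variation(obs, n_perm = 99, seed = 2)
  expect_gt(vp$fraction_taxon, 0.95)
  for (f in c("fraction_ontogeny", "fraction_bed", "joint_taxon_ontogeny",
              "joint_taxon_bed", "joint_ontogeny_bed", "joint_all"))
    expect_lt(abs(vp[[f]]), 0.02)
  expect_equal(partition_significance(vp, "unique_taxon"), 1 / 100)
})

test_that("pure-noise fractions are near zero and never clamped", {
  obs <- vp_obs(n = 200, seed = 55, effects = c(taxon = 0, stage = 0, bed = 0))
  vp <- partition_size_variation(obs, n_perm = 49, seed = 3)
  for (f in c("fraction_taxon", "fraction_ontogeny", "fraction_bed"))
    expect_lt(abs(vp[[f]]), 0.05)
  # adjusted fractions can be negative; at least one usually is under the null
  all8 <- c(vp$fraction_taxon, vp$fraction_ontogeny, vp$fraction_bed,
            vp$joint_taxon_ontogeny, vp$joint_taxon_bed,
            vp$joint_ontogeny_bed, vp$joint_all)
  expect_true(any(all8 < 0))
})

test_that("partition is invariant to observation shuffling", {
  obs <- vp_obs(n = 150, seed = 56, effects = c(taxon = 1, stage = 1, bed = 0))
  vp1 <- partition_size_variation(obs, n_perm = 19, seed = 4)
  vp2 <- partition_size_variation(obs[sample(nrow(obs)), ], n_perm = 19,
                                  seed = 4)
  expect_equal(vp1$fraction_taxon, vp2$fraction_taxon)
  expect_equal(vp1$p_values, vp2$p_values)
})

test_that("the three-way joint fraction is not testable", {
  obs <- vp_obs(n = 100, seed = 57)
  vp <- partition_size_variation(obs, n_perm = 9, seed = 5)
  expect_error(partition_significance(vp, "joint_all"),
               class = "belem_domain_error")
  expect_true(all(vp$p_values >= 1 / 10 & vp$p_values <= 1))
})
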