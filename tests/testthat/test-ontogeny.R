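test_that("Wilson interval matches the score-interval oracle", {
  ci <- wilson_ci(8, 16)
  expect_equal(unname(ci[c("lower", "upper")]), c(0.2799956, 0.7200044),
               tolerance = 1e-6)
  # prop.test without continuity correction is the Wilson interval
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:60, 1); x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    or <- suppressWarnings(prop.test(x, n, correct = FALSE)$conf.int)
    expect_equal(unname(ci[c("lower", "upper")]), as.numeric(or),
                 tolerance = 1e-9)
    expect_gte(ci[["lower"]], 0)
    expect_lte(ci[["upper"]], 1)
  }
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
})

test_that("stage proportions exclude indeterminate stages and warn on empties", {
  sp <- rbind(
    make_specimens(rep("P1", 8), stage = "juvenile", prefix = "j"),
    make_specimens(rep("P1", 8), stage = "adult", prefix = "a"),
    make_specimens(rep("P1", 3), stage = "indeterminate", prefix = "i"),
    make_specimens(rep("P2", 2), stage = "indeterminate", prefix = "k"))
  ds <- belem_dataset(sp, make_beds(2))
  obs <- size_observations(ds)
  expect_warning(st <- stage_proportions(obs, ds$beds), "P2")
  expect_equal(nrow(st), 1)
  expect_equal(st$n_adult + st$n_juvenile, 16L)
  expect_equal(st$prop_juvenile, 0.5)
  expect_equal(st$ci_low, 0.28, tolerance = 1e-2)
})

test_that("a multi-taxon scope aggregates the member species' counts", {
  sp <- rbind(
    make_specimens(rep("P1", 4), taxon = "Pa bi", stage = "juvenile",
                   prefix = "x"),
    make_specimens(rep("P1", 6), taxon = "Pa mi", stage = "adult",
                   prefix = "y"),
    make_specimens(rep("P1", 5), taxon = "Other", stage = "juvenile",
                   prefix = "z"))
  ds <- belem_dataset(sp, make_beds(1))
  obs <- size_observations(ds)
  genus <- stage_proportions(obs, ds$beds, taxon = c("Pa bi", "Pa mi"))
  expect_equal(genus$n_juvenile, 4L)
  expect_equal(genus$n_adult, 6L)
  s1 <- stage_proportions(obs, ds$beds, taxon = "Pa bi")
  s2 <- stage_proportions(obs, ds$beds, taxon = "Pa mi")
  expect_equal(genus$n_juvenile + genus$n_adult,
               s1$n_juvenile + s1$n_adult + s2$n_juvenile + s2$n_adult)
})

test_that("stage_shift recovers an injected adult-only decline", {
  set.seed(42)
  n <- 60
  mk <- function(bed, mu_a, mu_j, prefix) rbind(
    make_specimens(rep(bed, n), stage = "adult",
                   gm = exp(rnorm(n, mu_a, 0.1)), prefix = paste0(prefix, "a")),
    make_specimens(rep(bed, n), stage = "juvenile",
                   gm = exp(rnorm(n, mu_j, 0.1)), prefix = paste0(prefix, "j")))
  sp <- rbind(mk("P1", log(20), log(10), "p"),
              mk("P2", log(20) - 0.2, log(10), "q"))
  sp$specimen_id <- sprintf("s%03d", seq_len(nrow(sp)))
  ds <- belem_dataset(sp, make_beds(2))
  obs <- size_observations(ds)
  ad <- stage_shift(obs, "A", "adult", "P1", "P2")
  ju <- stage_shift(obs, "A", "juvenile", "P1", "P2")
  expect_false(ad$insufficient_data)
  expect_equal(ad$pct_change_logratio, -20, tolerance = 0.25)
  expect_lt(ad$p_mannwhitney, 0.001)
  expect_equal(ju$pct_change_logratio, 0, tolerance = 6)
  expect_gt(ju$p_mannwhitney, 0.05)
  # absent subset -> marker, no p-values
  none <- stage_shift(obs, "A", "indeterminate", "P1", "P2")
  expect_true(none$insufficient_data)
  expect_true(is.na(none$p_mannwhitney))
})

test_that("battery supports H1/H3/H4 only under an adult+juvenile lineage decline", {
  set.seed(43)
  n <- 80
  mk <- function(bed, shift, prefix) rbind(
    make_specimens(rep(bed, n), taxon = "A", stage = "adult",
                   gm = exp(rnorm(n, log(20) + shift, 0.1)),
                   prefix = paste0(prefix, 1)),
    make_specimens(rep(bed, round(n / 2)), taxon = "A", stage = "juvenile",
                   gm = exp(rnorm(round(n / 2), log(10) + shift, 0.1)),
                   prefix = paste0(prefix, 2)),
    make_specimens(rep(bed, round(n / 3)), taxon = "Bsp", stage = "adult",
                   gm = exp(rnorm(round(n / 3), log(30), 0.1)),
                   prefix = paste0(prefix, 3)))
  sp <- rbind(mk("P1", 0, "u"), mk("P2", -0.25, "v"))
  sp$specimen_id <- sprintf("s%03d", seq_len(nrow(sp)))
  ds <- belem_dataset(sp, make_beds(2))
  b <- hypothesis_battery(ds, "P1", "P2")
  expect_equal(unname(b$verdicts[c("H1", "H3", "H4")]),
               rep("supported", 3))
  expect_equal(unname(b$verdicts[c("H2", "H5")]),
               rep("not_supported", 2))
})

test_that("identical beds support nothing", {
  ds <- make_gm_dataset(list(P1 = list(A = c(5, 6, 7, 8, 9), Bsp = c(2, 3)),
                             P2 = list(A = c(5, 6, 7, 8, 9), Bsp = c(2, 3))))
  b <- hypothesis_battery(ds, "P1", "P2")
  expect_true(all(b$verdicts %in% c("not_supported", "insufficient_data")))
})

test_that("a doubled juvenile fraction with stable adult sizes flips H5 not H4", {
  set.seed(44)
  mk <- function(bed, n_j, prefix) rbind(
    make_specimens(rep(bed, 60), taxon = "A", stage = "adult",
                   gm = exp(rnorm(60, log(20), 0.1)),
                   prefix = paste0(prefix, 1)),
    make_specimens(rep(bed, n_j), taxon = "A", stage = "juvenile",
                   gm = exp(rnorm(n_j, log(10), 0.1)),
                   prefix = paste0(prefix, 2)))
  sp <- rbind(mk("P1", 20, "u"), mk("P2", 60, "v"))
  sp$specimen_id <- sprintf("s%03d", seq_len(nrow(sp)))
  ds <- belem_dataset(sp, make_beds(2))
  b <- hypothesis_battery(ds, "P1", "P2")
  expect_equal(unname(b$verdicts[["H5"]]), "supported")
  expect_equal(unname(b$verdicts[["H4"]]), "not_supported")
  # verdicts are re-derivable from the emitted table
  h5 <- b$table[b$table$hypothesis == "H5", ]
  expect_lt(h5$p_primary, 0.05)
})
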