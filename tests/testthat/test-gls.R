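test_that("rho = 0 reproduces OLS exactly", {
  set.seed(61)
  n <- 80
  x <- rnorm(n)
  y <- 2 + 0.5 * x + rnorm(n)
  f <- fit_gls_ar1(y, cbind(1, x = x), rho = 0)
  ols <- lm(y ~ x)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("profile ML log-likelihood matches the dense-covariance oracle", {
  set.seed(62)
  n <- 50
  x <- rnorm(n)
  e <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- 1 + 2 * x + e
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_gls_ar1(y, X)
  oracle <- bf_ar1_loglik(y, X, coef(f), f$rho, f$sigma2)
  expect_equal(f$loglik, as.numeric(oracle), tolerance = 1e-6)
})

test_that("fit agrees with nlme::gls under ML and corAR1", {
  skip_if_not_installed("nlme")
  set.seed(63)
  n <- 150
  x <- rnorm(n); z <- rnorm(n)
  y <- 1 - 2 * x + 0.5 * z + as.numeric(arima.sim(list(ar = 0.6), n))
  d <- data.frame(y = y, x = x, z = z)
  f <- gls_ar1(y ~ x + z, d)
  g <- nlme::gls(y ~ x + z, d, correlation = nlme::corAR1(form = ~1),
                 method = "ML")
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-5)
  expect_equal(f$rho,
               as.numeric(coef(g$modelStruct$corStruct,
                               unconstrained = FALSE)), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("observations are ordered by the stratigraphic key, not input order", {
  set.seed(64)
  n <- 100
  x <- rnorm(n)
  y <- 1 + x + as.numeric(arima.sim(list(ar = 0.7), n))
  shuffle <- sample(n)
  f1 <- fit_gls_ar1(y, cbind(1, x = x), order_key = seq_len(n))
  f2 <- fit_gls_ar1(y[shuffle], cbind(1, x = x[shuffle]),
                    order_key = seq_len(n)[shuffle])
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$rho, f2$rho)
  expect_equal(residuals(f2), residuals(f1)[shuffle], ignore_attr = TRUE)
})

test_that("AICc matches its formula, exceeds AIC, and converges to it", {
  expect_equal(aicc(-100, 3, 30), 206.9231, tolerance = 1e-4)
  expect_equal(aicc(-50, 0, 10), 100)
  aic <- function(ll, k) -2 * ll + 2 * k
  expect_gt(aicc(-100, 3, 30), aic(-100, 3))
  expect_equal(aicc(-100, 3, 1e9), aic(-100, 3), tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), class = "belem_domain_error")
})

test_that("model ranking computes deltas over all candidates with tie-breaks", {
  mkfit <- function(ll, k, id) structure(
    list(loglik = ll, k = as.integer(k), n = 100L, aicc = aicc(ll, k, 100),
         rho = 0, model_id = id, terms_label = paste0("m", id),
         coefficients = c(`(Intercept)` = 0), y_checksum = c(10, 20)),
    class = "gls_ar1")
  fits <- list(mkfit(-47, 3, 1), mkfit(-46, 4, 2), mkfit(-45.05, 3, 3))
  tab <- rank_models(fits)
  expect_equal(min(tab$delta_aicc), 0)
  expect_equal(sum(tab$delta_aicc == 0), 1)
  expect_equal(tab$model_id[1], 3)
  expect_equal(tab$retained, c(TRUE, FALSE, FALSE))
  # equal AICc: ranked by k then id
  fits2 <- list(mkfit(-46, 4, 2), mkfit(-45, 3, 1))
  expect_equal(rank_models(fits2)$model_id, c(1, 2))
  bad <- mkfit(-10, 3, 4); bad$n <- 50L
  expect_error(rank_models(c(fits, list(bad))), class = "belem_domain_error")
})

test_that("likelihood-ratio test against the null matches chi-square tails", {
  mk <- function(ll, terms) structure(
    list(loglik = ll, p = length(terms), n = 100L,
         coefficients = stats::setNames(rep(0, length(terms)), terms),
         y_checksum = c(1, 2)), class = "gls_ar1")
  best <- mk(-958, c("(Intercept)", "d18O"))
  null <- mk(-959.5, "(Intercept)")
  p <- compare_to_null(best, null)
  expect_equal(attr(p, "statistic"), 3)
  expect_equal(as.numeric(p), 0.08326452, tolerance = 1e-7)
  tied <- mk(-959.5, c("(Intercept)", "d18O"))
  expect_equal(as.numeric(compare_to_null(tied, null)), 1)
  expect_error(compare_to_null(null, null), class = "belem_domain_error")
  other <- mk(-950, c("(Intercept)", "hg_toc"))
  expect_error(compare_to_null(best, other), class = "belem_domain_error")
})

test_that("parameter recovery at rho = 0.6, beta = -2 over seeded replicates", {
  set.seed(65)
  n <- 400
  reps <- 30
  betas <- rhos <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- 1 - 2 * x + as.numeric(arima.sim(list(ar = 0.6), n))
    f <- fit_gls_ar1(y, cbind(1, x = x))
    betas[r] <- coef(f)[["x"]]
    rhos[r] <- f$rho
  }
  expect_equal(mean(betas), -2, tolerance = 0.1)
  expect_equal(mean(rhos), 0.6, tolerance = 0.1)
})

test_that("residualize regresses out lithology and abundance jointly", {
  ds <- make_gm_dataset(list(P1 = list(A = c(4, 5, 6)),
                             P2 = list(A = c(6, 7, 8)),
                             P3 = list(A = c(8, 9, 10))))
  obs <- size_observations(ds)
  ab <- data.frame(bed_id = c("P1", "P2", "P3"),
                   n_specimens_quadrats = c(4L, 8L, 12L), area_m2 = 2,
                   density_per_m2 = c(2, 4, 6))
  r <- residualize(obs, ds$beds, ab)
  # gm = 3 + 0.5 * abundance within-bed centred noise: residuals sum to 0
  expect_equal(sum(r), 0, tolerance = 1e-10)
  # gm is an exact linear function of abundance once lithology is constant
  ds2 <- ds; ds2$beds$lithology <- "marl"
  obs2 <- obs; obs2$gm_mm <- 2 + 0.5 * ab$density_per_m2[match(obs2$bed_id,
                                                               ab$bed_id)]
  expect_equal(max(abs(residualize(obs2, ds2$beds, ab))), 0,
               tolerance = 1e-10)
  expect_error(residualize(rbind(obs, transform(obs[1, ], bed_id = "PX",
                                                specimen_id = "zz")),
                           ds$beds, ab),
               "PX", class = "belem_referential_error")
})

test_that("collinearity screen flags near-duplicate variables", {
  set.seed(66)
  x <- rnorm(30)
  out <- collinearity(data.frame(a = x, b = 2 * x, c = rnorm(30)))
  ab <- out$flags[out$flags$var1 == "a" & out$flags$var2 == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$flagged)
  ac <- out$flags[out$flags$var1 == "a" & out$flags$var2 == "c", ]
  expect_false(ac$flagged)
  # hand-check r on three points
  d3 <- data.frame(u = c(1, 2, 4), v = c(2, 1, 5))
  expect_equal(collinearity(d3)$cor["u", "v"], cor(d3$u, d3$v))
  cst <- collinearity(data.frame(k = rep(1, 10), w = rnorm(10)))
  expect_true(all(cst$flags$flagged[is.na(cst$flags$r)]))
})

test_that("model selection recovers a pure d18O driver on synthetic data", {
  # constant composition: the only bed-level structure is the d18O signal
  cfg <- synthetic_config(
    seed = 77, n_beds = 6,
    species = list(synthetic_species("A", log_mu = log(20), beta_temp = 0.3,
                                     occupancy = rep(TRUE, 6),
                                     lambda_per_m2 = 25)),
    proxies = list(d18O = list(mean = c(-1, -2, -1.2, -1.8, -1, -1.6),
                               phi = 0.2, innovation_sd = 0.05),
                   d13C = list(mean = 1.5, phi = 0.2, innovation_sd = 0.1),
                   hg_toc = list(mean = 0.05, phi = 0.2,
                                 innovation_sd = 0.01)),
    lithology_sequence = rep(c("marl", "limestone"), 3),
    n_quadrats_per_bed = 2, n_offquadrat_per_bed = 20)
  sim <- simulate_section(cfg)
  ms <- run_model_selection(sim$dataset, correct_sedimentary = FALSE)
  expect_equal(nrow(ms$table), 7)
  expect_true("d18O" %in% strsplit(ms$table$terms[1], "+", fixed = TRUE)[[1]])
  expect_lt(ms$table$delta_aicc[ms$table$terms == "1"], Inf)
  expect_true(all(ms$table$delta_aicc >= 0))
  expect_equal(sum(ms$table$delta_aicc == 0), 1)
})

test_that("model selection refuses windows with missing proxies", {
  sim <- simulate_section(small_config(seed = 78))
  ds <- sim$dataset
  ds$proxies$d18O_permil[2] <- NA
  ds <- belem_dataset(ds$specimens, ds$beds, ds$proxies)
  expect_error(run_model_selection(ds, window = paste0("B", 1:3)),
               "B2", class = "belem_referential_error")
})
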