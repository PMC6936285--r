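# Fixture builders and independent oracles shared across the suite.

make_beds <- function(n = 3, n_quadrats = 2, pool_group = NA_character_) {
  data.frame(bed_id = paste0("P", seq_len(n)), order_index = seq_len(n),
             height_m = (seq_len(n) - 1) * 2,
             zone = rep("Z", n),
             lithology = rep(c("marl", "marly_limestone", "limestone"),
                             length.out = n),
             n_quadrats = rep_len(n_quadrats, n),
             quadrat_area_m2 = 1, pool_group = rep_len(pool_group, n),
             stringsAsFactors = FALSE)
}

make_specimens <- function(bed_id, taxon = "A", stage = "adult",
                           gm = NULL, dv = 2, dl = 4, len = 8,
                           completeness = "complete", quadrat_id = NA,
                           prefix = "s") {
  n <- max(length(bed_id), length(taxon), length(stage), length(dv),
           if (is.null(gm)) 0 else length(gm))
  if (!is.null(gm)) {
    # back-solve an equal-sided triple so geometric_mean() returns gm exactly
    dv <- dl <- len <- rep_len(gm, n)
  }
  data.frame(specimen_id = paste0(prefix, seq_len(n)),
             bed_id = rep_len(bed_id, n), taxon = rep_len(taxon, n),
             stage = rep_len(stage, n),
             completeness = rep_len(completeness, n),
             source = "calliper",
             dv_mm = rep_len(dv, n), dl_mm = rep_len(dl, n),
             length_mm = rep_len(len, n),
             quadrat_id = rep_len(as.character(quadrat_id), n),
             stringsAsFactors = FALSE)
}

# dataset with given per-bed/taxon gm values: sizes is a named list
# bed -> named list taxon -> numeric gm vector
make_gm_dataset <- function(sizes, stage = "adult", n_quadrats = 2) {
  rows <- list(); k <- 0
  for (bed in names(sizes)) for (tx in names(sizes[[bed]])) {
    g <- sizes[[bed]][[tx]]
    if (!length(g)) next
    rows[[length(rows) + 1]] <-
      make_specimens(bed, taxon = tx, stage = stage, gm = g,
                     prefix = sprintf("s%d_", k <- k + 1))
  }
  sp <- do.call(rbind, rows)
  sp$specimen_id <- sprintf("sp%04d", seq_len(nrow(sp)))
  beds <- make_beds(length(sizes))
  beds$bed_id <- names(sizes)
  belem_dataset(sp, beds)
}

# ---- brute-force oracles ---------------------------------------------------

# exact two-sided Mann-Whitney p by explicit enumeration of all label
# assignments (midranks kept as-is)
bf_mw_p <- function(x, y) {
  pooled <- c(x, y); n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  mu <- n * (N + 1) / 2
  w_obs <- sum(r[seq_len(n)])
  idx <- utils::combn(N, n)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-sided KS p by explicit enumeration
bf_ks <- function(x, y) {
  pooled <- c(x, y); n <- length(x); m <- length(y); N <- n + m
  dstat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), 0.0)))
  }
  d_obs <- dstat(x, y)
  idx <- utils::combn(N, n)
  ds <- apply(idx, 2, function(i) dstat(pooled[i], pooled[-i]))
  list(d = d_obs, p = mean(ds >= d_obs - 1e-9))
}

# independent adjusted-R2 via lm() for the variation-partitioning oracle
bf_adj_r2 <- function(y, X) {
  d <- data.frame(y = y, X)
  summary(stats::lm(y ~ ., data = d))$adj.r.squared
}

# dense-covariance AR(1) Gaussian log-likelihood oracle
bf_ar1_loglik <- function(y, X, beta, rho, sigma2_marginal) {
  n <- length(y)
  S <- sigma2_marginal * rho^abs(outer(seq_len(n), seq_len(n), "-"))
  r <- y - drop(as.matrix(X) %*% beta)
  -0.5 * (n * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
            drop(crossprod(r, solve(S, r))))
}

# small synthetic config for fast pipeline-level tests
small_config <- function(seed = 7, beta_a = 0.2) {
  synthetic_species_list <- list(
    synthetic_species("A", log_mu = log(18), beta_temp = beta_a,
                      occupancy = rep(TRUE, 5), lambda_per_m2 = 15),
    synthetic_species("Bsp", log_mu = log(24), occupancy = c(TRUE, TRUE, TRUE,
                                                             FALSE, FALSE),
                      lambda_per_m2 = 6),
    synthetic_species("Csp", log_mu = log(12),
                      occupancy = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                      lambda_per_m2 = 6))
  synthetic_config(
    seed = seed, n_beds = 5, species = synthetic_species_list,
    proxies = list(
      d18O = list(mean = c(-1, -1, -2, -1.5, -1.2), phi = 0.4,
                  innovation_sd = 0.05),
      d13C = list(mean = 1.5, phi = 0.4, innovation_sd = 0.1),
      hg_toc = list(mean = 0.05, phi = 0.3, innovation_sd = 0.01)),
    lithology_sequence = c("marl", "limestone", "marl", "limestone", "marl"),
    n_quadrats_per_bed = 2, n_offquadrat_per_bed = 20,
    boundary_pair = c("B2", "B3"))
}
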