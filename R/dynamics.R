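#' Per-bed body-size summaries
#'
#' Median and quartiles of the geometric-mean size per bed, in stratigraphic
#' order, optionally restricted to a taxon and/or ontogenetic stage. Beds with
#' no eligible observation are omitted. Summaries with n < 5 are flagged
#' `low_n`; they are still computed, but bed pooling (see [pool_beds()]) is
#' the usual remedy.
#'
#' @param obs size observation table from [size_observations()].
#' @param beds bed table (for stratigraphic order).
#' @param taxon optional taxon name(s) to restrict to.
#' @param stage optional stage (`"adult"` or `"juvenile"`) to restrict to.
#' @return data.frame: `bed_id`, `scope`, `n`, `median_gm_mm`, `q25_mm`,
#'   `q75_mm`, `low_n`, ordered by `order_index`.
#' @export
bed_summaries <- function(obs, beds, taxon = NULL, stage = NULL) {
  obs <- .filter_scope(obs, taxon, stage)
  scope <- .scope_label(taxon, stage)
  beds <- beds[order(beds$order_index), , drop = FALSE]
  rows <- lapply(beds$bed_id, function(b) {
    g <- obs$gm_mm[obs$bed_id == b]
    if (!length(g)) return(NULL)
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bed_id = b, scope = scope, n = length(g), median_gm_mm = q[2],
               q25_mm = q[1], q75_mm = q[3], low_n = length(g) < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bed_id = character(), scope = character(), n = integer(),
                      median_gm_mm = numeric(), q25_mm = numeric(),
                      q75_mm = numeric(), low_n = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.filter_scope <- function(obs, taxon = NULL, stage = NULL) {
  if (!is.null(taxon)) {
    bad <- setdiff(taxon, unique(obs$taxon))
    if (length(bad))
      belem_error("belem_validation_error",
                  "unknown taxon %s; valid: %s", paste(bad, collapse = ", "),
                  paste(sort(unique(obs$taxon)), collapse = ", "))
    obs <- obs[obs$taxon %in% taxon, , drop = FALSE]
  }
  if (!is.null(stage)) {
    if (!all(stage %in% .stage_levels))
      belem_error("belem_validation_error",
                  "unknown stage %s; valid: %s", paste(stage, collapse = ", "),
                  paste(.stage_levels, collapse = ", "))
    obs <- obs[obs$stage %in% stage, , drop = FALSE]
  }
  obs
}

.scope_label <- function(taxon = NULL, stage = NULL) {
  if (is.null(taxon) && is.null(stage)) return("assemblage")
  paste(c(if (!is.null(taxon)) paste(taxon, collapse = "+"),
          if (!is.null(stage)) paste(stage, collapse = "+")), collapse = ":")
}

#' Proportional change between two medians as a percentage of the log ratio
#'
#' `ln(median_to / median_from) * 100`. Negative values are decreases; the
#' statistic is antisymmetric under swapping the beds and additive over
#' consecutive pairs, and magnitudes above 100 are legal (a log-ratio of -1.09
#' prints as a "109%" decrease).
#'
#' @param median_from,median_to positive medians (mm, or any common unit).
#' @return Percent change on the log-ratio scale.
#' @export
proportional_change <- function(median_from, median_to) {
  if (any(!is.finite(c(median_from, median_to))) ||
      any(c(median_from, median_to) <= 0))
    belem_error("belem_domain_error", "medians must be positive and finite")
  log(median_to / median_from) * 100
}

#' Convert a GM log-ratio change to the volume-proxy change
#'
#' The volume proxy is the cube of the geometric mean, so on the log-ratio
#' percent scale a GM change maps to exactly three times itself:
#' a 17% GM decrease is a 51% volume decrease.
#'
#' @param pct_gm percent change of GM on the log-ratio scale.
#' @return Percent change of the volume proxy (3 times the input).
#' @export
gm_to_volume_change <- function(pct_gm) {
  if (any(!is.finite(pct_gm)))
    belem_error("belem_domain_error", "input must be finite")
  3 * pct_gm
}

## ---- exact two-sample tests under the permutation null (tie-aware) --------
## Both p-values are computed over all choose(n+m, n) label assignments of the
## pooled sample, by dynamic programming over tied-value groups with binomial
## multiplicities (never by explicit enumeration).

.tie_groups <- function(x, y) {
  pooled <- c(x, y)
  tv <- sort(unique(pooled))
  list(values = tv,
       count = vapply(tv, function(v) sum(pooled == v), 0L),
       n = length(x), m = length(y))
}

## exact two-sided Mann-Whitney p: P(|W - mu| >= |w_obs - mu|) where W is the
## (midrank) rank sum of the first sample; doubled ranks keep arithmetic integer
.exact_mw_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r2 <- as.integer(round(2 * rank(pooled)))
  w2_obs <- sum(r2[seq_len(n)])
  g <- .tie_groups(x, y)
  r2g <- as.integer(round(2 * rank(sort(pooled))))[cumsum(g$count)]  # doubled midrank per group
  S <- sum(as.numeric(r2))
  ways <- matrix(0, nrow = n + 1, ncol = S + 1)
  ways[1, 1] <- 1
  for (gi in seq_along(g$count)) {
    cg <- g$count[gi]; rg <- r2g[gi]
    new <- ways
    for (a in seq_len(min(cg, n))) {
      co <- choose(cg, a); sh <- a * rg
      rows <- seq_len(n + 1 - a)
      new[rows + a, (sh + 1):(S + 1)] <-
        new[rows + a, (sh + 1):(S + 1)] + ways[rows, seq_len(S + 1 - sh)] * co
    }
    ways <- new
  }
  dist <- ways[n + 1, ]
  s_vals <- 0:S
  mu2 <- n * (N + 1)
  dev_obs <- abs(w2_obs - mu2)
  sum(dist[abs(s_vals - mu2) >= dev_obs - 1e-9]) / choose(N, n)
}

## exact two-sided Kolmogorov-Smirnov p: P(D >= D_obs) by counting allocations
## whose every tie-group boundary deviation |i*m - j*n| stays below the
## observed integer numerator d_obs = D_obs * n * m
.exact_ks <- function(x, y) {
  n <- length(x); m <- length(y)
  g <- .tie_groups(x, y)
  cx <- vapply(g$values, function(v) sum(x == v), 0L)
  cum_i <- cumsum(cx); cum_j <- cumsum(g$count - cx)
  d_obs <- max(abs(cum_i * m - cum_j * n))
  ways <- numeric(n + 1); ways[1] <- 1
  Tcum <- 0L
  for (gi in seq_along(g$count)) {
    cg <- g$count[gi]
    new <- numeric(n + 1)
    for (a in 0:min(cg, n)) {
      co <- choose(cg, a)
      idx <- seq_len(n + 1 - a)
      new[idx + a] <- new[idx + a] + ways[idx] * co
    }
    Tcum <- Tcum + cg
    i <- 0:n
    bad <- abs(i * m - (Tcum - i) * n) >= d_obs | (Tcum - i) > m | i > Tcum
    new[bad] <- 0
    ways <- new
  }
  list(d = d_obs / (n * m), p = 1 - ways[n + 1] / choose(n + m, n))
}

#' Two-sample tests for a body-size shift between beds
#'
#' Computes two-sided Mann-Whitney U and Kolmogorov-Smirnov p-values for the
#' difference between two samples of per-specimen sizes. In `exact` mode both
#' p-values are taken over the full permutation null of the pooled sample
#' (ties kept as-is, handled by dynamic programming over tie groups); in
#' `asymptotic` mode the Mann-Whitney test uses midranks with the tie-corrected
#' normal approximation and continuity correction, and the KS test uses the
#' asymptotic two-sample distribution. `auto` selects the exact computation
#' when `length(x) * length(y) <= 10000`.
#'
#' @param sizes_from,sizes_to numeric samples (e.g. `gm_mm` of two beds).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return list with `p_mannwhitney`, `p_ks`, `statistic_u`, `statistic_d`,
#'   `method` (the method actually used) and `degenerate` (`TRUE` when all
#'   pooled values are identical, in which case both p-values are 1).
#' @export
pairwise_tests <- function(sizes_from, sizes_to,
                           method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  x <- sizes_from; y <- sizes_to
  if (!length(x) || !length(y))
    belem_error("belem_domain_error", "both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_stat <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(p_mannwhitney = 1.0, p_ks = 1.0, statistic_u = u_stat,
                statistic_d = 0.0, method = "degenerate", degenerate = TRUE))
  }
  use_exact <- switch(method, exact = TRUE, asymptotic = FALSE,
                      auto = n * m <= 10000)
  if (use_exact) {
    ks <- .exact_ks(x, y)
    list(p_mannwhitney = .exact_mw_p(x, y), p_ks = ks$p,
         statistic_u = u_stat, statistic_d = ks$d,
         method = "exact", degenerate = FALSE)
  } else {
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    list(p_mannwhitney = unname(mw$p.value), p_ks = unname(ks$p.value),
         statistic_u = u_stat, statistic_d = unname(ks$statistic),
         method = "asymptotic", degenerate = FALSE)
  }
}

#' Log-ratio shifts and tests between consecutive beds
#'
#' For every stratigraphically consecutive pair of beds that both hold at
#' least one eligible observation (beds without observations are skipped, so
#' a barren interval is bridged by its flanking beds), computes the
#' proportional median change and the two-sample tests. `significant`
#' requires BOTH tests below `alpha`; per-test p-values are always emitted so
#' either criterion can be applied. No multiple-testing correction is applied
#' across bed pairs.
#'
#' @inheritParams bed_summaries
#' @param alpha significance level (default 0.05).
#' @param method test method passed to [pairwise_tests()].
#' @return data.frame with columns `bed_from`, `bed_to`, `scope`,
#'   `pct_change_logratio`, `p_mannwhitney`, `p_ks`, `n_from`, `n_to`,
#'   `significant`, `low_n`.
#' @export
consecutive_shifts <- function(obs, beds, taxon = NULL, stage = NULL,
                               alpha = 0.05, method = "auto") {
  summ <- bed_summaries(obs, beds, taxon, stage)
  obs <- .filter_scope(obs, taxon, stage)
  scope <- .scope_label(taxon, stage)
  out <- NULL
  if (nrow(summ) >= 2) {
    for (i in seq_len(nrow(summ) - 1)) {
      b1 <- summ$bed_id[i]; b2 <- summ$bed_id[i + 1]
      g1 <- obs$gm_mm[obs$bed_id == b1]; g2 <- obs$gm_mm[obs$bed_id == b2]
      tt <- pairwise_tests(g1, g2, method)
      out <- rbind(out, data.frame(
        bed_from = b1, bed_to = b2, scope = scope,
        pct_change_logratio = proportional_change(summ$median_gm_mm[i],
                                                  summ$median_gm_mm[i + 1]),
        p_mannwhitney = tt$p_mannwhitney, p_ks = tt$p_ks,
        n_from = length(g1), n_to = length(g2),
        significant = tt$p_mannwhitney < alpha & tt$p_ks < alpha,
        low_n = length(g1) < 5 | length(g2) < 5,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(bed_from = character(), bed_to = character(),
                      scope = character(), pct_change_logratio = numeric(),
                      p_mannwhitney = numeric(), p_ks = numeric(),
                      n_from = integer(), n_to = integer(),
                      significant = logical(), low_n = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Absolute abundance per bed
#'
#' Density of belemnite rostra per square metre from the quadrat collections:
#' all quadrat-flagged specimens count, complete and fragmentary alike, and
#' the area is `n_quadrats * quadrat_area_m2`. Non-quadrat specimens never
#' change the density. Beds without quadrats are omitted.
#'
#' @param ds a `belem_dataset`.
#' @return data.frame: `bed_id`, `n_specimens_quadrats`, `area_m2`,
#'   `density_per_m2`, in stratigraphic order.
#' @export
abundance <- function(ds) {
  stopifnot(inherits(ds, "belem_dataset"))
  beds <- .ordered_beds(ds)
  beds <- beds[beds$n_quadrats > 0, , drop = FALSE]
  if (!nrow(beds))
    belem_error("belem_domain_error", "no beds with quadrat sampling")
  sp <- ds$specimens[!is.na(ds$specimens$quadrat_id), , drop = FALSE]
  n <- vapply(beds$bed_id, function(b) sum(sp$bed_id == b), 0L)
  area <- beds$n_quadrats * beds$quadrat_area_m2
  out <- data.frame(bed_id = beds$bed_id, n_specimens_quadrats = unname(n),
                    area_m2 = area, density_per_m2 = unname(n) / area,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
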