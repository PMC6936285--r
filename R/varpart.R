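#' Treatment-coded design matrices for the partitioning factors
#'
#' Full-rank indicator coding (intercept column excluded) for taxon, stage and
#' bed, with the most frequent level as reference (ties broken
#' lexicographically). Observations of indeterminate stage or `"indet"` taxon
#' are not handled here; drop them before encoding.
#'
#' @param obs size observation table.
#' @return list of three matrices: `taxon`, `ontogeny`, `bed`.
#' @export
encode_factors <- function(obs) {
  enc <- function(v, name) {
    lev <- sort(unique(v))
    if (length(lev) < 2)
      belem_error("belem_validation_error",
                  "factor '%s' has a single level", name)
    tab <- table(v)
    ref <- names(tab)[order(-tab, names(tab))][1]
    f <- factor(v, levels = c(ref, setdiff(lev, ref)))
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(name, ".", levels(f)[-1])
    m
  }
  list(taxon = enc(obs$taxon, "taxon"),
       ontogeny = enc(obs$stage, "ontogeny"),
       bed = enc(obs$bed_id, "bed"))
}

#' Ezekiel-adjusted R-squared of a least-squares fit
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` from an intercept-included fit of
#' `response` on `X`, the adjustment underlying unbiased variation
#' partitioning.
#'
#' @param response numeric vector.
#' @param X design matrix without intercept column.
#' @return Adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(response, X) {
  X <- as.matrix(X)
  n <- length(response); p <- ncol(X)
  if (n <= p + 1)
    belem_error("belem_domain_error",
                "n = %d too small for p = %d predictors", n, p)
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < p + 1)
    belem_error("belem_domain_error", "design matrix is rank deficient")
  rss <- sum(qr.resid(qrX, response)^2)
  tss <- sum((response - mean(response))^2)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

## adjusted R^2 from a precomputed qr (fast path for permutations)
.adj_r2_qr <- function(qrX, y) {
  n <- length(y); p <- qrX$rank - 1
  rss <- sum(qr.resid(qrX, y)^2)
  tss <- sum((y - mean(y))^2)
  1 - (1 - (1 - rss / tss)) * (n - 1) / (n - p - 1)
}

#' Partition body-size variation across taxonomy, ontogeny and bed separation
#'
#' Splits the variation in the geometric-mean size into unique and joint
#' adjusted-R-squared fractions of the three factor sets (the three-set Venn
#' diagram), by inclusion-exclusion over the seven subset regressions. With a
#' univariate response this coincides exactly with partial-RDA variation
#' partitioning on factor dummies, so the regressions are run directly.
#' Negative fractions are reported as computed (a known property of the
#' adjustment), never truncated.
#'
#' Permutation p-values: each unique (conditional) fraction is tested by
#' permuting residuals of the reduced two-factor model; each single-factor
#' marginal model by permuting the response; `p = (1 + #\{perm >= obs\}) /
#' (1 + n_perm)`. The three-way joint fraction has no valid test.
#' Observations of indeterminate stage or `"indet"` taxon are dropped (they
#' carry no taxonomic or ontogenetic information); observations are sorted by
#' `specimen_id` before permuting so results are invariant to input order.
#'
#' @param obs size observation table from [size_observations()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return Object of class `variation_partition`: the seven fractions
#'   (`fraction_taxon`, `fraction_ontogeny`, `fraction_bed`,
#'   `joint_taxon_ontogeny`, `joint_taxon_bed`, `joint_ontogeny_bed`,
#'   `joint_all`), `residual`, `p_values` (six entries), `n`, `n_perm`,
#'   `seed`.
#' @export
partition_size_variation <- function(obs, n_perm = 999, seed = 1L) {
  obs <- obs[obs$stage %in% c("adult", "juvenile") & obs$taxon != "indet", ,
             drop = FALSE]
  obs <- obs[order(obs$specimen_id), , drop = FALSE]
  fac <- encode_factors(obs)
  y <- obs$gm_mm
  n <- length(y)

  dm <- list(T = fac$taxon, O = fac$ontogeny, B = fac$bed)
  subsets <- list(T = "T", O = "O", B = "B", TO = c("T", "O"),
                  TB = c("T", "B"), OB = c("O", "B"), TOB = c("T", "O", "B"))
  ## aliased columns (e.g. a taxon confined to a single bed) are absorbed by
  ## projection onto the column space; the adjustment uses the effective rank
  qrs <- lapply(subsets, function(s) {
    X <- do.call(cbind, dm[s])
    if (n <= ncol(X) + 1)
      belem_error("belem_domain_error",
                  "n = %d too small for the %s model", n,
                  paste(s, collapse = "+"))
    qr(cbind(1, X))
  })
  A <- vapply(qrs, .adj_r2_qr, 0.0, y = y)

  frac <- c(
    fraction_taxon    = A[["TOB"]] - A[["OB"]],
    fraction_ontogeny = A[["TOB"]] - A[["TB"]],
    fraction_bed      = A[["TOB"]] - A[["TO"]],
    joint_taxon_ontogeny = A[["TB"]] + A[["OB"]] - A[["TOB"]] - A[["B"]],
    joint_taxon_bed      = A[["TO"]] + A[["OB"]] - A[["TOB"]] - A[["O"]],
    joint_ontogeny_bed   = A[["TO"]] + A[["TB"]] - A[["TOB"]] - A[["T"]])
  frac <- c(frac, joint_all = unname(A[["TOB"]] - sum(frac)))
  residual <- 1 - A[["TOB"]]

  ## permutation tests (vectorised: one n x n_perm response matrix per test,
  ## RSS via projection onto the precomputed orthonormal bases)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  proj <- lapply(qrs, function(q)
    t(qr.Q(q)[, seq_len(q$rank), drop = FALSE]))
  ranks <- vapply(qrs, function(q) q$rank, 0L)
  adj_mat <- function(key, Y) {
    p <- ranks[[key]] - 1L
    ss <- colSums(Y^2)
    tss <- ss - n * colMeans(Y)^2
    rss <- ss - colSums((proj[[key]] %*% Y)^2)
    1 - (rss / tss) * (n - 1) / (n - p - 1)
  }
  p_values <- c(unique_taxon = NA_real_, unique_ontogeny = NA_real_,
                unique_bed = NA_real_, marginal_taxon = NA_real_,
                marginal_ontogeny = NA_real_, marginal_bed = NA_real_)
  reduced_of <- c(unique_taxon = "OB", unique_ontogeny = "TB",
                  unique_bed = "TO")
  obs_stat <- c(unique_taxon = frac[["fraction_taxon"]],
                unique_ontogeny = frac[["fraction_ontogeny"]],
                unique_bed = frac[["fraction_bed"]])
  for (comp in names(reduced_of)) {
    qr_red <- qrs[[reduced_of[[comp]]]]
    mu <- qr.fitted(qr_red, y)
    e <- y - mu
    Y <- mu + matrix(e[P], n)
    stat <- adj_mat("TOB", Y) - adj_mat(reduced_of[[comp]], Y)
    p_values[[comp]] <- (1 + sum(stat >= obs_stat[[comp]] - 1e-12)) /
      (1 + n_perm)
  }
  marg <- c(marginal_taxon = "T", marginal_ontogeny = "O", marginal_bed = "B")
  Y <- matrix(y[P], n)
  for (nm in names(marg)) {
    stat <- adj_mat(marg[[nm]], Y)
    p_values[[nm]] <- (1 + sum(stat >= A[[marg[[nm]]]] - 1e-12)) / (1 + n_perm)
  }

  structure(c(as.list(frac),
              list(residual = residual, marginal = A, p_values = p_values,
                   n = n, n_perm = n_perm, seed = seed)),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat(sprintf("<variation_partition> n = %d, %d permutations (seed %d)\n",
              x$n, x$n_perm, x$seed))
  fmt <- function(nm, v, p = NA)
    cat(sprintf("  %-22s %7.4f%s\n", nm, v,
                if (is.na(p)) "" else sprintf("  (p = %.4f)", p)))
  fmt("taxon (unique)", x$fraction_taxon, x$p_values[["unique_taxon"]])
  fmt("ontogeny (unique)", x$fraction_ontogeny, x$p_values[["unique_ontogeny"]])
  fmt("bed (unique)", x$fraction_bed, x$p_values[["unique_bed"]])
  fmt("taxon&ontogeny", x$joint_taxon_ontogeny)
  fmt("taxon&bed", x$joint_taxon_bed)
  fmt("ontogeny&bed", x$joint_ontogeny_bed)
  fmt("all three", x$joint_all)
  fmt("residual", x$residual)
  invisible(x)
}

#' Permutation p-value of a partition component
#'
#' Accessor for the testable components of a [partition_size_variation()]
#' result: the three unique (conditional) fractions and the three marginal
#' single-factor models. The three-way joint fraction is not independently
#' testable and requesting it is an error.
#'
#' @param partition_result a `variation_partition`.
#' @param component one of `"unique_taxon"`, `"unique_ontogeny"`,
#'   `"unique_bed"`, `"marginal_taxon"`, `"marginal_ontogeny"`,
#'   `"marginal_bed"`.
#' @return The permutation p-value.
#' @export
partition_significance <- function(partition_result, component) {
  stopifnot(inherits(partition_result, "variation_partition"))
  if (component %in% c("joint_all", "joint_taxon_ontogeny",
                       "joint_taxon_bed", "joint_ontogeny_bed"))
    belem_error("belem_domain_error",
                "joint fractions are not independently testable")
  if (!component %in% names(partition_result$p_values))
    belem_error("belem_domain_error", "unknown component '%s'", component)
  partition_result$p_values[[component]]
}
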