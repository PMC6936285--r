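## ---- AR(1) generalized least squares by maximum likelihood ----------------
## The errors follow e_t = rho * e_{t-1} + innovation along the stratigraphic
## ordering. For fixed rho the Prais-Winsten transform whitens the series
## (first observation scaled by sqrt(1 - rho^2)), the transformed fit is OLS,
## and the exact Gaussian log-likelihood is profiled over rho by bounded
## scalar optimization.

.ar1_whiten <- function(y, X, rho) {
  n <- length(y)
  w <- sqrt(1 - rho^2)
  ys <- c(w * y[1], y[-1] - rho * y[-n])
  Xs <- rbind(w * X[1, , drop = FALSE],
              X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE])
  qrX <- qr(Xs)
  list(qr = qrX, rss = sum(qr.resid(qrX, ys)^2), ys = ys, Xs = Xs)
}

.ar1_profile_loglik <- function(y, X, rho) {
  n <- length(y)
  wh <- .ar1_whiten(y, X, rho)
  -n / 2 * (log(2 * pi * wh$rss / n) + 1) + 0.5 * log(1 - rho^2)
}

#' Fit a GLS model with AR(1) errors by maximum likelihood (matrix interface)
#'
#' Lower-level engine behind [gls_ar1()]. Observations are sorted by
#' `order_key` (the stratigraphic sequence along which first-order
#' autocorrelation acts); the AR(1) parameter is profiled out of the exact
#' Gaussian log-likelihood by bounded scalar optimization (tolerance 1e-8).
#' Coefficient standard errors come from the whitened information matrix with
#' the residual variance scaled by `n / (n - p)`; t-test p-values use
#' `n - p` degrees of freedom. The parameter count `k` includes the
#' intercept and slopes, the AR(1) parameter and the residual variance, so
#' information criteria are comparable across candidate models.
#'
#' @param response numeric response vector.
#' @param X design matrix including the intercept column.
#' @param order_key numeric vector defining the stratigraphic ordering
#'   (default: input order).
#' @param rho fix the AR(1) parameter instead of estimating it (e.g. `rho = 0`
#'   reproduces OLS exactly); default `NULL` estimates it.
#' @return An object of class `gls_ar1`.
#' @export
fit_gls_ar1 <- function(response, X, order_key = seq_along(response),
                        rho = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(response)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || length(order_key) != n)
    belem_error("belem_domain_error", "dimension mismatch")
  if (n <= p + 2)
    belem_error("belem_domain_error", "n = %d too small for %d coefficients",
                n, p)
  ord <- order(order_key)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  if (qr(X)$rank < p)
    belem_error("belem_domain_error", "design matrix is rank deficient")

  bound <- 0.999
  if (is.null(rho)) {
    opt <- stats::optimize(function(r) -.ar1_profile_loglik(y, X, r),
                           interval = c(-bound, bound), tol = 1e-8)
    rho_hat <- opt$minimum
    loglik <- -opt$objective
    rho_fixed <- FALSE
  } else {
    if (abs(rho) >= 1)
      belem_error("belem_domain_error", "|rho| must be < 1")
    rho_hat <- rho
    loglik <- .ar1_profile_loglik(y, X, rho_hat)
    rho_fixed <- TRUE
  }
  if (!is.finite(loglik))
    belem_error("belem_convergence_error",
                "AR(1) likelihood did not converge (loglik not finite)")
  boundary <- !rho_fixed && abs(rho_hat) >= bound - 1e-3
  if (boundary)
    warning("AR(1) parameter estimate at the boundary of (-1, 1); fit flagged")

  wh <- .ar1_whiten(y, X, rho_hat)
  beta <- qr.coef(wh$qr, wh$ys)
  s2_innov <- wh$rss / n                      # ML innovation variance
  sigma2 <- s2_innov / (1 - rho_hat^2)        # marginal error variance
  XtXinv <- chol2inv(chol(crossprod(wh$Xs)))
  vc <- s2_innov * n / (n - p) * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  k <- p + 2L
  fitted_vals <- drop(X %*% beta)

  structure(list(
    coefficients = beta,
    tTable = data.frame(term = colnames(X), value = unname(beta),
                        std_error = unname(se), t_value = unname(tval),
                        p_value = unname(pval), stringsAsFactors = FALSE),
    rho = rho_hat, rho_fixed = rho_fixed, boundary = boundary,
    sigma2 = sigma2, s2_innov = s2_innov,
    loglik = loglik, k = k, n = n, p = p,
    aicc = aicc(loglik, k, n),
    df_residual = n - p, vcov = vc,
    fitted = fitted_vals[order(ord)],
    residuals = (y - drop(X %*% beta))[order(ord)],
    y_checksum = c(sum(y), sum(y^2)),
    order_key = order_key), class = "gls_ar1")
}

#' Generalized least squares with AR(1) errors (formula interface)
#'
#' Fits `formula` in `data` by maximizing the exact AR(1) Gaussian
#' log-likelihood over the coefficients and the autoregressive parameter.
#' This is the classic model for regressing a stratigraphic size series on
#' environmental proxies while absorbing serial dependence along the section.
#'
#' @param formula model formula, e.g. `gm_mm ~ d18O_permil`.
#' @param data data.frame holding the variables.
#' @param order optional unquoted column (or numeric vector) giving the
#'   stratigraphic ordering; defaults to row order.
#' @param rho optional fixed AR(1) parameter (see [fit_gls_ar1()]).
#' @return An object of class `gls_ar1` with `print`, `summary`, `coef`,
#'   `logLik`, `vcov`, `residuals`, `fitted`, `predict`, `simulate` and
#'   `plot` methods.
#' @examples
#' d <- data.frame(x = rnorm(50))
#' d$y <- 1 + 2 * d$x + as.numeric(stats::arima.sim(list(ar = 0.5), 50))
#' fit <- gls_ar1(y ~ x, d)
#' coef(fit)
#' @export
gls_ar1 <- function(formula, data, order = NULL, rho = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ord <- eval(substitute(order), data, parent.frame())
  if (is.null(ord)) ord <- seq_along(y)
  fit <- fit_gls_ar1(y, X, ord, rho = rho)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @export
print.gls_ar1 <- function(x, ...) {
  cat("Generalized least squares with AR(1) errors (ML)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  cat(sprintf("rho = %.4f%s   logLik = %.4f   AICc = %.4f   n = %d\n",
              x$rho, if (x$rho_fixed) " (fixed)" else "", x$loglik,
              x$aicc, x$n))
  invisible(x)
}

#' @export
summary.gls_ar1 <- function(object, ...) {
  structure(list(fit = object), class = "summary.gls_ar1")
}

#' @export
print.summary.gls_ar1 <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nCoefficient tests (t, df = %d):\n", f$df_residual))
  print(f$tTable, row.names = FALSE)
  if (f$boundary) cat("warning: rho at parameter-space boundary\n")
  invisible(x)
}

#' @export
coef.gls_ar1 <- function(object, ...) object$coefficients

#' @export
vcov.gls_ar1 <- function(object, ...) object$vcov

#' @export
logLik.gls_ar1 <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
residuals.gls_ar1 <- function(object, ...) object$residuals

#' @export
fitted.gls_ar1 <- function(object, ...) object$fitted

#' @export
predict.gls_ar1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$terms))
    belem_error("belem_domain_error",
                "predict with newdata needs a formula-interface fit")
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  drop(X %*% object$coefficients)
}

#' @export
simulate.gls_ar1 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  ord <- order(object$order_key)
  out <- replicate(nsim, {
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, sqrt(object$sigma2))
    innov_sd <- sqrt(object$s2_innov)
    for (t in seq_len(n - 1))
      e[t + 1] <- object$rho * e[t] + stats::rnorm(1, 0, innov_sd)
    y <- numeric(n)
    y[ord] <- object$fitted[ord] + e
    y
  })
  as.data.frame(out)
}

#' @export
plot.gls_ar1 <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(oldpar))
  graphics::plot(x$fitted, x$residuals, xlab = "fitted", ylab = "residuals",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(x$residuals); stats::qqline(x$residuals)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `-2 logLik + 2k + 2k(k+1)/(n - k - 1)`; converges to the ordinary AIC as
#' `n` grows.
#'
#' @param loglik maximized log-likelihood (numeric or `logLik`).
#' @param k number of estimated parameters (including intercept, AR(1)
#'   parameter and residual variance).
#' @param n number of observations; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  loglik <- as.numeric(loglik)
  if (n <= k + 1)
    belem_error("belem_domain_error", "AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' The seven candidate environmental-driver models
#'
#' The fixed model set compared in the driver analysis: a null
#' (intercept-only) model and all single- and two-proxy combinations of the
#' palaeotemperature (`d18O`), carbon-cycle (`d13C`) and volcanogenic
#' outgassing (`hg_toc`) proxies (the full three-proxy model is not a
#' candidate).
#'
#' @return Named list `1`..`7` of term character vectors (model 1 is empty).
#' @export
model_specs <- function() {
  list(`1` = character(0),
       `2` = c("d18O", "d13C"),
       `3` = c("hg_toc", "d13C"),
       `4` = c("hg_toc", "d18O"),
       `5` = "d18O",
       `6` = "hg_toc",
       `7` = "d13C")
}

.proxy_col <- c(d18O = "d18O_permil", d13C = "d13C_permil", hg_toc = "hg_toc")

#' Rank candidate fits by AICc
#'
#' Computes `delta = AICc - min(AICc)` over all supplied fits (the null model
#' included) and marks the retained set `delta < delta_threshold`. Rows are
#' ordered by AICc with ties broken by fewer parameters, then lower model id.
#' Fits on different data (different n or response) are refused.
#'
#' @param fits list of `gls_ar1` fits, ideally carrying `$model_id` and
#'   `$terms_label` fields (added by [run_model_selection()]).
#' @param delta_threshold retention threshold (default 2).
#' @return data.frame: `model_id`, `terms`, `k`, `loglik`, `rho`, `aicc`,
#'   `delta_aicc`, `retained`.
#' @export
rank_models <- function(fits, delta_threshold = 2.0) {
  if (length(fits) < 2)
    belem_error("belem_domain_error", "need at least two fits to rank")
  n <- vapply(fits, function(f) f$n, 0L)
  if (length(unique(n)) != 1)
    belem_error("belem_domain_error", "fits are on different n")
  cs <- vapply(fits, function(f) f$y_checksum[1], 0.0)
  if (max(abs(cs - cs[1])) > 1e-8 * max(1, abs(cs[1])))
    belem_error("belem_domain_error", "fits are on different responses")
  ids <- vapply(seq_along(fits), function(i) {
    id <- fits[[i]]$model_id
    if (is.null(id)) i else as.integer(id)
  }, 0L)
  labels <- vapply(seq_along(fits), function(i) {
    lb <- fits[[i]]$terms_label
    if (is.null(lb))
      paste(setdiff(names(stats::coef(fits[[i]])), "(Intercept)"),
            collapse = "+")
    else lb
  }, "")
  labels[labels == ""] <- "1"
  aiccs <- vapply(fits, function(f) f$aicc, 0.0)
  out <- data.frame(model_id = ids, terms = labels,
                    k = vapply(fits, function(f) f$k, 0L),
                    loglik = vapply(fits, function(f) f$loglik, 0.0),
                    rho = vapply(fits, function(f) f$rho, 0.0),
                    aicc = aiccs, delta_aicc = aiccs - min(aiccs),
                    stringsAsFactors = FALSE)
  out$retained <- out$delta_aicc < delta_threshold
  out <- out[order(out$aicc, out$k, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of the best model against the null
#'
#' `2 (logLik_best - logLik_null)` referred to a chi-square with degrees of
#' freedom equal to the difference in fixed-effect terms. Both fits must be
#' ML fits on identical data and the null must be nested in the best model.
#'
#' @param best,null `gls_ar1` fits.
#' @return The p-value, with the statistic and df as attributes.
#' @export
compare_to_null <- function(best, null) {
  stopifnot(inherits(best, "gls_ar1"), inherits(null, "gls_ar1"))
  if (best$n != null$n ||
      max(abs(best$y_checksum - null$y_checksum)) >
        1e-8 * max(1, abs(best$y_checksum[1])))
    belem_error("belem_domain_error", "fits are not on identical data")
  tb <- names(best$coefficients); tn <- names(null$coefficients)
  if (!all(tn %in% tb))
    belem_error("belem_domain_error", "null model is not nested in best model")
  df <- best$p - null$p
  if (df <= 0)
    belem_error("belem_domain_error", "zero degrees of freedom for the test")
  stat <- max(0, 2 * (best$loglik - null$loglik))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  attr(p, "statistic") <- stat
  attr(p, "df") <- df
  p
}

#' Residualize size for sedimentary properties
#'
#' Ordinary least squares of per-specimen GM on bed lithology (categorical)
#' and belemnite absolute abundance (continuous, from the quadrat counts),
#' jointly; the residuals are the sediment-corrected response used in the
#' driver regressions. Constant terms (e.g. a single lithology in the window)
#' are dropped from the correction rather than failing.
#'
#' @param obs size observation table.
#' @param beds bed table (provides lithology).
#' @param abundance_tab abundance table from [abundance()].
#' @return Numeric residual vector in observation order, with the fitted lm
#'   attached as attribute `"fit"`.
#' @export
residualize <- function(obs, beds, abundance_tab) {
  i <- match(obs$bed_id, beds$bed_id)
  j <- match(obs$bed_id, abundance_tab$bed_id)
  bad <- unique(obs$bed_id[is.na(i) | is.na(j)])
  if (length(bad))
    belem_error("belem_referential_error",
                "bed(s) lacking lithology or abundance: %s",
                paste(bad, collapse = ", "))
  d <- data.frame(gm = obs$gm_mm,
                  lithology = factor(beds$lithology[i],
                                     levels = .lithology_levels),
                  abundance = abundance_tab$density_per_m2[j])
  terms <- c(if (nlevels(droplevels(d$lithology)) > 1) "lithology",
             if (length(unique(d$abundance)) > 1) "abundance")
  if (is.null(terms) || !length(terms)) {
    r <- d$gm - mean(d$gm)
    attr(r, "fit") <- NULL
    return(r)
  }
  fit <- stats::lm(stats::reformulate(terms, "gm"), data = droplevels(d))
  r <- unname(stats::residuals(fit))
  attr(r, "fit") <- fit
  r
}

#' Collinearity screen of candidate explanatory variables
#'
#' Pairwise Pearson correlations over complete pairs; pairs with
#' `|r| >= threshold` are flagged. Constant variables have undefined
#' correlation and are flagged as such. Screening is advisory only — the
#' candidate model set is fixed — but flagged pairs warn that their joint
#' models cannot separate the two effects.
#'
#' @param proxy_table data.frame of numeric variables (e.g. the proxies).
#' @param extra_vars optional additional numeric data.frame, column-bound.
#' @param threshold absolute-correlation flag threshold (default 0.7).
#' @return list with `cor` (the matrix) and `flags` (data.frame `var1`,
#'   `var2`, `r`, `flagged`).
#' @export
collinearity <- function(proxy_table, extra_vars = NULL, threshold = 0.7) {
  d <- as.data.frame(proxy_table)
  d <- d[vapply(d, is.numeric, TRUE)]
  if (!is.null(extra_vars)) d <- cbind(d, as.data.frame(extra_vars))
  cm <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  pairs <- utils::combn(colnames(cm), 2)
  flags <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                      r = cm[t(pairs)], stringsAsFactors = FALSE)
  flags$flagged <- is.na(flags$r) | abs(flags$r) >= threshold
  list(cor = cm, flags = flags)
}

#' Fit and rank the seven environmental-driver models
#'
#' Builds the per-specimen response for the requested scope (whole assemblage
#' or a single taxon), optionally residualized for sedimentary properties,
#' assigns each specimen its bed's proxy values, fits all seven candidate
#' GLS-AR(1) models along the stratigraphic ordering (specimens sorted by bed
#' `order_index`, then `specimen_id`) and ranks them by AICc. The best
#' non-null model is tested against the null by likelihood ratio.
#'
#' @param ds a `belem_dataset` with proxies.
#' @param window optional character vector of bed ids delimiting the analysis
#'   window (default: all beds with observations and complete proxies).
#' @param correct_sedimentary residualize for lithology and abundance first
#'   (default `TRUE`).
#' @param scope `"assemblage"` or a taxon name.
#' @param delta_threshold AICc retention threshold (default 2).
#' @return Object of class `model_selection`: list with `fits` (named by
#'   model id), `table` (from [rank_models()]), `lrt_p_vs_null`,
#'   `coefficients` (long table across models), `scope`, `window`,
#'   `corrected`, `n`.
#' @export
run_model_selection <- function(ds, window = NULL, correct_sedimentary = TRUE,
                                scope = "assemblage", delta_threshold = 2.0) {
  stopifnot(inherits(ds, "belem_dataset"))
  if (is.null(ds$proxies))
    belem_error("belem_domain_error", "dataset has no proxy table")
  obs <- suppressMessages(size_observations(ds))
  if (scope != "assemblage") obs <- .filter_scope(obs, taxon = scope)
  beds <- .ordered_beds(ds)
  px <- ds$proxies
  complete_px <- px$bed_id[stats::complete.cases(
    px[c("d18O_permil", "d13C_permil", "hg_toc")])]
  if (is.null(window)) {
    window <- intersect(beds$bed_id[beds$bed_id %in% complete_px],
                        unique(obs$bed_id))
  } else {
    missing_px <- setdiff(intersect(window, unique(obs$bed_id)), complete_px)
    if (length(missing_px))
      belem_error("belem_referential_error",
                  "bed(s) in window lacking proxies: %s",
                  paste(missing_px, collapse = ", "))
  }
  obs <- obs[obs$bed_id %in% window, , drop = FALSE]
  if (length(unique(obs$bed_id)) < 2)
    belem_error("belem_domain_error",
                "window must cover at least two beds with observations")

  y <- if (correct_sedimentary)
    as.numeric(residualize(obs, beds, abundance(ds)))
  else obs$gm_mm
  oi <- beds$order_index[match(obs$bed_id, beds$bed_id)]
  ord_key <- order(order(oi, obs$specimen_id))  # rank along the section
  pxm <- px[match(obs$bed_id, px$bed_id), , drop = FALSE]

  specs <- model_specs()
  fits <- lapply(names(specs), function(id) {
    terms <- specs[[id]]
    X <- cbind(`(Intercept)` = rep(1, nrow(obs)))
    for (tm in terms) {
      X <- cbind(X, pxm[[.proxy_col[[tm]]]])
      colnames(X)[ncol(X)] <- tm
    }
    f <- fit_gls_ar1(y, X, ord_key)
    f$model_id <- as.integer(id)
    f$terms_label <- if (length(terms)) paste(terms, collapse = "+") else "1"
    f
  })
  names(fits) <- names(specs)
  table <- rank_models(fits, delta_threshold)
  best_id <- table$model_id[1]
  lrt <- if (best_id != 1L)
    compare_to_null(fits[[as.character(best_id)]], fits[["1"]]) else NULL
  coefs <- do.call(rbind, lapply(fits, function(f)
    cbind(data.frame(model_id = f$model_id), f$tTable)))
  rownames(coefs) <- NULL
  structure(list(fits = fits, table = table, lrt_p_vs_null = lrt,
                 coefficients = coefs, scope = scope, window = window,
                 corrected = correct_sedimentary, n = length(y)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> scope = %s, n = %d, %s\n", x$scope, x$n,
              if (x$corrected) "sediment-corrected" else "uncorrected"))
  print(x$table, row.names = FALSE)
  if (!is.null(x$lrt_p_vs_null))
    cat(sprintf("best vs null LRT: stat = %.3f, df = %d, p = %.4g\n",
                attr(x$lrt_p_vs_null, "statistic"),
                attr(x$lrt_p_vs_null, "df"), as.numeric(x$lrt_p_vs_null)))
  invisible(x)
}
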