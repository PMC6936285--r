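#' Boundary-crossing taxa of a consecutive bed pair
#'
#' Taxa present (at least one complete measured specimen) in both beds of a
#' pair. Specimens whose taxon is the literal placeholder `"indet"` are
#' excluded: they cannot be tracked across beds (named open-nomenclature taxa
#' such as `"Hastitidae sp. indet."` are ordinary taxa and do cross).
#'
#' @param obs size observation table from [size_observations()].
#' @param bed_from,bed_to bed ids of the pair.
#' @return Character vector of crossing taxa (possibly empty).
#' @export
boundary_crossers <- function(obs, bed_from, bed_to) {
  t1 <- obs$taxon[obs$bed_id == bed_from]
  t2 <- obs$taxon[obs$bed_id == bed_to]
  if (!length(t1) || !length(t2))
    belem_error("belem_domain_error",
                "both beds must have at least one observation")
  sort(setdiff(intersect(unique(t1), unique(t2)), "indet"))
}

#' Decompose an assemblage median size shift into turnover and within-lineage
#' components
#'
#' The assemblage median shift between consecutive beds t and t+1 telescopes
#' exactly into three effects built from the boundary-crosser taxa:
#' \describe{
#'   \item{total}{`median(all taxa, t+1) - median(all taxa, t)`}
#'   \item{disappearance}{`median(crossers, t) - median(all taxa, t)`}
#'   \item{within-lineage}{`median(crossers, t+1) - median(crossers, t)`}
#'   \item{appearance}{`median(all taxa, t+1) - median(crossers, t+1)`}
#' }
#' Medians are taken over pooled individual specimens of each taxon set (not
#' over per-taxon medians); that is the only reading under which the three
#' components sum to the total identically. `"indet"` specimens count toward
#' the all-taxa medians but never toward the crosser set.
#'
#' @inheritParams boundary_crossers
#' @param scale `"mm"` (default) decomposes the median GM in mm; `"log"`
#'   decomposes the median log-GM (the shares are then shares of the log
#'   shift).
#' @return Object of class `shift_decomposition`: list with `bed_from`,
#'   `bed_to`, `boundary_crossers`, `total_shift_mm`, `disappearance_mm`,
#'   `within_mm`, `appearance_mm`, the three signed shares (percent of total;
#'   `NA` when `|total| < 1e-12`), and the four underlying medians.
#' @export
decompose_shift <- function(obs, bed_from, bed_to, scale = c("mm", "log")) {
  scale <- match.arg(scale)
  crossers <- boundary_crossers(obs, bed_from, bed_to)
  if (!length(crossers))
    belem_error("belem_domain_error",
                "no boundary-crossing taxa between %s and %s: decomposition undefined",
                bed_from, bed_to)
  g <- obs$gm_mm
  if (scale == "log") g <- log(g)
  med <- function(bed, taxa = NULL) {
    keep <- obs$bed_id == bed
    if (!is.null(taxa)) keep <- keep & obs$taxon %in% taxa
    stats::median(g[keep])
  }
  m_all_t    <- med(bed_from)
  m_all_t1   <- med(bed_to)
  m_cross_t  <- med(bed_from, crossers)
  m_cross_t1 <- med(bed_to, crossers)
  total <- m_all_t1 - m_all_t
  disap <- m_cross_t - m_all_t
  within <- m_cross_t1 - m_cross_t
  appear <- m_all_t1 - m_cross_t1
  shares <- if (abs(total) < 1e-12) rep(NA_real_, 3) else
    c(disap, within, appear) / total * 100
  structure(list(
    bed_from = bed_from, bed_to = bed_to, boundary_crossers = crossers,
    total_shift_mm = total, disappearance_mm = disap, within_mm = within,
    appearance_mm = appear,
    share_disappearance_pct = shares[1], share_within_pct = shares[2],
    share_appearance_pct = shares[3],
    medians = c(all_t = m_all_t, crossers_t = m_cross_t,
                crossers_t1 = m_cross_t1, all_t1 = m_all_t1),
    scale = scale), class = "shift_decomposition")
}

#' @export
print.shift_decomposition <- function(x, ...) {
  cat(sprintf("<shift_decomposition> %s -> %s (%s scale)\n",
              x$bed_from, x$bed_to, x$scale))
  cat(sprintf("  total %.4f = disappearance %.4f + within %.4f + appearance %.4f\n",
              x$total_shift_mm, x$disappearance_mm, x$within_mm,
              x$appearance_mm))
  if (is.na(x$share_within_pct))
    cat("  shares undefined (total shift ~ 0)\n")
  else
    cat(sprintf("  shares (%%): disappearance %.1f, within %.1f, appearance %.1f\n",
                x$share_disappearance_pct, x$share_within_pct,
                x$share_appearance_pct))
  cat(sprintf("  boundary crossers: %s\n",
              paste(x$boundary_crossers, collapse = ", ")))
  invisible(x)
}

#' Signed component shares of a decomposed shift
#'
#' Each component divided by the total, times 100. Shares are signed (a
#' component opposing the total is negative) and always sum to 100 when the
#' total is non-zero.
#'
#' @param d a `shift_decomposition`.
#' @return Named numeric of length 3: `disappearance`, `within`, `appearance`.
#' @export
shift_shares <- function(d) {
  stopifnot(inherits(d, "shift_decomposition"))
  if (abs(d$total_shift_mm) < 1e-12)
    belem_error("belem_domain_error",
                "shares undefined: total shift is zero")
  c(disappearance = d$share_disappearance_pct,
    within = d$share_within_pct,
    appearance = d$share_appearance_pct)
}

#' Decomposition table for every consecutive bed pair
#'
#' Runs [decompose_shift()] over each stratigraphically consecutive pair of
#' beds holding observations; pairs without boundary crossers, or with an
#' empty side, are skipped with a message.
#'
#' @inheritParams bed_summaries
#' @param scale passed to [decompose_shift()].
#' @return data.frame mirroring the per-pair decomposition fields, plus
#'   `n_crossers`.
#' @export
decompose_all <- function(obs, beds, scale = "mm") {
  occupied <- bed_summaries(obs, beds)$bed_id
  out <- NULL
  if (length(occupied) >= 2) {
    for (i in seq_len(length(occupied) - 1)) {
      d <- tryCatch(decompose_shift(obs, occupied[i], occupied[i + 1], scale),
                    belem_error = function(e) {
                      message(sprintf("decompose_all: skipping %s -> %s (%s)",
                                      occupied[i], occupied[i + 1],
                                      conditionMessage(e)))
                      NULL
                    })
      if (is.null(d)) next
      out <- rbind(out, data.frame(
        bed_from = d$bed_from, bed_to = d$bed_to,
        total_shift_mm = d$total_shift_mm,
        disappearance_mm = d$disappearance_mm, within_mm = d$within_mm,
        appearance_mm = d$appearance_mm,
        share_disappearance_pct = d$share_disappearance_pct,
        share_within_pct = d$share_within_pct,
        share_appearance_pct = d$share_appearance_pct,
        n_crossers = length(d$boundary_crossers), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(bed_from = character(), bed_to = character(),
                      total_shift_mm = numeric(), disappearance_mm = numeric(),
                      within_mm = numeric(), appearance_mm = numeric(),
                      share_disappearance_pct = numeric(),
                      share_within_pct = numeric(),
                      share_appearance_pct = numeric(),
                      n_crossers = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
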