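# Domain vocabulary shared by all stages. bed_id strings are opaque; every
# stratigraphic ordering in the package uses order_index, never the labels.

.stage_levels        <- c("adult", "juvenile", "indeterminate")
.completeness_levels <- c("complete", "fragment")
.source_levels       <- c("ct", "calliper", "none")
.lithology_levels    <- c("marl", "marly_limestone", "limestone")

.specimen_cols <- c("specimen_id", "bed_id", "taxon", "stage", "completeness",
                    "source", "dv_mm", "dl_mm", "length_mm", "quadrat_id")
.bed_cols      <- c("bed_id", "order_index", "height_m", "zone", "lithology",
                    "n_quadrats", "quadrat_area_m2", "pool_group")
.proxy_cols    <- c("bed_id", "d18O_permil", "d13C_permil", "hg_toc")

.specimen_classes <- c(specimen_id = "character", bed_id = "character",
                       taxon = "character", stage = "character",
                       completeness = "character", source = "character",
                       dv_mm = "numeric", dl_mm = "numeric",
                       length_mm = "numeric", quadrat_id = "character")
.bed_classes <- c(bed_id = "character", order_index = "integer",
                  height_m = "numeric", zone = "character",
                  lithology = "character", n_quadrats = "integer",
                  quadrat_area_m2 = "numeric", pool_group = "character")
.proxy_classes <- c(bed_id = "character", d18O_permil = "numeric",
                    d13C_permil = "numeric", hg_toc = "numeric")

belem_error <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "belem_error", "error", "condition")))
}

.read_table <- function(path, cols, classes) {
  if (!file.exists(path))
    belem_error("belem_schema_error", "input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN"),
                        colClasses = NA, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    belem_error("belem_schema_error", "missing mandatory column(s): %s in %s",
                paste(missing, collapse = ", "), path)
  df <- df[cols]
  for (cl in names(classes)) {
    df[[cl]] <- switch(classes[[cl]],
                       character = as.character(df[[cl]]),
                       numeric   = as.numeric(df[[cl]]),
                       integer   = as.integer(df[[cl]]))
  }
  df
}

#' Assemble and validate a belemnite measurement dataset
#'
#' Bundles per-specimen rostrum measurements, the bed (stratigraphic horizon)
#' table and optional per-bed environmental proxies into a single validated
#' object used by every downstream stage.
#'
#' Validation enforces: unique `specimen_id`; controlled vocabularies for
#' `stage`, `completeness`, `source` and `lithology`; all three linear
#' measurements present and positive for every `complete` specimen; every
#' `bed_id` referenced by a specimen or proxy row resolving to the bed table;
#' unique `order_index`; and no quadrat-flagged specimen in a bed declared to
#' have zero quadrats. Missing `stage` is mapped to `"indeterminate"` and
#' missing `source` to `"none"`.
#'
#' @param specimens data.frame with columns `specimen_id`, `bed_id`, `taxon`,
#'   `stage`, `completeness`, `source`, `dv_mm`, `dl_mm`, `length_mm`,
#'   `quadrat_id` (apical dorsoventral height, lateral width and length in mm).
#' @param beds data.frame with columns `bed_id`, `order_index`, `height_m`,
#'   `zone`, `lithology`, `n_quadrats`, `quadrat_area_m2`, `pool_group`.
#' @param proxies optional data.frame with columns `bed_id`, `d18O_permil`,
#'   `d13C_permil`, `hg_toc` (at most one row per bed).
#' @return An object of class `belem_dataset`: a list with elements
#'   `specimens`, `beds` and `proxies` (the latter possibly `NULL`).
#' @seealso [read_dataset()] to build one from CSV files.
#' @export
belem_dataset <- function(specimens, beds, proxies = NULL) {
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  beds <- as.data.frame(beds, stringsAsFactors = FALSE)
  for (col in setdiff(.specimen_cols, names(specimens))) {
    if (col == "quadrat_id") specimens$quadrat_id <- NA_character_
    else belem_error("belem_schema_error", "specimens lack column %s", col)
  }
  for (col in setdiff(.bed_cols, names(beds))) {
    if (col == "pool_group") beds$pool_group <- NA_character_
    else belem_error("belem_schema_error", "beds lack column %s", col)
  }
  specimens <- specimens[.specimen_cols]
  beds <- beds[.bed_cols]
  if (!is.null(proxies)) {
    proxies <- as.data.frame(proxies, stringsAsFactors = FALSE)
    miss <- setdiff(.proxy_cols, names(proxies))
    if (length(miss))
      belem_error("belem_schema_error", "proxies lack column(s): %s",
                  paste(miss, collapse = ", "))
    proxies <- proxies[.proxy_cols]
  }

  ## specimen-level checks
  dup <- specimens$specimen_id[duplicated(specimens$specimen_id)]
  if (length(dup))
    belem_error("belem_validation_error", "duplicate specimen_id: %s",
                paste(unique(dup), collapse = ", "))
  specimens$stage[is.na(specimens$stage)] <- "indeterminate"
  specimens$source[is.na(specimens$source)] <- "none"
  bad <- !specimens$stage %in% .stage_levels
  if (any(bad))
    belem_error("belem_validation_error", "invalid stage value(s): %s",
                paste(unique(specimens$stage[bad]), collapse = ", "))
  bad <- is.na(specimens$completeness) |
    !specimens$completeness %in% .completeness_levels
  if (any(bad))
    belem_error("belem_validation_error",
                "invalid completeness for specimen(s): %s",
                paste(specimens$specimen_id[bad], collapse = ", "))
  bad <- !specimens$source %in% .source_levels
  if (any(bad))
    belem_error("belem_validation_error", "invalid source value(s): %s",
                paste(unique(specimens$source[bad]), collapse = ", "))
  meas <- as.matrix(specimens[c("dv_mm", "dl_mm", "length_mm")])
  comp <- specimens$completeness == "complete"
  bad <- comp & (rowSums(is.na(meas)) > 0 |
                   rowSums(!is.na(meas) & meas <= 0) > 0)
  if (any(bad))
    belem_error("belem_validation_error",
                "complete specimen(s) with missing or nonpositive measurements: %s",
                paste(specimens$specimen_id[bad], collapse = ", "))

  ## bed-level checks
  if (anyDuplicated(beds$bed_id))
    belem_error("belem_validation_error", "duplicate bed_id in bed table")
  if (anyDuplicated(beds$order_index))
    belem_error("belem_validation_error", "duplicate order_index in bed table")
  bad <- is.na(beds$lithology) | !beds$lithology %in% .lithology_levels
  if (any(bad))
    belem_error("belem_validation_error", "invalid lithology for bed(s): %s",
                paste(beds$bed_id[bad], collapse = ", "))
  if (any(is.na(beds$n_quadrats) | beds$n_quadrats < 0))
    belem_error("belem_validation_error", "n_quadrats must be >= 0")
  beds$quadrat_area_m2[is.na(beds$quadrat_area_m2)] <- 1.0
  if (any(beds$quadrat_area_m2 <= 0))
    belem_error("belem_validation_error", "quadrat_area_m2 must be positive")

  ## referential checks
  unresolved <- setdiff(unique(specimens$bed_id), beds$bed_id)
  if (length(unresolved))
    belem_error("belem_referential_error",
                "specimen bed_id(s) absent from bed table: %s",
                paste(unresolved, collapse = ", "))
  nq <- beds$n_quadrats[match(specimens$bed_id, beds$bed_id)]
  bad <- !is.na(specimens$quadrat_id) & nq == 0
  if (any(bad))
    belem_error("belem_referential_error",
                "quadrat specimen(s) in bed(s) with n_quadrats = 0: %s",
                paste(unique(specimens$bed_id[bad]), collapse = ", "))
  if (!is.null(proxies)) {
    if (anyDuplicated(proxies$bed_id))
      belem_error("belem_validation_error", "more than one proxy row per bed")
    unresolved <- setdiff(proxies$bed_id, beds$bed_id)
    if (length(unresolved))
      belem_error("belem_referential_error",
                  "proxy bed_id(s) absent from bed table: %s",
                  paste(unresolved, collapse = ", "))
  }

  structure(list(specimens = specimens, beds = beds, proxies = proxies),
            class = "belem_dataset")
}

#' @export
print.belem_dataset <- function(x, ...) {
  n_complete <- sum(x$specimens$completeness == "complete")
  cat("<belem_dataset>\n")
  cat(sprintf("  %d specimens (%d complete, %d fragments) in %d beds\n",
              nrow(x$specimens), n_complete,
              nrow(x$specimens) - n_complete, nrow(x$beds)))
  cat(sprintf("  taxa: %s\n",
              paste(sort(unique(x$specimens$taxon)), collapse = ", ")))
  cat(sprintf("  proxies: %s\n",
              if (is.null(x$proxies)) "none" else
                sprintf("%d beds", nrow(x$proxies))))
  invisible(x)
}

#' Read a dataset from CSV files
#'
#' Parses the three standard CSV tables (specimens, beds, optional proxies)
#' and returns a validated [belem_dataset()]. Row order is preserved. Empty
#' cells, `"NA"` and `"NaN"` are read as missing; missing numeric cells are
#' never coerced to zero.
#'
#' @param specimen_path path to `specimens.csv`.
#' @param bed_path path to `beds.csv`.
#' @param proxy_path optional path to `proxies.csv`.
#' @return A validated `belem_dataset`.
#' @export
read_dataset <- function(specimen_path, bed_path, proxy_path = NULL) {
  specimens <- .read_table(specimen_path, .specimen_cols, .specimen_classes)
  beds <- .read_table(bed_path, .bed_cols, .bed_classes)
  proxies <- if (!is.null(proxy_path))
    .read_table(proxy_path, .proxy_cols, .proxy_classes) else NULL
  belem_dataset(specimens, beds, proxies)
}

#' Write a dataset to CSV files
#'
#' Inverse of [read_dataset()]: writes `specimens.csv`, `beds.csv` and (when
#' present) `proxies.csv` under `dir`. Missing values are written as empty
#' cells so that a read/write cycle is the identity on validated datasets.
#'
#' @param ds a `belem_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "belem_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(specimens = file.path(dir, "specimens.csv"),
             beds = file.path(dir, "beds.csv"))
  utils::write.csv(ds$specimens, paths[["specimens"]], row.names = FALSE,
                   na = "", quote = FALSE)
  utils::write.csv(ds$beds, paths[["beds"]], row.names = FALSE,
                   na = "", quote = FALSE)
  if (!is.null(ds$proxies)) {
    paths <- c(paths, proxies = file.path(dir, "proxies.csv"))
    utils::write.csv(ds$proxies, paths[["proxies"]], row.names = FALSE,
                     na = "", quote = FALSE)
  }
  invisible(paths)
}

#' Pool stratigraphically contiguous beds
#'
#' Merges groups of adjacent beds into single pooled beds, the standard remedy
#' when individual horizons yield too few specimens for stable medians.
#' Specimens are re-labelled to the pooled bed; the pooled bed takes the
#' lowest member `order_index` and `height_m`, the summed `n_quadrats`, and
#' the zone/lithology/quadrat area of the stratigraphically lowest member.
#' Pooled proxy values are the arithmetic mean of the member beds' values,
#' ignoring missing members.
#'
#' @param ds a `belem_dataset`.
#' @param pooling named character vector mapping member `bed_id` to pooled id,
#'   e.g. `c(P9a = "P9", P9b = "P9", P9c = "P9")`. When `NULL`, the mapping is
#'   derived from the non-missing `pool_group` column of the bed table.
#' @return A new validated `belem_dataset` with pooled beds.
#' @export
pool_beds <- function(ds, pooling = NULL) {
  stopifnot(inherits(ds, "belem_dataset"))
  beds <- ds$beds
  if (is.null(pooling)) {
    grp <- !is.na(beds$pool_group)
    pooling <- stats::setNames(beds$pool_group[grp], beds$bed_id[grp])
  }
  if (!length(pooling)) return(ds)
  unknown <- setdiff(names(pooling), beds$bed_id)
  if (length(unknown))
    belem_error("belem_referential_error",
                "pooling refers to unknown bed(s): %s",
                paste(unknown, collapse = ", "))
  ## identity entries are no-ops
  pooling <- pooling[pooling != names(pooling) |
                       duplicated(pooling) | duplicated(pooling, fromLast = TRUE)]
  if (!length(pooling)) return(ds)
  collide <- intersect(unique(pooling), setdiff(beds$bed_id, names(pooling)))
  if (length(collide))
    belem_error("belem_validation_error",
                "pooled id(s) collide with unpooled bed(s): %s",
                paste(collide, collapse = ", "))

  new_beds <- beds[!beds$bed_id %in% names(pooling), , drop = FALSE]
  for (pid in unique(pooling)) {
    members <- beds[beds$bed_id %in% names(pooling)[pooling == pid], ,
                    drop = FALSE]
    members <- members[order(members$order_index), , drop = FALSE]
    oi <- sort(members$order_index)
    ## contiguity relative to the full bed table: no other bed may interleave
    inter <- beds$order_index > min(oi) & beds$order_index < max(oi) &
      !beds$order_index %in% oi
    if (any(inter) || any(diff(match(oi, sort(beds$order_index))) != 1))
      belem_error("belem_validation_error",
                  "beds pooled into '%s' are not stratigraphically contiguous",
                  pid)
    pooled <- members[1, , drop = FALSE]
    pooled$bed_id <- pid
    pooled$n_quadrats <- sum(members$n_quadrats)
    pooled$pool_group <- NA_character_
    new_beds <- rbind(new_beds, pooled)
  }
  new_beds <- new_beds[order(new_beds$order_index), , drop = FALSE]
  rownames(new_beds) <- NULL

  specimens <- ds$specimens
  hit <- specimens$bed_id %in% names(pooling)
  specimens$bed_id[hit] <- unname(pooling[specimens$bed_id[hit]])

  proxies <- ds$proxies
  if (!is.null(proxies)) {
    hit <- proxies$bed_id %in% names(pooling)
    proxies$bed_id[hit] <- unname(pooling[proxies$bed_id[hit]])
    agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    proxies <- do.call(rbind, lapply(split(proxies, proxies$bed_id), function(d)
      data.frame(bed_id = d$bed_id[1], d18O_permil = agg(d$d18O_permil),
                 d13C_permil = agg(d$d13C_permil), hg_toc = agg(d$hg_toc),
                 stringsAsFactors = FALSE)))
    rownames(proxies) <- NULL
  }
  belem_dataset(specimens, new_beds, proxies)
}

#' Assign per-bed proxy values from a height-indexed proxy series
#'
#' Geochemical proxy series are typically sampled at their own stratigraphic
#' heights rather than at the collected beds. This helper assigns to each bed
#' the proxy sample nearest in height; when two samples are equidistant, the
#' lower one wins. This nearest-height rule is a documented package choice,
#' not a convention inherited from any particular study.
#'
#' @param ds a `belem_dataset`.
#' @param proxy_heights data.frame with columns `height_m` and any of
#'   `d18O_permil`, `d13C_permil`, `hg_toc`.
#' @return The dataset with its `proxies` table replaced by the assignment.
#' @export
assign_proxies <- function(ds, proxy_heights) {
  stopifnot(inherits(ds, "belem_dataset"))
  ph <- as.data.frame(proxy_heights, stringsAsFactors = FALSE)
  if (!"height_m" %in% names(ph))
    belem_error("belem_schema_error", "proxy_heights lacks column height_m")
  ph <- ph[order(ph$height_m), , drop = FALSE]
  pick <- function(h, col) {
    ok <- !is.na(ph[[col]])
    if (!any(ok)) return(NA_real_)
    hh <- ph$height_m[ok]
    d <- abs(hh - h)
    ## ties -> lower height: hh is sorted, which.min returns the first (lower)
    ph[[col]][ok][which.min(d)]
  }
  proxies <- data.frame(
    bed_id = ds$beds$bed_id,
    d18O_permil = vapply(ds$beds$height_m, pick, 0.0, col = "d18O_permil"),
    d13C_permil = vapply(ds$beds$height_m, pick, 0.0, col = "d13C_permil"),
    hg_toc = vapply(ds$beds$height_m, pick, 0.0, col = "hg_toc"),
    stringsAsFactors = FALSE)
  for (col in c("d18O_permil", "d13C_permil", "hg_toc"))
    if (!col %in% names(ph)) proxies[[col]] <- NA_real_
  belem_dataset(ds$specimens, ds$beds, proxies)
}

## beds ordered by order_index (internal convenience)
.ordered_beds <- function(ds) ds$beds[order(ds$beds$order_index), , drop = FALSE]
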