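#' Read a feeding-episode table
#'
#' A feeding episode is one reported observation of a bird consuming (or
#' catching) a dietary item at a foraging location — the unit record of the
#' monitoring data. Episode files are comma-separated UTF-8 with a fixed
#' header: `species, year, month, item, location, altitude_band, feeder_flag,
#' site_note` (an optional `exclude_flag` column marks records an analyst has
#' flagged for removal, e.g. uncertain plant/animal material).
#'
#' Category labels are validated against the schema and never coerced: an
#' unknown item or location label is an error naming the offending row.
#'
#' @param path path to the episode CSV file.
#' @param schema a [diet_schema()].
#' @return A data frame of feeding episodes, one row per episode, with
#'   `month` integer in 1..12, `feeder_flag` logical and `exclude_flag`
#'   logical (filled with `FALSE` when the column is absent).
#' @seealso [read_raw_reports()] for the multi-item raw dialect,
#'   [apply_filters()], [tally_episodes()].
#' @export
read_episodes <- function(path, schema = diet_schema()) {
  if (!file.exists(path)) stop("episode file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  required <- c("species", "year", "month", "item", "location",
                "altitude_band", "feeder_flag", "site_note")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("episode file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"exclude_flag" %in% names(df)) df$exclude_flag <- "FALSE"
  if (nrow(df) == 0L) return(empty_episodes())
  validate_episodes(df, schema)
}

#' Write a feeding-episode table
#'
#' Inverse of [read_episodes()]: writes the documented CSV dialect so that
#' reading the file back reproduces the episode table exactly.
#'
#' @param episodes a feeding-episode data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read raw multi-record reports and expand them into episodes
#'
#' Volunteer reports sometimes describe several dietary items (and locations)
#' in one record. The raw dialect stores these as semicolon-delimited lists in
#' the `item` and `location` fields; each record is expanded into one episode
#' per (item, location) pairing, preserving order. Either the two lists have
#' equal length, or a single location applies to every item.
#'
#' @inheritParams read_episodes
#' @return A data frame of feeding episodes (one row per expanded episode).
#' @export
read_raw_reports <- function(path, schema = diet_schema()) {
  if (!file.exists(path)) stop("raw report file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  required <- c("species", "year", "month", "item", "location",
                "altitude_band", "feeder_flag", "site_note")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("raw report file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"exclude_flag" %in% names(df)) df$exclude_flag <- "FALSE"
  if (nrow(df) == 0L) return(empty_episodes())
  out <- lapply(seq_len(nrow(df)), function(i) expand_multirecord(df[i, ]))
  validate_episodes(do.call(rbind, out), schema)
}

#' Expand one raw report row into feeding episodes
#'
#' @param raw_row a one-row data frame in the raw-report dialect, whose
#'   `item`/`location` fields may be semicolon-delimited lists.
#' @return A data frame with one row per (item, location) pairing.
#' @export
expand_multirecord <- function(raw_row) {
  stopifnot(nrow(raw_row) == 1L)
  items <- trimws(strsplit(as.character(raw_row$item), ";", fixed = TRUE)[[1]])
  locs <- trimws(strsplit(as.character(raw_row$location), ";",
                          fixed = TRUE)[[1]])
  if (length(locs) == 1L) {
    locs <- rep(locs, length(items))
  } else if (length(locs) != length(items)) {
    stop("raw report row has ", length(items), " items but ", length(locs),
         " locations; lists must have equal length or a single location")
  }
  out <- raw_row[rep(1L, length(items)), , drop = FALSE]
  out$item <- items
  out$location <- locs
  rownames(out) <- NULL
  out
}

empty_episodes <- function() {
  data.frame(species = character(), year = integer(), month = integer(),
             item = character(), location = character(),
             altitude_band = character(), feeder_flag = logical(),
             site_note = character(), exclude_flag = logical(),
             stringsAsFactors = FALSE)
}

validate_episodes <- function(df, schema) {
  stopifnot(is_schema(schema))
  month <- suppressWarnings(as.integer(df$month))
  bad <- which(is.na(month) | month < 1L | month > 12L)
  if (length(bad) > 0L)
    stop("invalid month at row ", bad[1], ": '", df$month[bad[1]],
         "' (must be an integer in 1..12)")
  bad <- which(!(df$item %in% schema$items))
  if (length(bad) > 0L)
    stop("unknown dietary item label at row ", bad[1], ": '",
         df$item[bad[1]], "'")
  bad <- which(!(df$location %in% schema$locations))
  if (length(bad) > 0L)
    stop("unknown foraging location label at row ", bad[1], ": '",
         df$location[bad[1]], "'")
  data.frame(species = as.character(df$species),
             year = suppressWarnings(as.integer(df$year)),
             month = month,
             item = df$item,
             location = df$location,
             altitude_band = as.character(df$altitude_band),
             feeder_flag = as.logical(df$feeder_flag),
             site_note = as.character(df$site_note),
             exclude_flag = as.logical(df$exclude_flag) %in% TRUE,
             stringsAsFactors = FALSE)
}

#' Apply the standard exclusion filters to feeding episodes
#'
#' Removes (1) episodes at artificial bird feeders, (2) episodes outside the
#' lowland altitude band, (3) episodes lacking information on both the dietary
#' item and the foraging location, and (4) analyst-flagged episodes
#' (`exclude_flag`). Episodes with an unidentified item but a known location
#' are retained — they carry the location information the imputation model
#' uses.
#'
#' @param episodes a feeding-episode data frame.
#' @param lowland_label value of `altitude_band` that marks lowland records.
#' @return The filtered episode data frame, with attribute `"filter_counts"`
#'   recording how many episodes each rule removed.
#' @export
apply_filters <- function(episodes, lowland_label = "lowland") {
  n0 <- nrow(episodes)
  keep <- !(episodes$feeder_flag %in% TRUE)
  n_feeder <- sum(!keep)
  ep <- episodes[keep, , drop = FALSE]

  keep <- ep$altitude_band == lowland_label
  n_altitude <- sum(!keep)
  ep <- ep[keep, , drop = FALSE]

  keep <- !(ep$item == "unidentified" & ep$location == "unidentified")
  n_uninformative <- sum(!keep)
  ep <- ep[keep, , drop = FALSE]

  keep <- !(ep$exclude_flag %in% TRUE)
  n_flagged <- sum(!keep)
  ep <- ep[keep, , drop = FALSE]

  rownames(ep) <- NULL
  attr(ep, "filter_counts") <- c(input = n0, feeder = n_feeder,
                                 altitude = n_altitude,
                                 uninformative = n_uninformative,
                                 flagged = n_flagged, retained = nrow(ep))
  ep
}

#' Tally feeding episodes into a month x item x location counts tensor
#'
#' Pools all episodes of one species across years and cross-tabulates them by
#' month, dietary item and foraging location. The resulting tensor is the
#' sufficient statistic for every composition estimator in the package.
#' Months with zero episodes are retained as all-zero slices (required by the
#' seasonal smoother).
#'
#' @param episodes a filtered feeding-episode data frame.
#' @param species species to tally; defaults to the single species present.
#' @param schema a [diet_schema()].
#' @return An object of class `"counts_tensor"`: an integer array of dimension
#'   `12 x n_items x n_locations` with dimnames, species stored as an
#'   attribute, and `totals_by_month(x)` giving the monthly episode totals.
#' @export
tally_episodes <- function(episodes, species = NULL, schema = diet_schema()) {
  if (is.null(species)) {
    sp <- unique(episodes$species)
    if (length(sp) > 1L)
      stop("episodes contain ", length(sp),
           " species; pass `species` explicitly")
    species <- if (length(sp) == 1L) sp else NA_character_
  }
  ep <- episodes[episodes$species %in% species, , drop = FALSE]
  counts <- table(factor(ep$month, levels = 1:12, labels = month_labels()),
                  factor(ep$item, levels = schema$items),
                  factor(ep$location, levels = schema$locations))
  counts <- array(as.integer(counts), dim = dim(counts),
                  dimnames = list(month = month_labels(),
                                  item = schema$items,
                                  location = schema$locations))
  structure(counts, species = species, class = "counts_tensor")
}

#' Monthly episode totals of a counts tensor
#'
#' @param x a `"counts_tensor"`.
#' @return Integer vector of length 12: the number of feeding episodes per
#'   month (the per-species monthly tallies of a monitoring summary table).
#' @export
totals_by_month <- function(x) {
  stopifnot(inherits(x, "counts_tensor"))
  apply(unclass(x), 1L, sum)
}

#' @export
print.counts_tensor <- function(x, ...) {
  cat("Feeding-episode counts tensor for species:",
      attr(x, "species"), "\n")
  d <- dim(x)
  cat("  ", d[1], " months x ", d[2], " items x ", d[3], " locations; ",
      sum(x), " episodes\n", sep = "")
  print(totals_by_month(x))
  invisible(x)
}
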