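#' Read a stomach-content table
#'
#' Long-format CSV of literature stomach-analysis data: columns `study_id,
#' species, month, n_specimens, item, count`. One row gives the pooled count
#' of one dietary item in the stomachs of `n_specimens` birds examined by one
#' study in one month (parts for plant items, individuals for animal items;
#' uncountable material is recorded as 1).
#'
#' @param path path to the CSV file.
#' @param schema a [diet_schema()]; item labels must be identified items.
#' @return A data frame of stomach records.
#' @export
read_stomach <- function(path, schema = diet_schema()) {
  if (!file.exists(path)) stop("stomach file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("study_id", "species", "month", "n_specimens", "item", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("stomach file is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!(df$item %in% schema$identified_items))
  if (length(bad) > 0L)
    stop("unknown (or unidentified) item label at row ", bad[1], ": '",
         df$item[bad[1]], "'")
  bad <- which(is.na(df$month) | df$month < 1 | df$month > 12)
  if (length(bad) > 0L)
    stop("invalid month at row ", bad[1])
  if (any(df$count < 0)) stop("negative item count")
  if (any(df$n_specimens < 1)) stop("n_specimens must be >= 1")
  df$month <- as.integer(df$month)
  df
}

#' Drop species-month combinations with too few specimens
#'
#' Literature comparisons only use bird-month combinations with at least
#' `threshold` individual specimens pooled across studies (the standard rule
#' excludes months with fewer than five).
#'
#' @param records a stomach-record data frame (long format; one
#'   `study_id`-`species`-`month` block shares a single `n_specimens` value).
#' @param threshold minimum pooled specimen count to keep a species-month.
#' @return The filtered records.
#' @export
filter_min_specimens <- function(records, threshold = 5L) {
  if (nrow(records) == 0L) return(records)
  # n_specimens is per study-species-month block, repeated on item rows
  blocks <- unique(records[c("study_id", "species", "month", "n_specimens")])
  pooled <- stats::aggregate(n_specimens ~ species + month, data = blocks, sum)
  keep_key <- with(pooled[pooled$n_specimens >= threshold, , drop = FALSE],
                   paste(species, month))
  out <- records[paste(records$species, records$month) %in% keep_key, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count proportions (CPs) from stomach records
#'
#' The CP of an item in a month is the total number of that item detected —
#' pooled across bird individuals from all studies — divided by the total
#' number of all items detected in that month.
#'
#' @param records stomach records for one species.
#' @param species species name; defaults to the single species present.
#' @param schema a [diet_schema()].
#' @return A `"composition_table"` over identified items (`kind = "CP"`);
#'   the support column holds monthly total item counts.
#' @export
compute_cp <- function(records, species = NULL, schema = diet_schema()) {
  if (is.null(species)) {
    sp <- unique(records$species)
    if (length(sp) > 1L)
      stop("records contain ", length(sp),
           " species; pass `species` explicitly")
    species <- if (length(sp) == 1L) sp else NA_character_
  }
  rec <- records[records$species %in% species, , drop = FALSE]
  counts <- matrix(0, nrow = 12L, ncol = length(schema$identified_items),
                   dimnames = list(month = month_labels(),
                                   item = schema$identified_items))
  if (nrow(rec) > 0L) {
    agg <- stats::aggregate(count ~ month + item, data = rec, sum)
    counts[cbind(agg$month, match(agg$item, schema$identified_items))] <-
      agg$count
  }
  n_m <- rowSums(counts)
  composition_table(counts / ifelse(n_m > 0, n_m, NA_real_), n_m,
                    kind = "CP", species = species)
}

#' Root-mean-square difference between two composition tables for one item
#'
#' Pairs every species-month cell that is defined in both a monitoring-based
#' table (ROP over identified items, or MOP) and a stomach-based CP table,
#' and computes the RMSD of the item's proportions on the percentage scale:
#' `sqrt(mean((100 * p_monitoring - 100 * p_cp)^2))`, in percentage points.
#' Smaller means closer agreement.
#'
#' @param monitoring a `"composition_table"` (or named list of them, one per
#'   species) of kind `ROP_identified_only` or `MOP`.
#' @param cp a `"composition_table"` (or named list) of kind `CP`.
#' @param item identified-item label to compare.
#' @return An object of class `"rmsd_comparison"`: list with `item`, `rmsd`
#'   (percentage points) and `pairs` (data frame of the paired cells, in
#'   percent).
#' @export
rmsd_compare <- function(monitoring, cp, item) {
  as_list <- function(x) {
    if (inherits(x, "composition_table")) {
      out <- list(x)
      names(out) <- x$species
      out
    } else x
  }
  mon <- as_list(monitoring)
  cps <- as_list(cp)
  shared <- intersect(names(mon), names(cps))
  pairs <- list()
  for (sp in shared) {
    a <- mon[[sp]]; b <- cps[[sp]]
    if (!(item %in% colnames(a$values)) || !(item %in% colnames(b$values)))
      next
    both <- a$defined & b$defined
    if (!any(both)) next
    pairs[[sp]] <- data.frame(
      species = sp, month = which(both),
      monitoring = 100 * a$values[both, item],
      cp = 100 * b$values[both, item],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L)
    stop("no paired species-month cells for item '", item, "'")
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  structure(list(item = item,
                 rmsd = sqrt(mean((pairs$monitoring - pairs$cp)^2)),
                 pairs = pairs),
            class = "rmsd_comparison")
}

#' @export
print.rmsd_comparison <- function(x, ...) {
  cat(sprintf("RMSD for item '%s': %.3f percentage points over %d species-month cells\n",
              x$item, x$rmsd, nrow(x$pairs)))
  invisible(x)
}
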