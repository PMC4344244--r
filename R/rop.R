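#' Composition tables
#'
#' A composition table holds a species' monthly proportions over a set of
#' categories (dietary items or foraging locations), together with the
#' per-month support (episode or specimen totals). Months with zero support
#' are flagged undefined and their rows are `NA`, never silently zero, so
#' downstream comparisons and plots can skip them explicitly.
#'
#' @param values numeric matrix, 12 months (rows) by categories (columns);
#'   each defined row sums to 1.
#' @param support integer vector of length 12 of per-month totals.
#' @param kind one of `"ROP"`, `"ROP_identified_only"`, `"MOP"`, `"CP"`,
#'   `"location"`.
#' @param species species name.
#' @return An object of class `"composition_table"`.
#' @keywords internal
composition_table <- function(values, support, kind, species) {
  stopifnot(nrow(values) == 12L, length(support) == 12L)
  defined <- support > 0
  values[!defined, ] <- NA_real_
  rownames(values) <- month_labels()
  structure(list(values = values, support = as.integer(support),
                 defined = defined, kind = kind, species = species),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, digits = 3, ...) {
  cat(x$kind, "composition table for species:", x$species, "\n")
  m <- cbind(round(x$values, digits), support = x$support)
  print(m)
  if (any(!x$defined))
    cat("undefined months (zero support):",
        paste(month_labels()[!x$defined], collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.composition_table <- function(x, ...) x$values

#' Raw observation proportions (ROPs)
#'
#' The ROP of a dietary item in a month is the fraction of that month's
#' feeding episodes (pooled across years) recorded with that item, with
#' `"unidentified"` kept as its own category.
#'
#' @param counts a `"counts_tensor"` from [tally_episodes()].
#' @return A `"composition_table"` over all item categories (`kind = "ROP"`).
#' @export
compute_rop <- function(counts) {
  stopifnot(inherits(counts, "counts_tensor"))
  by_item <- apply(unclass(counts), c(1L, 2L), sum)
  n_m <- rowSums(by_item)
  composition_table(by_item / ifelse(n_m > 0, n_m, NA_real_), n_m,
                    kind = "ROP", species = attr(counts, "species"))
}

#' ROPs over identified items only
#'
#' Recomputes the monthly proportions after excluding unidentified episodes,
#' i.e. renormalizing over the identified item categories. This is the
#' monitoring-side quantity compared against stomach-content count
#' proportions. It is biased whenever identifiability depends on foraging
#' location; [fit_mop()] exists to correct that bias.
#'
#' @inheritParams compute_rop
#' @return A `"composition_table"` over identified items
#'   (`kind = "ROP_identified_only"`); months whose episodes are all
#'   unidentified are flagged undefined.
#' @export
rop_identified_only <- function(counts) {
  stopifnot(inherits(counts, "counts_tensor"))
  items <- dimnames(counts)$item
  keep <- items != "unidentified"
  by_item <- apply(unclass(counts)[, keep, , drop = FALSE], c(1L, 2L), sum)
  n_m <- rowSums(by_item)
  composition_table(by_item / ifelse(n_m > 0, n_m, NA_real_), n_m,
                    kind = "ROP_identified_only",
                    species = attr(counts, "species"))
}

#' Monthly foraging-location profile
#'
#' Monthly proportions of the foraging-location categories, over all episodes
#' (the location `"unidentified"` is an observed reporting outcome and counts
#' as a category).
#'
#' @inheritParams compute_rop
#' @return A `"composition_table"` over locations (`kind = "location"`).
#' @export
location_profile <- function(counts) {
  stopifnot(inherits(counts, "counts_tensor"))
  by_loc <- apply(unclass(counts), c(1L, 3L), sum)
  n_m <- rowSums(by_loc)
  composition_table(by_loc / ifelse(n_m > 0, n_m, NA_real_), n_m,
                    kind = "location", species = attr(counts, "species"))
}

breeding_months <- function() 4:9   # April-September
wintering_months <- function() c(10:12, 1:3)

seasonal_test <- function(tab, species, direction) {
  # tab: 2x2 integer matrix, rows = c(focal, other), cols = c(breeding, wintering)
  undefined <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (undefined) {
    return(structure(list(species = species, statistic = NA_real_,
                          p_one_sided = NA_real_, table = tab,
                          direction_ok = NA, defined = FALSE,
                          direction = direction),
                     class = "seasonal_test"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p_breed <- tab[1, 1] / sum(tab[, 1])
  p_winter <- tab[1, 2] / sum(tab[, 2])
  direction_ok <- if (direction == "breeding") p_breed > p_winter
                  else p_winter > p_breed
  p_two <- unname(ct$p.value)
  p_one <- if (isTRUE(direction_ok)) p_two / 2 else 1 - p_two / 2
  structure(list(species = species, statistic = unname(ct$statistic),
                 p_one_sided = p_one, table = tab,
                 direction_ok = isTRUE(direction_ok), defined = TRUE,
                 direction = direction),
            class = "seasonal_test")
}

#' @export
print.seasonal_test <- function(x, ...) {
  cat("One-sided chi-square seasonal test for species:", x$species, "\n")
  if (!x$defined) {
    cat("  undefined (degenerate margin)\n")
    return(invisible(x))
  }
  cat(sprintf("  X-squared = %.4f, one-sided p = %.4g (direction %s: %s)\n",
              x$statistic, x$p_one_sided,
              if (x$direction == "breeding") "breeding > wintering"
              else "wintering > breeding",
              if (x$direction_ok) "observed" else "reversed"))
  print(x$table)
  invisible(x)
}

#' Seasonal shift test for animal diets
#'
#' Tests whether the proportion of animal diets (invertebrate, fish,
#' amphibian and reptile, bird, mammal) among identified episodes is higher in
#' the breeding season (April-September) than in the wintering season
#' (October-March). Pearson chi-square on the 2x2 table of identified
#' episodes, without continuity correction; the one-sided p-value is half the
#' two-sided p when the shift is in the tested direction and `1 - p/2`
#' otherwise.
#'
#' @inheritParams compute_rop
#' @param schema the [diet_schema()] naming the animal items.
#' @return An object of class `"seasonal_test"` with elements `statistic`,
#'   `p_one_sided`, `table`, `direction_ok` and `defined` (FALSE when a
#'   margin of the table is zero).
#' @export
seasonal_animal_test <- function(counts, schema = diet_schema()) {
  stopifnot(inherits(counts, "counts_tensor"))
  items <- dimnames(counts)$item
  by_item <- apply(unclass(counts), c(1L, 2L), sum)
  identified <- items != "unidentified"
  animal <- items %in% schema$animal_items
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("animal", "non-animal"),
                                c("breeding", "wintering")))
  tab[1, 1] <- sum(by_item[breeding_months(), animal & identified])
  tab[2, 1] <- sum(by_item[breeding_months(), !animal & identified])
  tab[1, 2] <- sum(by_item[wintering_months(), animal & identified])
  tab[2, 2] <- sum(by_item[wintering_months(), !animal & identified])
  seasonal_test(tab, attr(counts, "species"), direction = "breeding")
}

#' Seasonal shift test for ground foraging
#'
#' Tests whether the proportion of episodes foraged on the ground increases
#' from the breeding season to the wintering season. Same construction as
#' [seasonal_animal_test()] with ground vs non-ground locations (all episodes,
#' identified or not) and direction wintering > breeding.
#'
#' @inheritParams compute_rop
#' @return A `"seasonal_test"`.
#' @export
seasonal_ground_test <- function(counts) {
  stopifnot(inherits(counts, "counts_tensor"))
  locs <- dimnames(counts)$location
  by_loc <- apply(unclass(counts), c(1L, 3L), sum)
  ground <- locs == "ground"
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("ground", "other"),
                                c("breeding", "wintering")))
  tab[1, 1] <- sum(by_loc[breeding_months(), ground])
  tab[2, 1] <- sum(by_loc[breeding_months(), !ground])
  tab[1, 2] <- sum(by_loc[wintering_months(), ground])
  tab[2, 2] <- sum(by_loc[wintering_months(), !ground])
  seasonal_test(tab, attr(counts, "species"), direction = "wintering")
}

#' Summary tallies for a set of species
#'
#' Per-species totals in the style of a monitoring-program summary table:
#' total episodes, identified episodes, proportion unidentified (rounded to 3
#' decimals) and the 12 monthly episode counts.
#'
#' @param episodes a filtered feeding-episode data frame.
#' @param schema a [diet_schema()].
#' @return A data frame with one row per species, ordered by decreasing total.
#' @export
species_summary <- function(episodes, schema = diet_schema()) {
  species <- unique(episodes$species)
  rows <- lapply(species, function(sp) {
    ct <- tally_episodes(episodes, sp, schema)
    tot <- sum(ct)
    ident <- tot - sum(unclass(ct)[, "unidentified", ])
    monthly <- totals_by_month(ct)
    out <- data.frame(species = sp, total = tot, identified = ident,
                      prop_unidentified = unidentified_proportion(tot, ident),
                      stringsAsFactors = FALSE)
    out[month_labels()] <- as.list(monthly)
    out
  })
  out <- do.call(rbind, rows)
  out[order(-out$total), , drop = FALSE]
}

#' Proportion of unidentified episodes from printed totals
#'
#' @param total total number of feeding episodes.
#' @param identified number of episodes with an identified dietary item.
#' @param digits decimals to round to (summary tables print 3, occasionally 4).
#' @return `(total - identified) / total`, rounded.
#' @export
unidentified_proportion <- function(total, identified, digits = 3) {
  round((total - identified) / total, digits)
}
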