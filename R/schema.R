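#' Category schema for dietary items and foraging locations
#'
#' A schema pairs the ordered list of dietary-item categories with the ordered
#' list of foraging-location categories used to classify feeding episodes.
#' Both lists carry an `"unidentified"` label, but the two play different
#' roles: an unidentified *item* is treated as missing data (to be imputed by
#' [fit_mop()]), whereas an unidentified *location* is an ordinary observed
#' reporting outcome — the observer saw the bird handling the item but not
#' where it was caught.
#'
#' The default schema is the standard classification for terrestrial resident
#' birds in volunteer monitoring programs: 11 dietary items (10 identified
#' plus `"unidentified"`) and 10 foraging locations.
#'
#' @param items character vector of dietary-item labels; must contain
#'   `"unidentified"` exactly once (conventionally last).
#' @param locations character vector of foraging-location labels; may contain
#'   `"unidentified"` at most once as an observed category.
#' @return An object of class `"diet_schema"`: a list with elements `items`,
#'   `locations`, `identified_items` (items minus the missing marker), and
#'   `animal_items` (the subset of `identified_items` that are animal diets,
#'   used by the seasonal contingency tests).
#' @examples
#' sch <- diet_schema()
#' sch$identified_items
#' # a reduced schema for simulation experiments
#' diet_schema(items = c("A", "B", "unidentified"), locations = c("g", "t"))
#' @export
diet_schema <- function(items = c("seed", "fleshy fruit", "flower",
                                  "leaf and bud", "invertebrate", "fish",
                                  "amphibian and reptile", "bird", "mammal",
                                  "man-made food", "unidentified"),
                        locations = c("ground", "puddle", "tree", "tree trunk",
                                      "tall grass", "short grass", "bush",
                                      "in the air", "man-made structure",
                                      "unidentified")) {
  items <- as.character(items)
  locations <- as.character(locations)
  if (anyDuplicated(items))
    stop("dietary item labels must be unique")
  if (anyDuplicated(locations))
    stop("foraging location labels must be unique")
  if (sum(items == "unidentified") != 1L)
    stop("items must contain 'unidentified' exactly once")
  if (sum(locations == "unidentified") > 1L)
    stop("locations may contain 'unidentified' at most once")
  if (length(items) < 2L)
    stop("need at least one identified item")
  animal <- c("invertebrate", "fish", "amphibian and reptile", "bird", "mammal")
  structure(
    list(items = items,
         locations = locations,
         identified_items = setdiff(items, "unidentified"),
         animal_items = intersect(animal, items)),
    class = "diet_schema")
}

#' @export
print.diet_schema <- function(x, ...) {
  cat("Diet/location category schema\n")
  cat("  items (", length(x$items), "): ",
      paste(x$items, collapse = ", "), "\n", sep = "")
  cat("  locations (", length(x$locations), "): ",
      paste(x$locations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# months are fixed: analyses pool years and work on the 12-month cycle
month_labels <- function() month.abb

is_schema <- function(x) inherits(x, "diet_schema")
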