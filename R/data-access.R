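#' Published monitoring summary for the 15 focal resident birds
#'
#' Per-species totals from a 29-year volunteer monitoring program of
#' terrestrial resident birds in lowland Kanagawa, central Japan: total
#' feeding episodes, episodes with an identified dietary item, and monthly
#' episode counts. Shipped as a plain-text table; useful for checking the
#' summary arithmetic ([unidentified_proportion()]) and as realistic monthly
#' sample-size profiles for simulation studies.
#'
#' @return A data frame with columns `species`, `total`, `identified` and the
#'   12 month columns `Jan` .. `Dec`.
#' @examples
#' fs <- focal_species_summary()
#' unidentified_proportion(fs$total, fs$identified)
#' @export
focal_species_summary <- function() {
  path <- system.file("extdata", "focal_species_summary.csv",
                      package = "birdiet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
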