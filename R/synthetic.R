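#' Ground truth for synthetic monitoring data
#'
#' Defines the generating process of a synthetic species: true monthly
#' expected item frequencies (smooth log-sinusoidal seasonal curves by
#' default), a location-given-item probability row per item, and a
#' location-dependent probability that an episode's item is recorded as
#' unidentified. This emulates the statistical structure the imputation model
#' assumes — item identifiability driven by foraging location — and the
#' optional `miss_item_modifier` creates a controlled violation of it
#' (item-dependent missingness) for robustness experiments.
#'
#' Defaults give a desk-scale recovery experiment: 12 months, 4 identified
#' items, 3 locations, 40 episodes per month, and missingness probabilities
#' spread evenly between 0.1 and 0.6 across locations.
#'
#' @param n_items number of identified dietary items.
#' @param n_locations number of foraging locations.
#' @param n_per_month episodes per month (scalar or length-12 vector).
#' @param lambda_true optional `12 x n_items` matrix of positive monthly
#'   frequencies; default draws smooth curves
#'   `log lambda[m, k] = c_k + A_k * sin(2 * pi * (m - phi_k) / 12)`.
#' @param theta_true optional `n_items x n_locations` stochastic matrix;
#'   default gives each item a distinct preferred location.
#' @param miss_prob per-location probability that the item of an episode at
#'   that location is recorded as unidentified; default
#'   `seq(0.1, 0.6, length.out = n_locations)`.
#' @param miss_item_modifier per-item multiplier on `miss_prob` (all 1 keeps
#'   missingness location-only, the model's assumption).
#' @param species synthetic species name.
#' @param seed integer seed; drives both the curve generation and
#'   [generate_episodes()].
#' @return An object of class `"synthetic_truth"`; element `schema` is the
#'   matching [diet_schema()] (items plus `"unidentified"`), and `pi_true`
#'   holds the true monthly item proportions (normalised `lambda_true` rows).
#' @export
synthetic_truth <- function(n_items = 4L, n_locations = 3L, n_per_month = 40L,
                            lambda_true = NULL, theta_true = NULL,
                            miss_prob = NULL, miss_item_modifier = NULL,
                            species = "synthetic species", seed = 1L) {
  items <- paste0("item", seq_len(n_items))
  locations <- paste0("loc", seq_len(n_locations))
  if (length(n_per_month) == 1L) n_per_month <- rep(n_per_month, 12L)
  stopifnot(length(n_per_month) == 12L)
  set.seed(as.integer(seed))
  if (is.null(lambda_true)) {
    c_k <- stats::runif(n_items, log(2), log(12))
    a_k <- stats::runif(n_items, 0.5, 1.5)
    phi_k <- stats::runif(n_items, 0, 12)
    lambda_true <- sapply(seq_len(n_items), function(k)
      exp(c_k[k] + a_k[k] * sin(2 * pi * ((1:12) - phi_k[k]) / 12)))
  }
  stopifnot(nrow(lambda_true) == 12L, ncol(lambda_true) == n_items,
            all(lambda_true > 0))
  if (is.null(theta_true)) {
    theta_true <- matrix(1, n_items, n_locations)
    theta_true[cbind(seq_len(n_items),
                     (seq_len(n_items) - 1L) %% n_locations + 1L)] <-
      2 * n_locations
    theta_true <- theta_true / rowSums(theta_true)
  }
  stopifnot(nrow(theta_true) == n_items, ncol(theta_true) == n_locations,
            all(abs(rowSums(theta_true) - 1) < 1e-8))
  if (is.null(miss_prob)) miss_prob <- seq(0.1, 0.6,
                                           length.out = n_locations)
  stopifnot(length(miss_prob) == n_locations,
            all(miss_prob >= 0), all(miss_prob <= 1))
  if (is.null(miss_item_modifier)) miss_item_modifier <- rep(1, n_items)
  stopifnot(length(miss_item_modifier) == n_items)
  dimnames(lambda_true) <- list(month = month_labels(), item = items)
  dimnames(theta_true) <- list(item = items, location = locations)
  names(miss_prob) <- locations
  structure(
    list(schema = diet_schema(items = c(items, "unidentified"),
                              locations = locations),
         lambda_true = lambda_true,
         pi_true = lambda_true / rowSums(lambda_true),
         theta_true = theta_true, miss_prob = miss_prob,
         miss_item_modifier = miss_item_modifier,
         n_per_month = as.integer(n_per_month),
         species = species, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth for", x$species, "\n")
  cat("  ", ncol(x$lambda_true), " items x ", ncol(x$theta_true),
      " locations; ", sum(x$n_per_month), " episodes/year; miss_prob ",
      paste(round(x$miss_prob, 2), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic feeding-episode table
#'
#' For every month, each episode draws its item from the month's true item
#' distribution, its location from the item's location row, and is then
#' recorded as `"unidentified"` with the location's missingness probability
#' (times the item's modifier). Deterministic given `truth$seed`.
#'
#' @param truth a [synthetic_truth()].
#' @return A list with `episodes` (a feeding-episode data frame, lowland,
#'   feeder-free, ready for [tally_episodes()]) and `truth` (with the true
#'   item of every episode attached as `truth$true_items`).
#' @export
generate_episodes <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 1L)
  items <- colnames(truth$lambda_true)
  locations <- colnames(truth$theta_true)
  rows <- vector("list", 12L)
  true_items <- vector("list", 12L)
  for (m in 1:12) {
    n <- truth$n_per_month[m]
    if (n == 0L) {
      rows[[m]] <- NULL
      next
    }
    k <- sample.int(length(items), n, replace = TRUE,
                    prob = truth$pi_true[m, ])
    l <- vapply(k, function(ki)
      sample.int(length(locations), 1L, prob = truth$theta_true[ki, ]), 0L)
    p_miss <- pmin(1, truth$miss_prob[l] * truth$miss_item_modifier[k])
    hidden <- stats::runif(n) < p_miss
    rows[[m]] <- data.frame(
      species = truth$species, year = 2000L, month = m,
      item = ifelse(hidden, "unidentified", items[k]),
      location = locations[l],
      altitude_band = "lowland", feeder_flag = FALSE, site_note = "",
      exclude_flag = FALSE, stringsAsFactors = FALSE)
    true_items[[m]] <- items[k]
  }
  truth$true_items <- unlist(true_items)
  list(episodes = do.call(rbind, rows), truth = truth)
}

#' Generate synthetic stomach-content records
#'
#' Emulates literature stomach-analysis tables: each specimen's total item
#' count is Poisson(`items_per_specimen`) and item identities follow the
#' month's true item distribution; counts are pooled into one record per
#' month under a single synthetic study id.
#'
#' @param truth a [synthetic_truth()].
#' @param items_per_specimen expected number of diet items per stomach.
#' @param n_specimens specimens per month (scalar or length-12).
#' @return A long-format stomach-record data frame (columns `study_id,
#'   species, month, n_specimens, item, count`) as read by [read_stomach()].
#' @export
generate_stomach <- function(truth, items_per_specimen = 10,
                             n_specimens = 6L) {
  stopifnot(inherits(truth, "synthetic_truth"), items_per_specimen > 0)
  if (length(n_specimens) == 1L) n_specimens <- rep(n_specimens, 12L)
  set.seed(truth$seed + 2L)
  items <- colnames(truth$lambda_true)
  rows <- vector("list", 12L)
  for (m in 1:12) {
    ns <- n_specimens[m]
    if (ns == 0L) next
    total <- sum(stats::rpois(ns, items_per_specimen))
    counts <- if (total > 0L)
      as.integer(stats::rmultinom(1L, total, truth$pi_true[m, ]))
    else integer(length(items))
    rows[[m]] <- data.frame(
      study_id = "synthetic-study", species = truth$species, month = m,
      n_specimens = ns, item = items, count = counts,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean total-variation distance between a composition table and the truth
#'
#' For each defined month, half the L1 distance between the table's row and
#' the true item distribution restricted/renormalised to the table's
#' categories; averaged over defined months. Used by recovery experiments to
#' score how close ROPs and MOPs come to the generating distribution.
#'
#' @param tab a `"composition_table"` over identified items.
#' @param truth a [synthetic_truth()].
#' @return Mean total-variation distance (0 = exact recovery).
#' @export
tv_to_truth <- function(tab, truth) {
  stopifnot(inherits(tab, "composition_table"),
            inherits(truth, "synthetic_truth"))
  items <- colnames(truth$pi_true)
  stopifnot(all(items %in% colnames(tab$values)))
  tv <- vapply(which(tab$defined), function(m)
    0.5 * sum(abs(tab$values[m, items] - truth$pi_true[m, ])), 0)
  mean(tv)
}
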