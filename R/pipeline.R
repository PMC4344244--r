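#' Write a composition table as CSV
#'
#' One row per month with the category proportions and a `support` column;
#' undefined months keep `NA` proportions.
#'
#' @param tab a `"composition_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(tab, path) {
  df <- data.frame(month = month_labels(), tab$values,
                   support = tab$support, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full monitoring-to-comparison pipeline
#'
#' Orchestrates the stages: read and filter feeding episodes, tally each
#' species, compute ROPs, identified-only ROPs, foraging-location profiles
#' and the two seasonal chi-square tests, fit the Bayesian imputation model
#' and compute MOPs, and — when stomach data are supplied — compute CPs and
#' the per-item RMSD comparison of ROPs and MOPs against CPs. All artifacts
#' are written as CSV under `outdir`; a plain-text log records stage-tagged
#' progress and every filter count. All randomness flows from the single
#' `seed` entry, so identical configurations yield byte-identical outputs.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{episodes}{path to an episode CSV (or `raw_reports` for the
#'       multi-item dialect).}
#'     \item{stomach}{optional path to a stomach-record CSV; when absent the
#'       comparison stage is skipped with a logged notice.}
#'     \item{outdir}{output directory (created if needed).}
#'     \item{species}{optional character vector; default = all species found.}
#'     \item{seed}{master integer seed (default 1).}
#'     \item{mop}{optional list of [mop_control()] overrides.}
#'     \item{min_specimens}{specimen threshold for the comparison (default 5).}
#'     \item{items, locations}{optional schema overrides.}
#'   }
#' @return Invisibly, a list with the per-species results (`counts`, `rop`,
#'   `rop_identified`, `locations`, `mop_fit`, `mop`), the `summary` table,
#'   `seasonal_tests`, and (if computed) `cp` and `rmsd`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must name an output directory 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  log_lines <- character()
  say <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  default <- diet_schema()
  schema <- diet_schema(
    items = if (is.null(config$items)) default$items else config$items,
    locations = if (is.null(config$locations)) default$locations
                else config$locations)

  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  episodes <- stage_wrap("episodes", {
    if (!is.null(config$raw_reports)) {
      say("episodes", "reading raw reports from ", config$raw_reports)
      read_raw_reports(config$raw_reports, schema)
    } else if (!is.null(config$episodes)) {
      say("episodes", "reading episodes from ", config$episodes)
      read_episodes(config$episodes, schema)
    } else stop("config must name 'episodes' or 'raw_reports'")
  })
  episodes <- apply_filters(episodes)
  fc <- attr(episodes, "filter_counts")
  say("episodes", "filters: ", paste(names(fc), fc, sep = "=", collapse = ", "))

  species <- config$species
  if (is.null(species)) species <- sort(unique(episodes$species))
  say("episodes", length(species), " species to analyse")

  summary_tab <- species_summary(episodes[episodes$species %in% species, ,
                                          drop = FALSE], schema)
  utils::write.csv(summary_tab, file.path(outdir, "species_summary.csv"),
                   row.names = FALSE)

  mop_args <- config$mop
  control <- if (is.null(mop_args)) mop_control()
             else do.call(mop_control, mop_args)

  results <- list()
  seasonal <- list()
  for (sp in species) {
    tag <- gsub("[^A-Za-z0-9]+", "_", sp)
    counts <- stage_wrap("tally", tally_episodes(episodes, sp, schema))
    rop <- compute_rop(counts)
    rop_id <- rop_identified_only(counts)
    locs <- location_profile(counts)
    write_composition(rop, file.path(outdir, paste0("rop_", tag, ".csv")))
    write_composition(rop_id,
                      file.path(outdir, paste0("rop_identified_", tag, ".csv")))
    write_composition(locs, file.path(outdir, paste0("location_", tag, ".csv")))
    st_animal <- seasonal_animal_test(counts, schema)
    st_ground <- seasonal_ground_test(counts)
    seasonal[[sp]] <- data.frame(
      species = sp,
      test = c("animal_diet", "ground_foraging"),
      statistic = c(st_animal$statistic, st_ground$statistic),
      p_one_sided = c(st_animal$p_one_sided, st_ground$p_one_sided),
      direction_ok = c(st_animal$direction_ok, st_ground$direction_ok),
      stringsAsFactors = FALSE)
    say("mop", "fitting imputation model for ", sp)
    fit <- stage_wrap("mop", fit_mop(counts, control, seed = seed))
    mop <- compute_mop(fit)
    write_composition(mop, file.path(outdir, paste0("mop_", tag, ".csv")))
    utils::write.csv(fit$diagnostics,
                     file.path(outdir, paste0("mop_diagnostics_", tag, ".csv")),
                     row.names = FALSE)
    results[[sp]] <- list(counts = counts, rop = rop, rop_identified = rop_id,
                          locations = locs, mop_fit = fit, mop = mop)
  }
  seasonal <- do.call(rbind, seasonal)
  rownames(seasonal) <- NULL
  utils::write.csv(seasonal, file.path(outdir, "seasonal_tests.csv"),
                   row.names = FALSE)

  out <- list(results = results, summary = summary_tab,
              seasonal_tests = seasonal)

  if (is.null(config$stomach)) {
    say("compare", "no stomach data configured; comparison stage skipped")
  } else {
    records <- stage_wrap("stomach", read_stomach(config$stomach, schema))
    threshold <- if (is.null(config$min_specimens)) 5L
                 else as.integer(config$min_specimens)
    records <- filter_min_specimens(records, threshold)
    cp <- lapply(intersect(species, unique(records$species)),
                 function(sp) compute_cp(records, sp, schema))
    names(cp) <- vapply(cp, function(x) x$species, "")
    for (sp in names(cp))
      write_composition(cp[[sp]],
                        file.path(outdir, paste0("cp_", gsub("[^A-Za-z0-9]+",
                                                             "_", sp), ".csv")))
    rop_list <- lapply(results[names(cp)], function(r) r$rop_identified)
    mop_list <- lapply(results[names(cp)], function(r) r$mop)
    rmsd_rows <- list()
    for (item in schema$identified_items) {
      r_rop <- tryCatch(rmsd_compare(rop_list, cp, item),
                        error = function(e) NULL)
      r_mop <- tryCatch(rmsd_compare(mop_list, cp, item),
                        error = function(e) NULL)
      if (is.null(r_rop) || is.null(r_mop)) next
      rmsd_rows[[item]] <- data.frame(item = item, rmsd_rop = r_rop$rmsd,
                                      rmsd_mop = r_mop$rmsd,
                                      n_pairs = nrow(r_rop$pairs),
                                      stringsAsFactors = FALSE)
    }
    rmsd_tab <- do.call(rbind, rmsd_rows)
    if (!is.null(rmsd_tab)) {
      rownames(rmsd_tab) <- NULL
      utils::write.csv(rmsd_tab, file.path(outdir, "rmsd_summary.csv"),
                       row.names = FALSE)
      say("compare", "RMSD computed for ", nrow(rmsd_tab), " items")
    } else {
      say("compare", "no overlapping species-month cells; RMSD table empty")
    }
    out$cp <- cp
    out$rmsd <- rmsd_tab
  }

  writeLines(log_lines, log_path)
  invisible(out)
}

#' Write a synthetic data bundle
#'
#' Generates a synthetic species with [synthetic_truth()] and writes
#' `episodes.csv`, `stomach.csv` and the generating parameters
#' (`truth_lambda.csv`, `truth_theta.csv`, `truth_miss.csv`) to a directory,
#' ready to be fed back through [run_pipeline()].
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param ... further arguments to [synthetic_truth()].
#' @return Invisibly, the [synthetic_truth()] used.
#' @export
simulate_bundle <- function(outdir, seed = 1L, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- synthetic_truth(seed = seed, ...)
  gen <- generate_episodes(truth)
  write_episodes(gen$episodes, file.path(outdir, "episodes.csv"))
  utils::write.csv(generate_stomach(truth),
                   file.path(outdir, "stomach.csv"), row.names = FALSE)
  utils::write.csv(data.frame(month = month_labels(), truth$lambda_true,
                              check.names = FALSE),
                   file.path(outdir, "truth_lambda.csv"), row.names = FALSE)
  utils::write.csv(data.frame(item = rownames(truth$theta_true),
                              truth$theta_true, check.names = FALSE),
                   file.path(outdir, "truth_theta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(location = names(truth$miss_prob),
                              miss_prob = truth$miss_prob),
                   file.path(outdir, "truth_miss.csv"), row.names = FALSE)
  invisible(gen$truth)
}
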