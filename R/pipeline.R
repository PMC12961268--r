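#' Load a pipeline run configuration
#'
#' Reads a YAML configuration with the blocks the pipeline needs. Recognised
#' keys (all optional unless noted):
#' * `simulate`: arguments for [sim_config()] — mutually exclusive with
#'   `input_dir`, a directory of `YYYYQn` subdirectories of FAERS ASCII files.
#' * `quarters`: `from`/`to` labels (default 2014Q1-2024Q3) filtering
#'   ingested quarters.
#' * `exposure`: arguments for [exposure_rule()].
#' * `term_sets`: path to a term-set CSV (default: shipped SMQ lists).
#' * `unmasking`: named list of class-name vectors (default:
#'   [default_unmasking_classes()]).
#' * `ic_method`: `"shrinkage"` (default) or `"plain"`.
#' * `seed`: integer, overrides `simulate$seed`.
#' * `output_dir`: where [run_pipeline()] writes results.
#'
#' @param path YAML file path, or a list already in this shape.
#' @return A validated configuration list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  if (is.null(cfg$simulate) && is.null(cfg$input_dir)) {
    stop("config must have either a `simulate` block or `input_dir`",
         call. = FALSE)
  }
  cfg$quarters <- cfg$quarters %||% list(from = "2014Q1", to = "2024Q3")
  for (q in unlist(cfg$quarters)) {
    if (!grepl("^[0-9]{4}Q[1-4]$", q)) {
      stop("invalid quarter label: ", q, call. = FALSE)
    }
  }
  if (cfg$quarters$from > cfg$quarters$to) {
    stop("empty quarter range: ", cfg$quarters$from, " > ", cfg$quarters$to,
         call. = FALSE)
  }
  cfg$ic_method <- cfg$ic_method %||% "shrinkage"
  stopifnot(cfg$ic_method %in% c("shrinkage", "plain"))
  cfg$seed <- as.integer(cfg$seed %||% cfg$simulate$seed %||% 1L)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes ingest (or simulate) -> deduplicate -> normalize drug names ->
#' cohort/event classification -> descriptive tables -> signal estimates
#' (baseline, per PT, unmasked, sex-stratified) -> time-to-onset analysis ->
#' reporting-year counts, and (when `output_dir` is set) writes every result
#' as CSV plus a machine-readable JSON run manifest with per-stage counts.
#' Identical configuration and seed give identical results.
#'
#' @param config a [run_config()], a path to one, or a list.
#' @return Invisibly, a named list of result data.frames plus the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  log_counts <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sc <- do.call(sim_config, sim_args)
    gen <- generate_dataset(sc)
    dup <- inject_duplicates(gen$tables, sc$duplicate_rate,
                             seed = config$seed + 1L,
                             ground_truth = gen$ground_truth)
    tables <- dup$tables
    ground_truth <- dup$ground_truth
  } else {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    labs <- basename(dirs)
    sel <- grepl("^[0-9]{4}Q[1-4]$", labs) & labs >= config$quarters$from &
      labs <= config$quarters$to
    if (!any(sel)) stop("no quarter directories in range under ",
                        config$input_dir, call. = FALSE)
    bundles <- lapply(dirs[sel], read_quarter)
    tables <- bind_quarters(bundles)
    ground_truth <- NULL
  }
  log_counts$reports_in <- nrow(tables$demo)

  tables <- deduplicate(tables)
  log_counts$reports_after_dedup <- nrow(tables$demo)
  log_counts$duplicates_removed <- log_counts$reports_in -
    log_counts$reports_after_dedup

  tables <- normalize_drugs(tables, synonym_table())
  term_sets <- if (!is.null(config$term_sets)) {
    read_term_sets(config$term_sets)
  } else {
    default_term_sets()
  }
  rule <- do.call(exposure_rule, config$exposure %||% list())
  frame <- report_frame(tables, rule, term_sets)
  log_counts$cohort_sizes <- as.list(table(frame$exposure))

  results <- list()
  results$cohorts <- frame
  for (nm in names(term_sets)) {
    results[[paste0("descriptive_", nm)]] <-
      build_descriptive_table(frame, nm)
  }
  results$signals <- signal_table(tables, frame, term_sets, per_pt = TRUE,
                                  ic_method = config$ic_method)

  unmask_specs <- config$unmasking %||% default_unmasking_classes()
  um_rows <- list()
  for (spec_name in names(unmask_specs)) {
    for (nm in names(term_sets)) {
      est <- run_unmasking(tables, frame, nm, unmask_specs[[spec_name]],
                           ic_method = config$ic_method)
      um_rows[[length(um_rows) + 1L]] <- data.frame(
        exclusion = spec_name, term_set = nm, a = est$a, b = est$b,
        c = est$c, d = est$d, ror = est$ror, ror_ci_low = est$ror_ci_low,
        ror_ci_high = est$ror_ci_high, ic = est$ic, ic025 = est$ic025,
        estimable = est$estimable, is_signal = est$is_signal,
        stringsAsFactors = FALSE)
    }
  }
  results$unmasking <- do.call(rbind, um_rows)

  suicide_set <- term_sets[["suicide_self_injury"]]
  if (!is.null(suicide_set)) {
    results$sex_subgroups <- sex_subgroup_analysis(
      tables, frame, suicide_set, ic_method = config$ic_method)
  }

  results$tto <- tto_stage(tables, frame, term_sets)
  results$tto_histogram <- tto_histogram_stage(tables, frame, term_sets)
  results$reporting_years <- reporting_year_counts(frame)

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersdp")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    ic_method = config$ic_method,
    counts = log_counts,
    config_hash = config_hash(config)
  )
  results$manifest <- manifest

  if (!is.null(config$output_dir)) {
    export_results(results, config$output_dir, format = "csv")
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

tto_stage <- function(tables, frame, term_sets) {
  rows <- list()
  groups <- list(combination = "glp1ra", glp1ra_only = "glp1ra",
                 metformin_only = "metformin")
  for (nm in names(term_sets)) {
    flag <- frame[[paste0("event_", nm)]]
    for (ex in names(groups)) {
      tto <- extract_tto(tables, target_class = groups[[ex]])
      keep <- flag & frame$exposure == ex & tto$included
      x <- tto$tto_days[keep]
      if (length(x) == 0L) next
      mq <- median_iqr(x)
      fit <- if (length(x) >= 3L && length(unique(x)) >= 2L) {
        tryCatch(fit_weibull(x), error = function(e) NULL)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        term_set = nm, exposure = ex, n = mq$n, median = mq$median,
        q25 = mq$q25, q75 = mq$q75,
        scale_alpha = fit$scale_alpha %||% NA_real_,
        scale_ci_low = fit$scale_ci_low %||% NA_real_,
        scale_ci_high = fit$scale_ci_high %||% NA_real_,
        shape_beta = fit$shape_beta %||% NA_real_,
        shape_ci_low = fit$shape_ci_low %||% NA_real_,
        shape_ci_high = fit$shape_ci_high %||% NA_real_,
        failure_type = fit$failure_type %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

tto_histogram_stage <- function(tables, frame, term_sets) {
  rows <- list()
  groups <- list(combination = "glp1ra", glp1ra_only = "glp1ra",
                 metformin_only = "metformin")
  for (nm in names(term_sets)) {
    flag <- frame[[paste0("event_", nm)]]
    for (ex in names(groups)) {
      tto <- extract_tto(tables, target_class = groups[[ex]])
      keep <- flag & frame$exposure == ex & tto$included
      x <- tto$tto_days[keep]
      if (length(x) == 0L) next
      h <- onset_histogram(x)
      h$term_set <- nm
      h$exposure <- ex
      rows[[length(rows) + 1L]] <- h[c("term_set", "exposure", "bin",
                                       "count", "percent")]
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Reporting-year counts
#'
#' Number of reports per receipt year (the reporting-trend export).
#'
#' @param frame a [report_frame()].
#' @return data.frame with `year`, `n`; `sum(n)` equals `nrow(frame)`.
#' @export
reporting_year_counts <- function(frame) {
  tab <- table(factor(frame$year))
  data.frame(year = as.integer(names(tab)), n = as.integer(tab))
}

#' Export pipeline results
#'
#' @param results named list of data.frames (list entries that are not
#'   data.frames, e.g. the manifest, are written as JSON).
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(results, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (format == "json") {
    path <- file.path(dir, "results.json")
    out <- lapply(results, function(x) {
      if (is.data.frame(x)) x[!vapply(x, is.list, TRUE)] else x
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x[!vapply(x, is.list, TRUE)], path, row.names = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a synthetic dataset as quarterly FAERS ASCII files
#'
#' @param tables a [faers_tables] bundle.
#' @param dir output directory; one `YYYYQn` subdirectory per quarter.
#' @return Invisibly, the quarter labels written.
#' @export
write_faers_dataset <- function(tables, dir) {
  qs <- split_quarters(tables)
  for (lab in names(qs)) write_quarter(qs[[lab]], file.path(dir, lab))
  invisible(names(qs))
}
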