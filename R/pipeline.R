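# End-to-end orchestration: generate a cohort, run the repeated-split
# protocol, render the summary table. Functions are file-oriented so a
# whole analysis is reproducible from one config object (or YAML/JSON
# file) and one master seed.

#' Assemble a full pipeline configuration
#'
#' @param cohort A [cohort_config()]; defaults to the published cohort
#'   geometry (`preset = "published"`).
#' @param net A [network_spec()] or `NULL` (derived from the cohort data).
#' @param profile `"fast"` (scaled schedule, 5 runs) or `"published"`
#'   (published schedule, 50 runs). Determines training defaults and
#'   `n_runs` unless overridden.
#' @param train Optional [train_config()] overriding the profile's.
#' @param n_runs Number of cross-validation experiments.
#' @param n_train,n_test,n_validation Case-level split sizes.
#' @param master_seed Integer master seed.
#' @param output_dir Directory for generated files.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(preset = "published"),
                            net = NULL,
                            profile = c("fast", "published"),
                            train = NULL,
                            n_runs = NULL,
                            n_train = 229, n_test = 29, n_validation = 28,
                            master_seed = 1,
                            output_dir = "fluordx-output") {
  profile <- match.arg(profile)
  structure(
    list(
      cohort = cohort,
      net = net,
      profile = profile,
      train = train %||% train_config(profile),
      n_runs = as.integer(n_runs %||% switch(profile, fast = 5L, published = 50L)),
      n_train = as.integer(n_train),
      n_test = as.integer(n_test),
      n_validation = as.integer(n_validation),
      master_seed = as.integer(master_seed),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  profile:", x$profile, " runs:", x$n_runs, "\n")
  cat("  split:", x$n_train, "/", x$n_test, "/", x$n_validation, "cases\n")
  cat("  master seed:", x$master_seed, "\n")
  cat("  training: lr", x$train$learning_rate, "epochs", x$train$max_epochs,
      "patience", x$train$patience, "\n")
  cat("  output:", x$output_dir, "\n")
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()],
#' [cohort_config()] and [train_config()]; unknown keys are rejected.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "fluordx_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("cohort", "train", "profile", "n_runs", "n_train", "n_test",
             "n_validation", "master_seed", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "fluordx_value_error")
  }
  cohort <- if (is.null(raw$cohort)) cohort_config(preset = "published")
            else do.call(cohort_config, raw$cohort)
  train <- if (is.null(raw$train)) NULL else do.call(train_config, raw$train)
  args <- raw[setdiff(names(raw), c("cohort", "train"))]
  do.call(pipeline_config, c(list(cohort = cohort, train = train), args))
}

pipeline_log <- function(dir, event, config, elapsed = NULL) {
  line <- sprintf(
    "%s\t%s\tconfig_hash=%s\tseed=%s\tfluordx=%s%s",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), event,
    rlang::hash(config), config$master_seed %||% config$seed %||% "NA",
    as.character(utils::packageVersion("fluordx")),
    if (is.null(elapsed)) "" else sprintf("\telapsed_s=%.2f", elapsed)
  )
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

#' Generate a cohort and write it to disk
#'
#' Writes `cohort.csv` (the spectra table), `cohort_meta.json` (counts and
#' generator settings) and appends to `pipeline.log`. The CSV depends only
#' on the generator config and seed, so identical configs give identical
#' files.
#'
#' @param config A `pipeline_config`.
#' @param dir Output directory (created if missing); defaults to
#'   `config$output_dir`.
#' @return Path to the written spectra table, invisibly.
#' @export
pipeline_generate <- function(config, dir = config$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort)
  path <- file.path(dir, "cohort.csv")
  write_spectra(cohort, path)
  summary <- spectra_summary(cohort)
  meta <- list(
    preset = config$cohort$preset,
    seed = config$cohort$seed,
    excitations_nm = config$cohort$excitations,
    n_channels = length(config$cohort$emission_grid),
    counts = as.list(stats::setNames(summary$n_spectra, summary$label)),
    cases = as.list(stats::setNames(summary$n_cases, summary$label))
  )
  jsonlite::write_json(meta, file.path(dir, "cohort_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log(dir, "generate", config$cohort,
               proc.time()[["elapsed"]] - t0)
  invisible(path)
}

#' Run the full cross-validation pipeline and write results
#'
#' Generates the cohort if `cohort.csv` is absent from `dir`, runs
#' [cross_validate()], and writes `runs.csv` (one row per experiment),
#' `summary.csv` (Table-style order statistics for specificity and
#' sensitivity), per-run training histories and ROC points under
#' `history/` and `roc/`, and optionally per-run plots.
#'
#' @param config A `pipeline_config`.
#' @param dir Output directory.
#' @param plots Write `autoplot` PNGs per run (off by default; plotting
#'   devices are not available everywhere).
#' @return The `cv_runs` tibble, invisibly.
#' @export
pipeline_crossval <- function(config, dir = config$output_dir,
                              plots = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "cohort.csv")
  if (!file.exists(cohort_path)) pipeline_generate(config, dir)
  cohort <- read_spectra(cohort_path)

  runs <- cross_validate(
    cohort, n_runs = config$n_runs,
    n_train = config$n_train, n_test = config$n_test,
    n_validation = config$n_validation,
    net_spec = config$net, config = config$train,
    master_seed = config$master_seed, detail = TRUE
  )
  readr::write_csv(as_tibble(runs), file.path(dir, "runs.csv"))
  readr::write_csv(summarize_runs(runs), file.path(dir, "summary.csv"))

  details <- attr(runs, "details")
  hist_dir <- file.path(dir, "history")
  roc_dir <- file.path(dir, "roc")
  dir.create(hist_dir, showWarnings = FALSE)
  dir.create(roc_dir, showWarnings = FALSE)
  for (i in seq_along(details)) {
    readr::write_csv(details[[i]]$history,
                     file.path(hist_dir, sprintf("run_%02d.csv", i)))
    readr::write_csv(as_tibble(details[[i]]$roc),
                     file.path(roc_dir, sprintf("run_%02d.csv", i)))
    if (plots) {
      tryCatch({
        ggplot2::ggsave(
          file.path(roc_dir, sprintf("run_%02d.png", i)),
          ggplot2::autoplot(details[[i]]$roc),
          width = 5, height = 5, dpi = 120)
      }, error = function(e) {
        warn(paste0("Could not write ROC plot: ", conditionMessage(e)))
      })
    }
  }
  pipeline_log(dir, "crossval", config, proc.time()[["elapsed"]] - t0)
  invisible(runs)
}

#' Render the cross-validation summary table
#'
#' Prints sensitivity and specificity order statistics in the published
#' column order (N, Min, Max, Mean, Median, Std, 25th Perc, 75th Perc).
#'
#' @param path Either a `runs.csv` written by [pipeline_crossval()] or the
#'   directory containing it.
#' @return The summary tibble, invisibly.
#' @export
pipeline_report <- function(path) {
  file <- if (dir.exists(path)) file.path(path, "runs.csv") else path
  if (!file.exists(file)) {
    abort(paste0("Results file not found: ", file),
          class = "fluordx_io_error")
  }
  runs <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  if (nrow(runs) == 0) {
    abort("Results file holds no runs.", class = "fluordx_value_error")
  }
  summary <- summarize_runs(runs)
  display <- summary |>
    mutate(metric = tools::toTitleCase(.data$metric)) |>
    dplyr::rename(` ` = "metric", N = "n", Min = "min", Max = "max",
                  Mean = "mean", Median = "median", Std = "sd",
                  `25th Perc` = "p25", `75th Perc` = "p75") |>
    mutate(across(-1, ~ round(.x, 2)))
  cat("Sensitivity and specificity statistics (case-level, validation sets)\n")
  print.data.frame(as.data.frame(display), row.names = FALSE)
  invisible(summary)
}
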