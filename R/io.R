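#' Validate a table against a column schema
#'
#' @param df data frame.
#' @param schema named character vector mapping required column names to
#'   base types (`"numeric"`, `"integer"`, `"character"`, `"logical"`);
#'   factors satisfy `"character"`.
#' @param name label used in error messages.
#' @return The (invisible) validated tibble.
#' @export
validate_table <- function(df, schema, name = "table") {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    abort(paste0(
      name, " is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in names(schema)) {
    v <- df[[col]]
    ok <- switch(schema[[col]],
      numeric = is.numeric(v),
      integer = is.numeric(v) && all(v == round(v), na.rm = TRUE),
      character = is.character(v) || is.factor(v),
      logical = is.logical(v) || all(v %in% c(0, 1, NA)),
      abort(paste0("Unknown schema type for ", col))
    )
    if (!ok) {
      abort(paste0(
        name, " column `", col, "` is not of type ", schema[[col]], "."
      ))
    }
  }
  invisible(as_tibble(df))
}

schema_pupil_samples <- c(
  time_ms = "numeric", pupil = "numeric",
  blink = "logical", saccade = "logical"
)
schema_keywords <- c(
  list_id = "integer", snr = "numeric",
  keyword = "integer", correct = "logical"
)

#' Read a pupil sample table from CSV
#'
#' Expects columns `time_ms`, `pupil`, `blink`, `saccade` (0/1 or logical).
#'
#' @param path CSV path.
#' @return Validated tibble with logical artifact flags.
#' @export
read_pupil_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- validate_table(df, schema_pupil_samples, "pupil sample table")
  df$blink <- as.logical(df$blink)
  df$saccade <- as.logical(df$saccade)
  df
}

#' Read a QuickSIN keyword table from CSV
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_keyword_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_table(df, schema_keywords, "keyword table")
}

#' Write / read a stimulus-event sidecar (JSON)
#'
#' The sidecar stores per-epoch onsets (1-based sample indices) and
#' polarities for a continuous recording.
#'
#' @param events tibble with `onset`, `polarity` (`"+"`/`"-"`).
#' @param path JSON path.
#' @param n_samples recording length used for bounds checking on read.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(events, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, n_samples = Inf) {
  events <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_table(
    events, c(onset = "integer", polarity = "character"), "event sidecar"
  )
  bad <- which(events$onset < 1 | events$onset > n_samples)
  if (length(bad)) {
    abort(paste0(
      "Event sidecar has out-of-range onset at index ",
      paste(head(bad, 5), collapse = ", "), "."
    ))
  }
  if (is.unsorted(events$onset, strictly = TRUE)) {
    abort("Event onsets must be strictly increasing.")
  }
  events$onset <- as.integer(events$onset)
  events
}

#' Write the tables of a pipeline run to a directory
#'
#' Emits CSV tables (cohort covariates, ground-truth ledger, EFR results,
#' slope table, keyword proportions, ANOVA, correlation, elastic-net
#' coefficients) plus a JSON manifest carrying the seed and a hash of the
#' configuration, so a run can be reproduced from its artifacts.
#'
#' @param run an `"earpipe_run"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_run_tables <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, nm) {
    readr::write_csv(df, file.path(dir, paste0(nm, ".csv")))
  }
  latent <- grepl("^\\.latent_", names(run$cohort))
  w(run$cohort[, !latent], "cohort")
  w(run$cohort[, c(1, which(latent))], "ground_truth")
  if (!is.null(run$efr)) w(run$efr, "efr_results")
  if (!is.null(run$slopes)) w(run$slopes, "pupil_slopes")
  if (!is.null(run$behavior)) {
    w(run$behavior$proportions, "quicksin_proportions")
    w(run$behavior$snr_loss$per_list, "quicksin_snr_loss")
  }
  if (!is.null(run$anova)) w(run$anova, "efr_anova")
  if (!is.null(run$followup)) w(run$followup, "efr_followup")
  if (!is.null(run$correlation)) w(run$correlation, "efr_behavior_correlation")
  if (!is.null(run$elastic_net)) {
    w(tidy(run$elastic_net), "elastic_net_coefficients")
    w(
      tibble(
        observed = run$elastic_net$y,
        predicted = run$elastic_net$fitted
      ),
      "elastic_net_predicted"
    )
  }
  manifest <- list(
    seed = run$seed,
    config_hash = rlang::hash(run$config),
    resolved_config = lapply(unclass(run$config), function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    }),
    created = format(Sys.time(), tz = "UTC"),
    tables = list.files(dir, pattern = "\\.csv$")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
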