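#' Synthesize a QuickSIN keyword-correctness table
#'
#' Four test lists of six sentences (one per SNR: 25, 20, 15, 10, 5, 0 dB),
#' five keywords each. Every keyword is an independent Bernoulli draw with
#' success probability given by the participant's logistic psychometric
#' function `plogis(slope * (snr - midpoint))`, where the latent midpoint
#' carries the participant's group base, threshold, survival and effort
#' contributions (see [simulate_cohort()]).
#'
#' @param participant one row of [simulate_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @param lists test-list identifiers.
#' @return Tibble: `id`, `list_id`, `snr`, `keyword` (1-5), `correct` (0/1).
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = c(YA = 2, MA = 2))
#' p <- simulate_cohort(cfg)[1, ]
#' kw <- synthesize_quicksin(p, cfg, seed = 1)
#' score_proportions(kw)
synthesize_quicksin <- function(participant, config, seed = config$seed,
                                lists = 1:4) {
  if (!all(is.finite(c(
    participant$.latent_midpoint, config$psychometric_slope
  )))) {
    abort("Psychometric parameters must be finite.")
  }
  set.seed(seed)
  snrs <- as.numeric(names(config$effort_slope_listening))
  grid <- tidyr::expand_grid(list_id = lists, snr = snrs, keyword = 1:5)
  pc <- stats::plogis(
    config$psychometric_slope * (grid$snr - participant$.latent_midpoint)
  )
  tibble(
    id = participant$id,
    list_id = grid$list_id,
    snr = grid$snr,
    keyword = grid$keyword,
    correct = as.integer(runif(nrow(grid)) < pc)
  )
}

#' Per-SNR proportion of keywords identified
#'
#' Pools the four test lists: 20 keywords per SNR (4 lists x 5 keywords).
#'
#' @param keyword_table tibble with `snr`, `list_id`, `keyword`, `correct`
#'   (0/1), optionally `id`.
#' @return Tibble: (`id`,) `snr`, `n_keywords`, `proportion_correct`.
#' @export
score_proportions <- function(keyword_table) {
  check_keyword_table(keyword_table)
  keys <- intersect("id", names(keyword_table))
  keyword_table %>%
    group_by(across(dplyr::all_of(c(keys, "snr")))) %>%
    summarise(
      n_keywords = dplyr::n(),
      proportion_correct = mean(.data$correct),
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$snr), .by_group = FALSE)
}

#' Clinical dB SNR loss per test list
#'
#' Each list has 30 keywords (6 sentences x 5); the list's SNR loss is
#' `25.5 - (keywords correct in the list)`, and the participant score is
#' the mean over the four lists. A perfect list scores -4.5 dB, an empty
#' one 25.5 dB.
#'
#' @inheritParams score_proportions
#' @return List with `per_list` (tibble: (`id`,) `list_id`, `n_correct`,
#'   `snr_loss`) and `mean_snr_loss` (tibble keyed by `id` when present).
#' @export
snr_loss <- function(keyword_table) {
  check_keyword_table(keyword_table)
  keys <- intersect("id", names(keyword_table))
  per_list <- keyword_table %>%
    group_by(across(dplyr::all_of(c(keys, "list_id")))) %>%
    summarise(
      n_keywords = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    )
  if (any(per_list$n_keywords != 30)) {
    abort("Each test list must contain exactly 30 keyword outcomes.")
  }
  per_list <- per_list %>%
    mutate(snr_loss = 25.5 - .data$n_correct) %>%
    select(-"n_keywords")
  mean_loss <- per_list %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise(mean_snr_loss = mean(.data$snr_loss), .groups = "drop")
  list(per_list = per_list, mean_snr_loss = mean_loss)
}

check_keyword_table <- function(keyword_table) {
  need <- c("snr", "list_id", "keyword", "correct")
  missing_cols <- setdiff(need, names(keyword_table))
  if (length(missing_cols)) {
    abort(paste0(
      "Keyword table is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!all(keyword_table$correct %in% c(0, 1))) {
    abort("`correct` must be 0/1.")
  }
  counts <- keyword_table %>%
    group_by(across(dplyr::any_of(c("id", "list_id", "snr")))) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (length(unique(counts$n)) > 1) {
    abort("Malformed keyword table: unequal cell sizes across list x SNR.")
  }
  invisible(keyword_table)
}
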