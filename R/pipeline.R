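#' Run the full synthetic-cohort analysis chain
#'
#' Simulates a cohort, synthesizes and analyzes EFR recordings at every AM
#' rate, generates and preprocesses pupillometry trials for both analysis
#' windows, scores QuickSIN keyword tables, and runs the association stage:
#' mixed ANOVA of EFR amplitude (group x AM rate) with per-rate
#' Bonferroni-corrected follow-ups, the outlier-screened Pearson
#' correlation between 1024 Hz EFR amplitude and 0 dB keyword accuracy, and
#' the elastic net predicting 0 dB accuracy (scaled 0-100) from PTA4k, EFR
#' amplitude, per-SNR pupillary slopes and any decoy covariates.
#'
#' All randomness derives from `seed`. `n_epochs` below the configured
#' study value triggers variance-preserving downscaling: per-sample noise
#' is multiplied by `sqrt(n_epochs / config$n_epochs)` so the averaged
#' waveform has the noise level of the full-size study condition.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param n_epochs EFR sweeps per recording actually synthesized.
#' @param slopes_method `"ols"` (per-cell least squares; fast) or `"blup"`
#'   (growth-curve mixed model conditional modes).
#' @param n_decoys number of pure-noise decoy predictors appended to the
#'   elastic-net design matrix.
#' @param stages character subset of `c("efr", "pupil", "behavior",
#'   "association")`; `"association"` requires the other three.
#' @return List of class `"earpipe_run"` with elements `cohort`, `efr`,
#'   `slopes`, `behavior` (`proportions`, `snr_loss`), `anova`,
#'   `followup`, `correlation`, `elastic_net`, `counts`, `seed`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = config$seed,
                         n_epochs = config$n_epochs,
                         slopes_method = c("ols", "blup"),
                         n_decoys = 0,
                         stages = c("efr", "pupil", "behavior", "association")) {
  slopes_method <- match.arg(slopes_method)
  stages <- match.arg(stages, several.ok = TRUE)
  if ("association" %in% stages &&
    !all(c("efr", "pupil", "behavior") %in% stages)) {
    abort("The association stage needs the efr, pupil and behavior stages.")
  }
  cohort <- simulate_cohort(config, seed = seed)
  out <- list(cohort = cohort, seed = seed, config = config)
  counts <- list()

  if ("efr" %in% stages) {
    noise_scale <- sqrt(n_epochs / config$n_epochs)
    rates <- c(40, 110, 512, 1024)
    efr <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      purrr::map_dfr(rates, function(r) {
        rec <- synthesize_efr_recording(
          cohort[i, ], r, config,
          mode = "human",
          seed = (seed + 104729L * i + 7L * r) %% .Machine$integer.max,
          noise_scale = noise_scale, n_epochs = n_epochs
        )
        res <- analyze_efr(rec)
        res$id <- cohort$id[i]
        res[, c("id", setdiff(names(res), "id"))]
      })
    })
    out$efr <- left_join(efr, select(cohort, "id", "group"), by = "id")
    counts$efr_recordings <- nrow(efr)
  }

  if ("pupil" %in% stages) {
    snrs <- as.numeric(names(config$effort_slope_listening))
    n_rejected <- 0L
    windows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      rows <- purrr::map_dfr(snrs, function(snr) {
        purrr::map_dfr(1:4, function(list_id) {
          trial_seed <- (seed + 7919L * i + 131L * as.integer(snr) +
            17L * list_id) %% .Machine$integer.max
          tr <- synthesize_pupil_trial(
            cohort[i, ], snr, list_id, config,
            seed = trial_seed
          )
          w <- process_pupil_windows(tr)
          if (is.null(w)) {
            n_rejected <<- n_rejected + 1L
            return(NULL)
          }
          w$snr <- snr
          w$list_id <- list_id
          w
        })
      })
      if (nrow(rows) == 0) {
        return(NULL)
      }
      rows$id <- cohort$id[i]
      rows
    })
    windows <- left_join(windows, select(cohort, "id", "group"), by = "id")
    avg <- average_by_condition(windows)
    counts$pupil_trials_rejected <- n_rejected

    if (slopes_method == "ols") {
      out$slopes <- purrr::map_dfr(
        c("listening", "integration"),
        function(w) {
          mutate(
            extract_slopes(filter(avg, .data$window == w), method = "ols"),
            window = w, .before = 1
          )
        }
      )
    } else {
      out$gca <- purrr::map(
        setNames(c("listening", "integration"), c("listening", "integration")),
        function(w) fit_gca(filter(avg, .data$window == w), window = w)
      )
      out$slopes <- purrr::map_dfr(
        c("listening", "integration"),
        function(w) mutate(extract_slopes(out$gca[[w]]), window = w, .before = 1)
      )
    }
    out$pupil_means <- avg %>%
      group_by(.data$group, .data$snr, .data$window, .data$t_rel_s) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  }

  if ("behavior" %in% stages) {
    kw <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      synthesize_quicksin(
        cohort[i, ], config,
        seed = (seed + 65537L * i) %% .Machine$integer.max
      )
    })
    out$behavior <- list(
      proportions = score_proportions(kw),
      snr_loss = snr_loss(kw)
    )
  }

  if ("association" %in% stages) {
    out$anova <- mixed_anova(
      out$efr,
      dv = "amplitude", id = "id",
      between = "group", within = "am_rate_hz"
    )
    out$followup <- followup_by_level(
      out$efr,
      dv = "amplitude", between = "group", within = "am_rate_hz"
    )

    acc0 <- out$behavior$proportions %>% filter(.data$snr == 0)
    efr1024 <- out$efr %>% filter(.data$am_rate_hz == 1024)
    paired <- left_join(
      select(efr1024, "id", "amplitude"),
      select(acc0, "id", "proportion_correct"),
      by = "id"
    )
    out$correlation <- pearson_cor(
      paired$amplitude, paired$proportion_correct
    )

    pm <- build_predictor_matrix(
      cohort, out$efr, out$slopes, out$behavior$proportions,
      covariates = c("pta4k", "ehf_mean")
    )
    if (n_decoys > 0) {
      set.seed((seed + 999983L) %% .Machine$integer.max)
      decoys <- matrix(
        rnorm(nrow(pm$x) * n_decoys),
        ncol = n_decoys,
        dimnames = list(NULL, sprintf("decoy_%02d", seq_len(n_decoys)))
      )
      pm$x <- cbind(pm$x, decoys)
    }
    out$elastic_net <- elastic_net_cv(
      pm$x, pm$y,
      n_folds = min(pipeline_defaults()$n_folds, length(pm$y) - 1L),
      seed = (seed + 524287L) %% .Machine$integer.max
    )
    out$predictors <- pm
    counts$subjects_dropped <- pm$n_dropped
  }

  out$counts <- counts
  class(out) <- "earpipe_run"
  out
}

#' @export
print.earpipe_run <- function(x, ...) {
  cat("<earpipe_run> seed", x$seed, "\n")
  cat("  cohort:", nrow(x$cohort), "participants\n")
  if (!is.null(x$efr)) {
    cat("  efr:", nrow(x$efr), "recordings analyzed\n")
  }
  if (!is.null(x$slopes)) {
    cat("  pupil slopes:", nrow(x$slopes), "cells\n")
  }
  if (!is.null(x$elastic_net)) {
    cat(
      "  elastic net: alpha", x$elastic_net$alpha,
      "selected", paste(x$elastic_net$selected_predictors, collapse = ", "), "\n"
    )
  }
  invisible(x)
}
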