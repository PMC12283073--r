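#' Synthesize a pupillometry trial
#'
#' Builds a 1000 Hz pupil trace for one sentence trial following the task
#' timeline: fixation, 100 ms alert beep, 2 s gap, babble masker onset, 3 s
#' masker lead, target sentence, 2 s masker tail, 2 s gap, response prompt.
#' The evoked response is a linear-plus-quadratic percent-change trend in
#' each analysis window - the same basis the growth-curve model fits, so
#' recovery is exact in expectation. The listening-window trend starts at
#' masker onset with the participant's latent effort slope for that SNR; the
#' integration-window trend starts at target offset, expressed relative to
#' the trace's own 1 s pre-offset mean so that downstream trial-wise
#' baseline normalization recovers the programmed slope. Blinks are
#' Poisson-placed dropout segments (pupil = 0, flagged); saccades are short
#' flagged events with the pupil unchanged; measurement noise is additive
#' AR(1).
#'
#' @param participant one row of [simulate_cohort()].
#' @param snr trial SNR in dB, one of 25, 20, 15, 10, 5, 0.
#' @param list_id test-list identifier (1-4).
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @param noise_scale multiplier on AR(1) noise, blink rate and saccade rate
#'   (0 gives a deterministic trace).
#' @return List of class `"pupil_trial"`: `samples` tibble (`time_ms`,
#'   `pupil`, `blink`, `saccade`), `events` (named ms vector), `id`, `snr`,
#'   `list_id`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = c(YA = 2, MA = 2))
#' p <- simulate_cohort(cfg)[1, ]
#' trial <- synthesize_pupil_trial(p, snr = 10, list_id = 1, cfg, seed = 1)
#' head(trial$samples)
synthesize_pupil_trial <- function(participant, snr, list_id, config,
                                   seed = config$seed, noise_scale = 1) {
  snr_key <- as.character(snr)
  if (!snr_key %in% names(config$effort_slope_listening)) {
    abort(paste0("Unknown SNR ", snr, " dB."))
  }
  set.seed(seed)
  tl <- pupil_timeline()
  n <- tl[["trace_end_ms"]]
  t_ms <- 0:(n - 1)
  b0 <- config$pupil_baseline_au

  s_listen <- participant[[paste0(".latent_slope_listening_", snr_key)]]
  s_integ <- participant[[paste0(".latent_slope_integration_", snr_key)]]
  q <- config$effort_quad_coef

  # quadratic component centred on the window (orthogonal to the linear
  # term over the window), so the window's least-squares slope is exactly
  # the programmed slope and g(0) = 0
  quad <- function(tau, span) q * ((tau - span / 2)^2 - (span / 2)^2)

  listen_on <- tl[["masker_onset_ms"]]
  span_l <- 5.8
  tau_l <- pmin(pmax((t_ms - listen_on) / 1000, 0), span_l)
  g <- s_listen * tau_l + quad(tau_l, span_l)
  pupil <- b0 * (1 + g / 100)

  # integration trend, anchored to the trace's own 1 s pre-offset mean so
  # that trial-wise baseline normalization recovers s_integ exactly
  off <- tl[["target_offset_ms"]]
  b_int <- mean(pupil[t_ms >= off - 1000 & t_ms < off])
  span_i <- 3.0
  tau_i <- pmin(pmax((t_ms - off) / 1000, 0), span_i)
  post <- t_ms >= off
  pupil[post] <- b_int *
    (1 + (s_integ * tau_i[post] + quad(tau_i[post], span_i)) / 100)

  if (noise_scale > 0 && config$pupil_noise_sd > 0) {
    phi <- config$pupil_noise_ar
    innov_sd <- config$pupil_noise_sd * noise_scale * sqrt(1 - phi^2) / 100 * b0
    noise <- as.numeric(
      stats::filter(rnorm(n, 0, innov_sd), phi, method = "recursive")
    )
    pupil <- pupil + noise
  }

  blink <- logical(n)
  saccade <- logical(n)
  if (noise_scale > 0) {
    blink <- event_mask(
      n, config$blink_rate * noise_scale, config$blink_dur_ms
    )
    saccade <- event_mask(
      n, config$saccade_rate * noise_scale, config$saccade_dur_ms
    )
  }
  pupil[blink] <- 0

  structure(
    list(
      samples = tibble(
        time_ms = t_ms, pupil = pupil, blink = blink, saccade = saccade
      ),
      events = tl,
      id = participant$id,
      snr = snr,
      list_id = list_id
    ),
    class = "pupil_trial"
  )
}

event_mask <- function(n, rate_hz, dur_range_ms) {
  mask <- logical(n)
  k <- rpois(1, rate_hz * n / 1000)
  if (k == 0) {
    return(mask)
  }
  onsets <- sort(sample.int(n, k, replace = TRUE))
  durs <- round(runif(k, dur_range_ms[1], dur_range_ms[2]))
  for (i in seq_len(k)) {
    span <- onsets[i]:min(n, onsets[i] + durs[i] - 1)
    mask[span] <- TRUE
  }
  mask
}

#' Synthesize all pupillometry trials for a cohort
#'
#' One trial per participant x SNR x test list. Trials are generated with
#' per-trial seeds derived from `seed`, so the set is reproducible and any
#' single trial can be regenerated.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a [cohort_config()].
#' @param lists test-list identifiers.
#' @param seed integer base seed.
#' @param noise_scale passed to [synthesize_pupil_trial()].
#' @return List of `"pupil_trial"` objects.
#' @export
synthesize_pupil_session <- function(cohort, config, lists = 1:4,
                                     seed = config$seed, noise_scale = 1) {
  snrs <- as.numeric(names(config$effort_slope_listening))
  grid <- tidyr::expand_grid(
    row = seq_len(nrow(cohort)), snr = snrs, list_id = lists
  )
  purrr::pmap(grid, function(row, snr, list_id) {
    trial_seed <- (seed + 7919L * row + 131L * as.integer(snr) +
      17L * as.integer(list_id)) %% .Machine$integer.max
    synthesize_pupil_trial(
      cohort[row, ], snr, list_id, config,
      seed = trial_seed, noise_scale = noise_scale
    )
  })
}
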