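#' Synthesize an event-marked EFR recording
#'
#' Builds a continuous single-channel recording emulating envelope following
#' response acquisition: `n_epochs` repetitions of a 250 ms, 3 kHz
#' sinusoidally amplitude-modulated tone response presented at 3.1
#' repetitions/s in alternating polarity. Each epoch embeds (i) an
#' envelope-locked sinusoid at exactly the AM rate whose amplitude is
#' `efr_amp_by_rate[am_rate]`, plus `efr_gain * latent survival` at 1024 Hz
#' only, and (ii) a carrier-locked 3 kHz component whose sign follows the
#' stimulus polarity, so it cancels under cross-polarity averaging. The
#' phase-locked response lags the stimulus by a 10 ms neural latency, which
#' is why spectral analysis windows start 10 ms after stimulus onset.
#' Additive noise is Gaussian with a 1/f-shaped power spectrum up to 3 kHz;
#' movement artifacts are injected as high-amplitude bursts (> 200 uV peak)
#' in a Bernoulli-selected subset of epochs.
#'
#' @param participant one row of [simulate_cohort()] output (or any list
#'   with `.latent_survival`); may be `NULL` for a survival of 1.
#' @param am_rate modulation rate in Hz. Human mode permits 40, 110, 512,
#'   1024; gerbil mode 16, 40, 110, 256, 724, 1024.
#' @param config a [cohort_config()].
#' @param mode `"human"` or `"gerbil"` (selects the admissible rates).
#' @param seed integer RNG seed for the noise and artifact draws.
#' @param noise_scale multiplier on the noise spectrum level (0 gives a
#'   noiseless recording).
#' @param n_epochs number of stimulus presentations; defaults to the
#'   configured study value.
#' @return An object of class `"efr_recording"`: list with `samples` (uV),
#'   `fs`, `events` (tibble of `onset` sample index and `polarity`
#'   `"+"`/`"-"`), and `stimulus` description.
#' @export
#' @examples
#' cfg <- cohort_config(fs_hz = 8192, n_epochs = 20)
#' rec <- synthesize_efr_recording(NULL, 1024, cfg, seed = 1)
#' rec
synthesize_efr_recording <- function(participant, am_rate, config,
                                     mode = c("human", "gerbil"),
                                     seed = config$seed,
                                     noise_scale = 1,
                                     n_epochs = config$n_epochs) {
  mode <- match.arg(mode)
  am_rate <- check_am_rate(am_rate, mode)
  validate_cohort_config(config)
  set.seed(seed)

  fs <- config$fs_hz
  p <- pipeline_defaults()
  epoch_len <- round(fs / p$rep_rate_hz)
  n_total <- n_epochs * epoch_len

  survival <- if (is.null(participant)) 1 else participant$.latent_survival
  amp <- config$efr_amp_by_rate[[as.character(am_rate)]] +
    if (am_rate == 1024) config$efr_gain * survival else 0

  latency <- round(0.010 * fs)
  resp_len <- round(p$stim_duration_s * fs)
  t_resp <- seq_len(resp_len) / fs
  env_comp <- amp * sin(2 * pi * am_rate * t_resp)
  car_comp <- config$carrier_amp_uv * sin(2 * pi * 3000 * t_resp)

  polarity <- rep_len(c(1, -1), n_epochs)
  epochs <- matrix(0, nrow = epoch_len, ncol = n_epochs)
  rows <- latency + seq_len(resp_len)
  epochs[rows, ] <- env_comp + outer(car_comp, polarity)

  samples <- as.vector(epochs)
  if (noise_scale > 0 && config$noise_spectrum_level > 0) {
    samples <- samples + shaped_noise(
      n_total, fs,
      level = config$noise_spectrum_level * noise_scale
    )
  }

  onsets <- (seq_len(n_epochs) - 1L) * epoch_len + 1L
  if (config$artifact_rate > 0) {
    hit <- runif(n_epochs) < config$artifact_rate
    for (e in which(hit)) {
      burst_len <- round(0.05 * fs)
      start <- onsets[e] + sample.int(epoch_len - burst_len, 1L)
      peak <- runif(1, 260, 400) * sample(c(-1, 1), 1)
      burst <- peak * sin(pi * seq_len(burst_len) / burst_len)^2
      samples[start:(start + burst_len - 1L)] <-
        samples[start:(start + burst_len - 1L)] + burst
    }
  }

  structure(
    list(
      samples = samples,
      fs = fs,
      events = tibble(
        onset = onsets,
        polarity = ifelse(polarity > 0, "+", "-")
      ),
      stimulus = list(
        carrier_hz = 3000, am_rate_hz = am_rate,
        duration_s = p$stim_duration_s, rise_fall_s = 0.005,
        rep_rate_hz = p$rep_rate_hz, mode = mode
      )
    ),
    class = "efr_recording"
  )
}

check_am_rate <- function(am_rate, mode) {
  allowed <- if (mode == "human") {
    c(40, 110, 512, 1024)
  } else {
    c(16, 40, 110, 256, 724, 1024)
  }
  if (!am_rate %in% allowed) {
    abort(paste0(
      "AM rate ", am_rate, " Hz is not a ", mode, "-mode rate (",
      paste(allowed, collapse = ", "), ")."
    ))
  }
  am_rate
}

# Gaussian noise with one-sided PSD level^2 * (1024 / f) uV^2/Hz (floored at
# 1 Hz), rolled off with a 4th-power factor above 3 kHz. `level` is the
# amplitude spectral density at 1024 Hz in uV/sqrt(Hz).
shaped_noise <- function(n, fs, level) {
  n_fft <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(n_fft)
  freq <- c(
    seq(0, floor(n_fft / 2)),
    seq(-(ceiling(n_fft / 2) - 1), -1)
  ) * fs / n_fft
  af <- pmax(abs(freq), 1)
  s <- level^2 * 1024 / af
  s <- s * ifelse(af > 3000, (3000 / af)^4, 1)
  s[1] <- 0
  gain <- sqrt(s * fs / 2)
  shaped <- Re(fft(fft(w) * gain, inverse = TRUE)) / n_fft
  shaped[seq_len(n)]
}

#' @export
print.efr_recording <- function(x, ...) {
  cat(
    "<efr_recording>", length(x$samples), "samples at", x$fs, "Hz;",
    nrow(x$events), "epochs;", x$stimulus$am_rate_hz, "Hz AM (",
    x$stimulus$mode, "mode )\n"
  )
  invisible(x)
}
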