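#' Window-of-interest bounds for a pupil trial
#'
#' The listening window runs from babble-masker onset through 5.8 s; the
#' integration window from target-sentence offset through 3.0 s.
#'
#' @param events named ms vector with `masker_onset_ms` and
#'   `target_offset_ms`.
#' @param window `"listening"` or `"integration"`.
#' @param defaults parameter list from [pipeline_defaults()].
#' @return Named numeric: `start_ms`, `end_ms`.
#' @export
pupil_window_bounds <- function(window = c("listening", "integration"),
                                events, defaults = pipeline_defaults()) {
  window <- match.arg(window)
  start <- if (window == "listening") {
    events[["masker_onset_ms"]]
  } else {
    events[["target_offset_ms"]]
  }
  span <- defaults$window_span_s[[window]] * 1000
  c(start_ms = start, end_ms = start + span)
}

#' Should a trial be discarded for artifact coverage?
#'
#' A trial is removed when more than 15% of the samples in the window of
#' interest are flagged as blinks or saccades (exactly 15% is kept: the
#' rule is "more than").
#'
#' @param trial a `"pupil_trial"` or its `samples` tibble.
#' @param window `"listening"` or `"integration"`.
#' @param events event vector (taken from the trial if omitted).
#' @param defaults parameter list from [pipeline_defaults()].
#' @return `TRUE` if the trial should be rejected.
#' @export
reject_trial <- function(trial, window = "listening", events = NULL,
                         defaults = pipeline_defaults()) {
  samples <- if (inherits(trial, "pupil_trial")) trial$samples else trial
  events <- events %||% trial$events
  if (nrow(samples) == 0) abort("Empty pupil trace.")
  b <- pupil_window_bounds(window, events, defaults)
  inside <- samples$time_ms >= b[["start_ms"]] & samples$time_ms < b[["end_ms"]]
  if (!any(inside)) abort("Window of interest contains no samples.")
  frac <- mean(samples$blink[inside] | samples$saccade[inside])
  frac > defaults$artifact_max_frac
}

#' Linearly interpolate blink and saccade artifacts
#'
#' Each contiguous blink run is replaced, together with a pad from 60 ms
#' before to 160 ms after it, by the straight line joining the pad's
#' boundary samples; saccade runs use a 60 ms pad on both sides.
#' Overlapping pads merge into a single interpolated span. Samples outside
#' the dilated spans are returned unchanged. An artifact whose pad touches
#' the start or end of the trace has no interpolation anchor and raises an
#' error (callers treat this as trial rejection).
#'
#' @inheritParams reject_trial
#' @param fs_hz sampling rate of the trace.
#' @return The trial (or samples tibble) with interpolated pupil values;
#'   the artifact flags are left as recorded.
#' @export
interpolate_artifacts <- function(trial, defaults = pipeline_defaults(),
                                  fs_hz = defaults$pupil_fs_hz) {
  is_trial <- inherits(trial, "pupil_trial")
  samples <- if (is_trial) trial$samples else trial
  ms_per_sample <- 1000 / fs_hz
  dil <- dilate_mask(samples$blink, defaults$blink_pad_ms / ms_per_sample) |
    dilate_mask(samples$saccade, defaults$saccade_pad_ms / ms_per_sample)
  if (any(dil)) {
    if (dil[1] || dil[length(dil)]) {
      abort("Artifact span touches the trace boundary; no interpolation anchor.")
    }
    keep <- which(!dil)
    samples$pupil[dil] <- approx(
      x = keep, y = samples$pupil[keep], xout = which(dil)
    )$y
  }
  if (is_trial) {
    trial$samples <- samples
    trial
  } else {
    samples
  }
}

# Dilate TRUE runs of a logical mask by (before, after) samples.
dilate_mask <- function(mask, pad) {
  if (!any(mask)) {
    return(mask)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- logical(length(mask))
  for (i in which(r$values)) {
    span <- max(1, starts[i] - round(pad[1])):min(length(mask), ends[i] + round(pad[2]))
    out[span] <- TRUE
  }
  out
}

#' Downsample a 1000 Hz pupil trace to 50 Hz by block averaging
#'
#' Non-overlapping 20-sample blocks are averaged; timestamps are the mean
#' sample time of each block. Block averaging acts as the anti-alias step
#' (a trailing partial block is dropped).
#'
#' @inheritParams interpolate_artifacts
#' @param target_hz output rate.
#' @return The trial (or samples tibble) at 50 Hz; artifact flags become the
#'   block means of the 0/1 flags (fraction of flagged samples per block).
#' @export
downsample_50hz <- function(trial, defaults = pipeline_defaults(),
                            fs_hz = defaults$pupil_fs_hz,
                            target_hz = defaults$downsample_hz) {
  is_trial <- inherits(trial, "pupil_trial")
  samples <- if (is_trial) trial$samples else trial
  block <- fs_hz / target_hz
  if (block != round(block)) {
    abort("Input rate must be an integer multiple of the target rate.")
  }
  n_block <- floor(nrow(samples) / block)
  idx <- seq_len(n_block * block)
  block_mean <- function(x) colMeans(matrix(x[idx], nrow = block))
  out <- tibble(
    time_ms = block_mean(samples$time_ms),
    pupil = block_mean(samples$pupil),
    blink = block_mean(samples$blink),
    saccade = block_mean(samples$saccade)
  )
  if (is_trial) {
    trial$samples <- out
    trial$fs_hz <- target_hz
    trial
  } else {
    out
  }
}

#' Baseline-normalize and cut a window of interest
#'
#' The baseline is the mean pupil size over the 1000 ms immediately before
#' the window start (computed on the interpolated, downsampled trace so
#' blink zeros cannot corrupt it); samples in the window are expressed as
#' percent change, `(pupil - baseline) / baseline * 100`.
#'
#' @inheritParams reject_trial
#' @return Tibble: `window`, `t_rel_s` (s from window start), `value`
#'   (percent change), `baseline` (a.u.).
#' @export
baseline_normalize <- function(trial, window = c("listening", "integration"),
                               events = NULL,
                               defaults = pipeline_defaults()) {
  window <- match.arg(window)
  samples <- if (inherits(trial, "pupil_trial")) trial$samples else trial
  events <- events %||% trial$events
  b <- pupil_window_bounds(window, events, defaults)
  pre <- samples$time_ms >= b[["start_ms"]] - defaults$baseline_ms &
    samples$time_ms < b[["start_ms"]]
  dt <- diff(samples$time_ms[1:2])
  if (sum(pre) < floor(defaults$baseline_ms / dt)) {
    abort("Less than 1000 ms of data before the window of interest.")
  }
  baseline <- mean(samples$pupil[pre])
  if (!is.finite(baseline) || baseline <= 0) {
    abort("Baseline pupil size must be positive.")
  }
  inside <- samples$time_ms >= b[["start_ms"]] & samples$time_ms < b[["end_ms"]]
  tibble(
    window = window,
    t_rel_s = (samples$time_ms[inside] - b[["start_ms"]]) / 1000,
    value = (samples$pupil[inside] - baseline) / baseline * 100,
    baseline = baseline
  )
}

#' Preprocess one pupil trial end to end
#'
#' Fixed order: artifact-coverage rejection, linear interpolation of blinks
#' and saccades, 50 Hz downsampling, trial-wise baseline normalization, and
#' window cutting. Returns `NULL` when the trial is rejected (more than 15%
#' artifact coverage in the window, or an artifact span touching the trace
#' boundary).
#'
#' @inheritParams reject_trial
#' @return A window tibble as from [baseline_normalize()], or `NULL`.
#' @export
process_pupil_trial <- function(trial, window = c("listening", "integration"),
                                defaults = pipeline_defaults()) {
  window <- match.arg(window)
  if (reject_trial(trial, window, defaults = defaults)) {
    return(NULL)
  }
  interp <- tryCatch(
    interpolate_artifacts(trial, defaults),
    rlang_error = function(e) NULL
  )
  if (is.null(interp)) {
    return(NULL)
  }
  down <- downsample_50hz(interp, defaults)
  baseline_normalize(down, window, defaults = defaults)
}

#' Preprocess one trial for several windows in a single pass
#'
#' Shares the interpolation and downsampling work between the listening and
#' integration windows (the per-window artifact-coverage decision is still
#' taken on the raw flags of each window separately).
#'
#' @inheritParams reject_trial
#' @param windows character vector of windows of interest.
#' @return Bound tibble of per-window results (possibly empty if all
#'   windows are rejected).
#' @export
process_pupil_windows <- function(trial,
                                  windows = c("listening", "integration"),
                                  defaults = pipeline_defaults()) {
  keep <- windows[!vapply(
    windows, function(w) reject_trial(trial, w, defaults = defaults),
    logical(1)
  )]
  if (length(keep) == 0) {
    return(NULL)
  }
  interp <- tryCatch(
    interpolate_artifacts(trial, defaults),
    rlang_error = function(e) NULL
  )
  if (is.null(interp)) {
    return(NULL)
  }
  down <- downsample_50hz(interp, defaults)
  bind_rows(lapply(keep, function(w) {
    baseline_normalize(down, w, defaults = defaults)
  }))
}

#' Preprocess a set of pupil trials into a long window table
#'
#' @param trials list of `"pupil_trial"` objects (e.g. from
#'   [synthesize_pupil_session()]).
#' @param cohort cohort table used to attach the group label.
#' @param window `"listening"` or `"integration"`.
#' @param defaults parameter list from [pipeline_defaults()].
#' @return Long tibble: `id`, `group`, `snr`, `list_id`, `window`,
#'   `t_rel_s`, `value`, with attribute `n_rejected`.
#' @export
preprocess_pupil <- function(trials, cohort,
                             window = c("listening", "integration"),
                             defaults = pipeline_defaults()) {
  window <- match.arg(window)
  res <- purrr::map(trials, function(tr) {
    w <- process_pupil_trial(tr, window, defaults)
    if (is.null(w)) {
      return(NULL)
    }
    w$id <- tr$id
    w$snr <- tr$snr
    w$list_id <- tr$list_id
    w
  })
  n_rejected <- sum(vapply(res, is.null, logical(1)))
  out <- bind_rows(res)
  if (nrow(out) > 0) {
    out <- out %>%
      left_join(select(cohort, "id", "group"), by = "id") %>%
      select(
        "id", "group", "snr", "list_id", "window", "t_rel_s", "value"
      )
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Average preprocessed windows across test lists
#'
#' Pointwise mean of the surviving trials for each participant x SNR x
#' window cell; per-cell trial counts are attached so empty cells can be
#' audited (cells with no surviving trial are simply absent and are treated
#' as missing downstream).
#'
#' @param windows long tibble from [preprocess_pupil()].
#' @return Tibble: `id`, `group`, `snr`, `window`, `t_rel_s`, `value`,
#'   `n_trials`.
#' @export
average_by_condition <- function(windows) {
  windows %>%
    group_by(.data$id, .data$group, .data$snr, .data$window, .data$t_rel_s) %>%
    summarise(
      value = mean(.data$value),
      n_trials = dplyr::n_distinct(.data$list_id),
      .groups = "drop"
    )
}

#' Flag blinks and saccades in an unflagged pupil trace
#'
#' Convenience detector for raw exports that lack eye-tracker flags (an
#' extension; recorded flags are always preferred). Blinks are runs of
#' non-positive pupil samples; saccades are runs where the absolute sample
#' to sample change of pupil size exceeds `vel_threshold` units.
#'
#' @param samples tibble with `time_ms`, `pupil`.
#' @param vel_threshold a.u. change per sample treated as saccadic.
#' @return The tibble with logical `blink` and `saccade` columns added.
#' @export
flag_artifacts <- function(samples, vel_threshold = 30) {
  samples$blink <- samples$pupil <= 0
  vel <- c(0, abs(diff(samples$pupil)))
  samples$saccade <- vel > vel_threshold & !samples$blink
  samples
}
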