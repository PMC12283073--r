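#' Analysis-stage default parameters
#'
#' Returns the fixed preprocessing and statistical constants used throughout
#' the pipeline. Every value is the protocol value the pipeline implements:
#' Butterworth band edges per AM rate, the 200 uV epoch
#' rejection threshold, the 6 dB spectral significance criterion, the pupil
#' artifact thresholds and interpolation pads, analysis window spans, the
#' Tukey fence multiplier and the cross-validation fold count.
#'
#' @return A named list of defaults. Components:
#' \describe{
#'   \item{efr_highpass_by_rate}{named numeric, high-pass cutoff (Hz) per AM
#'     rate. The four human rates map 40/110/512/1024 -> 5/80/200/300 Hz;
#'     the additional gerbil rates use the cutoff of the nearest slower
#'     human rate.}
#'   \item{efr_lowpass_hz, filter_order}{low-pass cutoff and Butterworth order.}
#'   \item{reject_uv}{epoch peak-amplitude rejection threshold (uV).}
#'   \item{snr_criterion_db}{spectral SNR needed to call a response present.}
#'   \item{n_peak_bins, n_flank_bins}{bins searched for the peak / averaged
#'     per flank for the noise floor.}
#'   \item{gerbil_cap_per_polarity}{artifact-free sweeps averaged per
#'     polarity in gerbil mode.}
#'   \item{pupil_fs_hz, downsample_hz}{raw and analysis pupil sampling rates.}
#'   \item{artifact_max_frac}{maximum tolerated artifact coverage of a
#'     window of interest before the trial is discarded.}
#'   \item{blink_pad_ms, saccade_pad_ms}{interpolation pads, (before, after).}
#'   \item{baseline_ms}{pre-window baseline span.}
#'   \item{window_span_s}{named numeric, listening/integration spans (s).}
#'   \item{tukey_k}{fence multiplier for outlier screening.}
#'   \item{n_folds}{cross-validation folds for the elastic net.}
#'   \item{alpha_grid, n_lambda, lambda_decades}{elastic-net tuning grids.}
#' }
#' @export
#' @examples
#' pipeline_defaults()$snr_criterion_db
pipeline_defaults <- function() {
  list(
    efr_highpass_by_rate = c(
      "16" = 5, "40" = 5, "110" = 80, "256" = 80,
      "512" = 200, "724" = 200, "1024" = 300
    ),
    efr_lowpass_hz = 3000,
    filter_order = 4,
    reject_uv = 200,
    rep_rate_hz = 3.1,
    stim_duration_s = 0.25,
    analysis_start_s = 0.010,
    analysis_end_pad_s = c(human = 0.010, gerbil = 0),
    snr_criterion_db = 6,
    n_peak_bins = 3,
    n_flank_bins = 5,
    gerbil_cap_per_polarity = 250,
    pupil_fs_hz = 1000,
    downsample_hz = 50,
    artifact_max_frac = 0.15,
    blink_pad_ms = c(60, 160),
    saccade_pad_ms = c(60, 60),
    baseline_ms = 1000,
    window_span_s = c(listening = 5.8, integration = 3.0),
    tukey_k = 1.5,
    n_folds = 10,
    alpha_grid = seq(0, 1, by = 0.1),
    n_lambda = 100,
    lambda_decades = 4
  )
}

# Trial event timeline (ms from trace start), following the acquisition
# sequence: fixation (>=500 ms), 100 ms alert beep, 2 s gap, masker onset,
# 3 s masker lead, target sentence, 2 s masker tail, 2 s gap, response prompt.
pupil_timeline <- function(target_dur_ms = 3000) {
  fixation <- 0
  beep <- 500
  masker_onset <- beep + 100 + 2000
  target_onset <- masker_onset + 3000
  target_offset <- target_onset + target_dur_ms
  masker_offset <- target_offset + 2000
  prompt <- masker_offset + 2000
  c(
    fixation_ms = fixation, beep_ms = beep, masker_onset_ms = masker_onset,
    target_onset_ms = target_onset, target_offset_ms = target_offset,
    masker_offset_ms = masker_offset, response_prompt_ms = prompt,
    trace_end_ms = prompt + 400
  )
}
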