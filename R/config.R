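#' Cohort generator configuration
#'
#' Builds and validates the configuration that defines a synthetic cohort:
#' group sizes, the latent synapse-survival distribution, EFR signal and
#' noise levels, pupillary effort slopes, blink/saccade statistics, the
#' psychometric function linking SNR to keyword accuracy, and the gerbil
#' synapse-to-EFR link. Defaults define the emulated study: two groups
#' (younger adults, YA; middle-aged, MA) of 35/37 participants, a latent
#' survival deficit in MA, an EFR whose 1024 Hz amplitude scales with
#' survival while slower rates do not, listening effort elevated in MA at
#' moderate SNR, and a psychometric deficit emerging at low SNR.
#'
#' @param n_per_group named integer, participants per group (names must be
#'   the group labels). Default `c(YA = 35, MA = 37)`.
#' @param group_labels character(2), group names; first is the reference
#'   (younger) group.
#' @param synapse_survival_mean named numeric in (0, 1], latent mean synapse
#'   survival per group.
#' @param synapse_survival_sd numeric >= 0, between-subject survival SD
#'   (draws are clipped to (0, 1]).
#' @param efr_gain uV of 1024 Hz EFR amplitude per unit survival.
#' @param efr_amp_by_rate named numeric, survival-independent EFR amplitude
#'   (uV) per AM rate. Rates 16/256/724 Hz are only used in gerbil mode.
#' @param carrier_amp_uv amplitude of the polarity-flipping carrier-locked
#'   component (cancels in cross-polarity averaging).
#' @param noise_spectrum_level uV/sqrt(Hz) amplitude of the recording noise
#'   at 1024 Hz; the noise power spectrum is shaped 1/f up to 3 kHz.
#' @param artifact_rate probability that an epoch is contaminated by a
#'   movement artifact exceeding the 200 uV rejection threshold.
#' @param fs_hz electrophysiology sampling rate (synthesis choice; the
#'   acquisition rate is not part of the analysis contract).
#' @param n_epochs stimulus repetitions per recording (alternating polarity).
#' @param pupil_baseline_au baseline pupil size, arbitrary eye-tracker units.
#' @param effort_slope_listening named-by-SNR numeric, mean listening-window
#'   dilation slope (percent of baseline per s) for the reference group.
#' @param effort_slope_group_delta named-by-SNR numeric, additive slope
#'   elevation for the second group (listening effort recruited by MA at
#'   moderate SNR).
#' @param integration_slope_scale integration-window slopes as a fraction of
#'   the listening-window slopes.
#' @param effort_quad_coef quadratic coefficient (%/s^2) of the evoked
#'   response within each window.
#' @param slope_sd_shared between-subject SD of a subject-level effort trait
#'   added to every condition's slope (%/s).
#' @param slope_sd_specific between-subject SD of the condition-specific
#'   slope deviation (%/s); the 10 dB listening deviation is the latent
#'   effort driver of behavior.
#' @param pupil_noise_sd marginal SD of additive AR(1) measurement noise on
#'   the pupil trace, in percent of baseline.
#' @param pupil_noise_ar AR(1) coefficient of the pupil noise at 1000 Hz.
#' @param blink_rate,saccade_rate events per second.
#' @param blink_dur_ms,saccade_dur_ms duration range (min, max) in ms.
#' @param psychometric_midpoint named numeric per group, dB SNR at which
#'   keyword identification is 50% correct for an average participant.
#' @param psychometric_slope logistic slope, 1/dB.
#' @param midpoint_coef_pta dB of midpoint shift per dB HL of PTA4k above
#'   10 dB HL (subclinical threshold contribution).
#' @param midpoint_coef_survival dB of midpoint shift per unit of (1 -
#'   survival) (neural-degeneration contribution).
#' @param midpoint_coef_effort dB of midpoint shift per %/s of
#'   subject-specific 10 dB listening-slope deviation (effort contribution).
#' @param midpoint_sd residual SD of the per-subject midpoint (dB).
#' @param pta4k_mean,pta4k_sd named numeric per group / numeric: pure-tone
#'   average 0.5-4 kHz, dB HL.
#' @param ehf_mean,ehf_sd extended-high-frequency (>8 kHz) threshold mean per
#'   group and SD, dB HL (carried as a covariate; does not drive behavior).
#' @param gerbil_n_per_group named integer, gerbils per age group.
#' @param gerbil_synapse_mean_young mean synapses per inner hair cell at the
#'   3 kHz place in young gerbils.
#' @param gerbil_synapse_loss fraction of synapses lost in middle-aged
#'   gerbils relative to young.
#' @param gerbil_synapse_sd between-animal synapse-count SD.
#' @param gerbil_efr_intercept,gerbil_efr_slope,gerbil_efr_sd linear link
#'   efr = a + b * synapses + N(0, sd) (uV).
#' @param seed integer seed stored with the configuration.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = c(YA = 4, MA = 4), seed = 1)
#' cfg$synapse_survival_mean
cohort_config <- function(
    n_per_group = c(YA = 35, MA = 37),
    group_labels = c("YA", "MA"),
    synapse_survival_mean = c(YA = 1.0, MA = 0.8),
    synapse_survival_sd = 0.10,
    efr_gain = 0.12,
    efr_amp_by_rate = c(
      "16" = 0.50, "40" = 0.40, "110" = 0.25, "256" = 0.18,
      "512" = 0.12, "724" = 0.08, "1024" = 0
    ),
    carrier_amp_uv = 0.5,
    noise_spectrum_level = 0.13,
    artifact_rate = 0.03,
    fs_hz = 16384,
    n_epochs = 500,
    pupil_baseline_au = 4000,
    effort_slope_listening = c(
      "25" = 0.5, "20" = 0.8, "15" = 1.2, "10" = 2.0, "5" = 2.8, "0" = 3.5
    ),
    effort_slope_group_delta = c(
      "25" = 0, "20" = 0, "15" = 0.3, "10" = 1.0, "5" = 0.4, "0" = 0.2
    ),
    integration_slope_scale = 0.5,
    effort_quad_coef = -0.15,
    slope_sd_shared = 0.2,
    slope_sd_specific = 0.6,
    pupil_noise_sd = 2,
    pupil_noise_ar = 0.98,
    blink_rate = 0.15,
    saccade_rate = 0.3,
    blink_dur_ms = c(100, 400),
    saccade_dur_ms = c(20, 60),
    psychometric_midpoint = c(YA = -3.0, MA = -1.5),
    psychometric_slope = 0.4,
    midpoint_coef_pta = 0.2,
    midpoint_coef_survival = 6,
    midpoint_coef_effort = 1.2,
    midpoint_sd = 0.5,
    pta4k_mean = c(YA = 8, MA = 12),
    pta4k_sd = 4,
    ehf_mean = c(YA = 15, MA = 30),
    ehf_sd = 8,
    gerbil_n_per_group = c(young = 14, middle_aged = 13),
    gerbil_synapse_mean_young = 14,
    gerbil_synapse_loss = 0.20,
    gerbil_synapse_sd = 1.5,
    gerbil_efr_intercept = 0.01,
    gerbil_efr_slope = 0.0064,
    gerbil_efr_sd = 0.010,
    seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$group_labels) != 2 || anyDuplicated(cfg$group_labels)) {
    abort("`group_labels` must be two distinct labels.")
  }
  if (!setequal(names(cfg$n_per_group), cfg$group_labels)) {
    abort("`n_per_group` must be named by the group labels.")
  }
  if (any(cfg$n_per_group < 2)) {
    abort("Need at least 2 participants per group.")
  }
  if (!setequal(names(cfg$synapse_survival_mean), cfg$group_labels)) {
    abort("`synapse_survival_mean` must be named by the group labels.")
  }
  if (any(cfg$synapse_survival_mean <= 0 | cfg$synapse_survival_mean > 1)) {
    abort("Survival means must lie in (0, 1].")
  }
  rates <- c(
    "synapse_survival_sd", "efr_gain", "noise_spectrum_level",
    "artifact_rate", "blink_rate", "saccade_rate", "pupil_noise_sd",
    "gerbil_synapse_sd", "gerbil_efr_sd", "midpoint_sd",
    "slope_sd_shared", "slope_sd_specific"
  )
  for (nm in rates) {
    if (cfg[[nm]] < 0) abort(paste0("`", nm, "` must be >= 0."))
  }
  if (cfg$artifact_rate > 1) abort("`artifact_rate` must be <= 1.")
  if (!setequal(
    names(cfg$effort_slope_listening),
    names(cfg$effort_slope_group_delta)
  )) {
    abort("Listening slopes and group deltas must cover the same SNRs.")
  }
  if (!all(is.finite(c(cfg$psychometric_midpoint, cfg$psychometric_slope)))) {
    abort("Psychometric parameters must be finite.")
  }
  if (cfg$fs_hz <= 2 * 3000) {
    abort("`fs_hz` must exceed twice the 3 kHz carrier frequency.")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(
    "  groups:",
    paste0(
      x$group_labels, " (n=", x$n_per_group[x$group_labels],
      ", survival ", x$synapse_survival_mean[x$group_labels], ")",
      collapse = ", "
    ), "\n"
  )
  cat(
    "  EFR: gain", x$efr_gain, "uV/survival at 1024 Hz AM,",
    "noise", x$noise_spectrum_level, "uV/sqrt(Hz), fs", x$fs_hz, "Hz\n"
  )
  cat(
    "  pupil: slopes",
    paste0(
      names(x$effort_slope_listening), "dB=",
      x$effort_slope_listening,
      collapse = " "
    ), "%/s\n"
  )
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file holds any subset of [cohort_config()] arguments; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the yaml package.")
    }
    yaml::read_yaml(path)
  } else {
    # simplifyVector drops element names, which the group-keyed fields need
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0(
      "Unknown config keys: ", paste(unknown, collapse = ", ")
    ))
  }
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(cohort_config, vals)
}
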