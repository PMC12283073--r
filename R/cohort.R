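#' Simulate a human cohort with known ground truth
#'
#' Draws one record per participant: group membership, observed covariates
#' (PTA4k, extended-high-frequency thresholds) and the latent quantities the
#' generator needs downstream - synapse survival, per-condition pupillary
#' effort slopes, and the psychometric midpoint. Latent columns are
#' namespaced with a leading `".latent_"` so that analysis stages can be
#' audited never to consume ground truth.
#'
#' The latent psychometric midpoint combines the group base midpoint with
#' contributions from subclinical thresholds, neural survival and the
#' subject-specific 10 dB listening-effort deviation, which is what makes
#' PTA4k, the 1024 Hz EFR and the 10 dB listening slope the true drivers of
#' low-SNR keyword accuracy in the synthetic world.
#'
#' @param config a [cohort_config()].
#' @param seed integer; defaults to the seed embedded in `config`.
#' @return A tibble with one row per participant: `id`, `group`, `pta4k`,
#'   `ehf_mean`, and `.latent_*` ground-truth columns (survival, midpoint,
#'   and one slope per window x SNR).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_group = c(YA = 3, MA = 3)))
#' names(cohort)
simulate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  snrs <- as.numeric(names(config$effort_slope_listening))

  groups <- rep(config$group_labels, config$n_per_group[config$group_labels])
  n <- length(groups)
  survival <- rnorm(
    n,
    mean = config$synapse_survival_mean[groups],
    sd = config$synapse_survival_sd
  )
  survival <- pmin(pmax(survival, 1e-6), 1)

  pta4k <- rnorm(n, config$pta4k_mean[groups], config$pta4k_sd)
  ehf <- rnorm(n, config$ehf_mean[groups], config$ehf_sd)

  shared <- rnorm(n, 0, config$slope_sd_shared)
  is_ref <- groups == config$group_labels[1]
  cells <- matrix(NA_real_, n, length(snrs))
  specific10 <- numeric(n)
  for (j in seq_along(snrs)) {
    snr_key <- names(config$effort_slope_listening)[j]
    mu <- config$effort_slope_listening[snr_key] +
      ifelse(is_ref, 0, config$effort_slope_group_delta[snr_key])
    specific <- rnorm(n, 0, config$slope_sd_specific)
    if (snrs[j] == 10) specific10 <- specific
    cells[, j] <- mu + shared + specific
  }
  colnames(cells) <- paste0(".latent_slope_listening_", names(config$effort_slope_listening))

  integ <- cells * config$integration_slope_scale
  colnames(integ) <- sub("listening", "integration", colnames(cells))

  # The behavioral effort contribution uses the condition-specific 10 dB
  # deviation (not the shared trait), so the 10 dB listening slope is the
  # only slope variable that truly drives low-SNR accuracy.
  slope10_dev <- specific10
  midpoint <- config$psychometric_midpoint[groups] +
    config$midpoint_coef_pta * (pta4k - 10) +
    config$midpoint_coef_survival * (1 - survival) +
    config$midpoint_coef_effort * slope10_dev +
    rnorm(n, 0, config$midpoint_sd)

  out <- tibble(
    id = sprintf("S%03d", seq_len(n)),
    group = factor(groups, levels = config$group_labels),
    pta4k = pta4k,
    ehf_mean = ehf,
    .latent_survival = survival,
    .latent_midpoint = unname(midpoint)
  )
  bind_cols_matrix(bind_cols_matrix(out, cells), integ)
}

bind_cols_matrix <- function(df, m) {
  for (nm in colnames(m)) df[[nm]] <- unname(m[, nm])
  df
}

#' Extract the per-window latent effort slopes in long format
#'
#' Helper for tests and recovery checks; analysis stages do not use it.
#'
#' @param cohort output of [simulate_cohort()].
#' @return Tibble with `id`, `window`, `snr`, `true_slope`.
#' @export
true_effort_slopes <- function(cohort) {
  cohort %>%
    select("id", dplyr::starts_with(".latent_slope_")) %>%
    tidyr::pivot_longer(
      -"id",
      names_to = c("window", "snr"),
      names_pattern = "\\.latent_slope_([a-z]+)_(\\d+)",
      values_to = "true_slope"
    ) %>%
    mutate(snr = as.numeric(.data$snr))
}

#' Simulate a gerbil cohort with a linear synapse-to-EFR link
#'
#' Synapse counts per inner hair cell at the 3 kHz cochlear place are drawn
#' per age group, with the middle-aged mean set to a configured fraction of
#' the young mean; 1024 Hz EFR amplitudes follow the linear link
#' `efr = a + b * synapses + N(0, sd)`.
#'
#' @inheritParams simulate_cohort
#' @return Tibble: `id`, `age_group`, `synapse_count`, `efr_amp_1024`.
#' @export
#' @examples
#' gerbils <- synthesize_gerbil_cohort(cohort_config(seed = 2))
#' cor(gerbils$synapse_count, gerbils$efr_amp_1024)
synthesize_gerbil_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  n_young <- config$gerbil_n_per_group[["young"]]
  n_ma <- config$gerbil_n_per_group[["middle_aged"]]
  mu_young <- config$gerbil_synapse_mean_young
  mu_ma <- mu_young * (1 - config$gerbil_synapse_loss)
  age <- rep(c("young", "middle_aged"), c(n_young, n_ma))
  syn <- pmax(rnorm(
    n_young + n_ma,
    mean = ifelse(age == "young", mu_young, mu_ma),
    sd = config$gerbil_synapse_sd
  ), 0)
  efr <- pmax(
    config$gerbil_efr_intercept + config$gerbil_efr_slope * syn +
      rnorm(length(syn), 0, config$gerbil_efr_sd),
    0
  )
  tibble(
    id = sprintf("G%02d", seq_along(age)),
    age_group = factor(age, levels = c("young", "middle_aged")),
    synapse_count = syn,
    efr_amp_1024 = efr
  )
}
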