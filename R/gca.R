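#' Orthonormal polynomial time basis
#'
#' Gram-Schmidt orthonormalization of \{1, t, t^2\} on the realized time
#' grid (the constant is absorbed into the model intercept). `ot1` is the
#' linear term (rate of dilation) and `ot2` the quadratic term (curvature);
#' both have unit norm, are mutually orthogonal and orthogonal to the
#' constant vector.
#'
#' @param t numeric time grid (length >= 3) or a single integer giving the
#'   number of equally spaced points.
#' @return Tibble with columns `t`, `ot1`, `ot2`.
#' @export
#' @examples
#' b <- orthogonal_time_basis(5)
#' crossprod(as.matrix(b[, c("ot1", "ot2")]))
orthogonal_time_basis <- function(t) {
  if (length(t) == 1) {
    if (t < 3) abort("Need at least 3 timepoints.")
    t <- seq_len(t)
  }
  if (length(t) < 3) abort("Need at least 3 timepoints.")
  p <- poly(t, degree = 2)
  tibble(t = t, ot1 = p[, 1], ot2 = p[, 2])
}

#' Fit the second-order growth-curve mixed model
#'
#' Models baseline-normalized pupil values as
#' `Pupil ~ (ot1 + ot2) * SNR * Group` with treatment coding (reference SNR
#' 25 dB, reference group the first factor level), fit by maximum
#' likelihood (`REML = FALSE`, bobyqa optimizer). The random-effect
#' structure follows the window: for the listening window, uncorrelated
#' `ot1` and `ot2` slopes per participant (no random intercept) plus
#' correlated `ot1 + ot2` (with intercept) per participant-by-SNR cell; for
#' the integration window, correlated `ot1 + ot2` per participant plus the
#' same per-cell term. Factors with a single level in the data are dropped
#' from the fixed-effect formula, so the same function fits degenerate
#' designs (one group, one SNR). Wald p-values use the large-sample normal
#' approximation of the t-ratio; small-sample p-values from
#' degrees-of-freedom approximations may differ.
#'
#' @param window_table long tibble with `id`, `group`, `snr`, `t_rel_s`,
#'   `value` (typically from [average_by_condition()]).
#' @param window `"listening"` or `"integration"` (selects the random
#'   structure).
#' @param random_effects set `FALSE` to fit the fixed-effect structure by
#'   ordinary maximum likelihood (no random terms) - useful for noiseless
#'   identifiability checks.
#' @param optimizer lme4 optimizer label. The default `"nloptwrap"` reaches
#'   the same maximum as `"bobyqa"` on this model class (asserted in the
#'   test suite) in roughly a third of the time.
#' @return Object of class `"gca_fit"`: the lme4 (or lm) model plus a tidy
#'   fixed-effects table, convergence flags and the time basis.
#' @export
fit_gca <- function(window_table, window = c("listening", "integration"),
                    random_effects = TRUE, optimizer = "nloptwrap") {
  window <- match.arg(window)
  d <- as_tibble(window_table)
  need <- c("id", "group", "snr", "t_rel_s", "value")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  grid <- sort(unique(d$t_rel_s))
  basis <- orthogonal_time_basis(grid)
  d <- d %>%
    left_join(rename(basis, t_rel_s = "t"), by = "t_rel_s") %>%
    mutate(
      snr_f = factor(.data$snr, levels = sort(unique(.data$snr), decreasing = TRUE)),
      group_f = if (is.factor(.data$group)) droplevels(.data$group) else factor(.data$group),
      cell = interaction(.data$id, .data$snr, sep = ":", drop = TRUE)
    )

  fx <- "(ot1 + ot2)"
  if (nlevels(d$snr_f) > 1) fx <- paste0(fx, " * snr_f")
  if (nlevels(d$group_f) > 1) fx <- paste0(fx, " * group_f")
  multi_snr <- nlevels(d$snr_f) > 1

  if (!random_effects) {
    model <- lm(stats::as.formula(paste("value ~", fx)), data = d)
    # noiseless identifiability checks produce "essentially perfect fit"
    co <- suppressWarnings(summary(model)$coefficients)
    fixed <- tibble(
      term = rownames(co), estimate = co[, 1], se = co[, 2],
      t = co[, 3], p = 2 * pnorm(-abs(co[, 3]))
    )
    out <- list(
      model = model, window = window, fixed = fixed, converged = TRUE,
      singular = FALSE, basis = basis, data = d, random_effects = FALSE
    )
    class(out) <- "gca_fit"
    return(out)
  }

  re <- if (window == "listening") {
    "(0 + ot1 + ot2 || id)"
  } else {
    "(ot1 + ot2 | id)"
  }
  if (multi_snr) re <- paste0(re, " + (ot1 + ot2 | cell)")
  form <- stats::as.formula(paste("value ~", fx, "+", re))
  model <- withCallingHandlers(
    lme4::lmer(
      form,
      data = d, REML = FALSE,
      control = lme4::lmerControl(optimizer = optimizer, calc.derivs = FALSE)
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  co <- as.data.frame(summary(model)$coefficients)
  fixed <- tibble(
    term = rownames(co), estimate = co[, 1], se = co[, 2],
    t = co[, 3], p = 2 * pnorm(-abs(co[, 3]))
  )
  conv <- model@optinfo$conv$opt == 0
  out <- list(
    model = model, window = window, fixed = fixed,
    converged = isTRUE(conv), singular = lme4::isSingular(model),
    basis = basis, data = d, random_effects = TRUE
  )
  class(out) <- "gca_fit"
  out
}

#' @export
print.gca_fit <- function(x, ...) {
  cat(
    "<gca_fit>", x$window, "window;",
    nrow(x$data), "observations;",
    if (x$converged) "converged" else "NOT converged",
    if (x$singular) "(singular fit)" else "", "\n"
  )
  print(x$fixed, n = 6)
  invisible(x)
}

#' @export
tidy.gca_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  x$fixed %>%
    mutate(
      conf_low = .data$estimate - z * .data$se,
      conf_high = .data$estimate + z * .data$se
    )
}

#' @export
glance.gca_fit <- function(x, ...) {
  ll <- as.numeric(logLik(x$model))
  tibble(
    window = x$window,
    n_obs = nrow(x$data),
    log_likelihood = ll,
    aic = stats::AIC(x$model),
    converged = x$converged,
    singular = x$singular
  )
}

#' Per-participant, per-SNR pupillary slope indices
#'
#' The default (`"blup"`) slope is the fixed-effect `ot1` total for the
#' participant's group x SNR cell plus the conditional modes of the
#' participant-level and participant-by-SNR `ot1` random effects. The
#' `"ols"` alternative is the per-cell ordinary least-squares `ot1`
#' coefficient, bypassing the mixed model. Slopes are reported both in
#' `ot1` units and converted to percent change per second (`slope_pps`).
#'
#' @param fit a converged [fit_gca()] object (`"blup"`), or the window
#'   table itself (`"ols"`).
#' @param method `"blup"` or `"ols"`.
#' @return Tibble: `id`, `group`, `snr`, `slope_ot1`, `slope_pps`.
#' @export
extract_slopes <- function(fit, method = c("blup", "ols")) {
  method <- match.arg(method)
  if (method == "ols") {
    d <- if (inherits(fit, "gca_fit")) fit$data else as_tibble(fit)
    if (!"ot1" %in% names(d)) {
      grid <- sort(unique(d$t_rel_s))
      basis <- orthogonal_time_basis(grid)
      d <- left_join(d, rename(basis, t_rel_s = "t"), by = "t_rel_s")
    }
    conv <- ot1_per_second(d)
    return(
      d %>%
        group_by(.data$id, .data$group, .data$snr) %>%
        summarise(
          # ot1 is orthonormal and orthogonal to 1 and ot2, so the OLS
          # coefficient is the inner product with the response
          slope_ot1 = sum(.data$value * .data$ot1),
          .groups = "drop"
        ) %>%
        mutate(slope_pps = .data$slope_ot1 * conv) %>%
        arrange(.data$id, dplyr::desc(.data$snr))
    )
  }
  if (!inherits(fit, "gca_fit")) abort("`fit` must be a gca_fit.")
  if (!fit$converged) abort("Cannot extract slopes from an unconverged fit.")
  d <- fit$data
  cells <- distinct(d, .data$id, .data$group, .data$snr, .data$snr_f, .data$group_f, .data$cell)

  fe <- fixed_ot1_totals(fit)
  cells <- left_join(cells, fe, by = c("snr_f", "group_f"))

  if (fit$random_effects) {
    re <- lme4::ranef(fit$model)
    for (k in seq_along(re)) {
      mat <- re[[k]]
      if (!"ot1" %in% colnames(mat)) next
      key <- rownames(mat)
      add <- setNames(mat[["ot1"]], key)
      grp_name <- names(re)[k]
      if (grp_name == "id") {
        cells$fixed_total <- cells$fixed_total + add[as.character(cells$id)]
      } else {
        cells$fixed_total <- cells$fixed_total +
          add[as.character(cells$cell)]
      }
    }
  }
  conv <- ot1_per_second(d)
  cells %>%
    arrange(.data$id, dplyr::desc(.data$snr)) %>%
    transmute(
      id = .data$id, group = .data$group, snr = .data$snr,
      slope_ot1 = .data$fixed_total,
      slope_pps = .data$fixed_total * conv
    )
}

# ot1 is linear in t; its per-second rate converts ot1-unit slopes to %/s
ot1_per_second <- function(d) {
  b <- distinct(d, .data$t_rel_s, .data$ot1) %>% arrange(.data$t_rel_s)
  (b$ot1[nrow(b)] - b$ot1[1]) / (b$t_rel_s[nrow(b)] - b$t_rel_s[1])
}

# Fixed-effect ot1 totals per (snr_f, group_f) cell via model-matrix rows
fixed_ot1_totals <- function(fit) {
  d <- fit$data
  cells <- distinct(d, .data$snr_f, .data$group_f)
  beta <- if (fit$random_effects) lme4::fixef(fit$model) else coef(fit$model)
  nd0 <- cells %>% mutate(ot1 = 0, ot2 = 0, value = 0)
  nd1 <- cells %>% mutate(ot1 = 1, ot2 = 0, value = 0)
  ff <- stats::formula(fit$model)
  tt <- delete.response(terms(lme4::nobars(ff)))
  x0 <- model.matrix(tt, nd0)
  x1 <- model.matrix(tt, nd1)
  cells$fixed_total <- as.numeric((x1 - x0) %*% beta)
  cells
}
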