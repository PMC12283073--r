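#' Factorial / mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Sequential (Type I) sums-of-squares ANOVA via `aov` with treatment
#' contrasts (the `aov` convention). With a repeated
#' factor (`within`), the design is `dv ~ between * within +
#' Error(id/within)`; when the repeated factor has more than two levels,
#' the Greenhouse-Geisser epsilon is estimated from the pooled
#' within-group covariance of the repeated measures and applied to the
#' degrees of freedom of every effect involving the repeated factor
#' (producing the fractional df familiar from sphericity-corrected
#' tables). Epsilon equals 1 when the covariance is compound symmetric.
#'
#' @param data long tibble.
#' @param dv,id,between,within column names (strings); `between` and/or
#'   `within` may be `NULL`.
#' @param gg_correct apply the Greenhouse-Geisser correction to repeated
#'   effects with more than 2 levels.
#' @return Tibble of class `"anova_result"`: `effect`, `df_num`, `df_den`,
#'   `statistic` (F), `p_value`, `epsilon` (NA for between effects).
#' @export
#' @examples
#' d <- tidyr::expand_grid(id = factor(1:8), rate = factor(c(40, 1024)))
#' d$group <- rep(c("YA", "MA"), each = 8)
#' d$amp <- rnorm(nrow(d))
#' mixed_anova(d, dv = "amp", id = "id", between = "group", within = "rate")
mixed_anova <- function(data, dv, id, between = NULL, within = NULL,
                        gg_correct = TRUE) {
  d <- as_tibble(data)
  for (v in c(id, between, within)) d[[v]] <- factor(d[[v]])
  rhs <- paste(c(between, within), collapse = " * ")
  if (rhs == "") abort("Need at least one factor.")

  if (is.null(within)) {
    form <- stats::as.formula(paste(dv, "~", rhs))
    fit <- aov(form, data = d)
    s <- summary(fit)[[1]]
    eff <- trimws(rownames(s))
    resid_row <- eff == "Residuals"
    out <- tibble(
      effect = eff[!resid_row],
      df_num = s$Df[!resid_row],
      df_den = s$Df[resid_row],
      statistic = s$`F value`[!resid_row],
      p_value = s$`Pr(>F)`[!resid_row],
      epsilon = NA_real_
    )
    class(out) <- c("anova_result", class(out))
    return(out)
  }

  check_balanced_cells(d, id, within)
  form <- stats::as.formula(paste(
    dv, "~", rhs, "+ Error(", id, "/", within, ")"
  ))
  fit <- aov(form, data = d)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    resid_row <- eff == "Residuals"
    if (all(resid_row)) next
    df_den <- tab$Df[resid_row]
    for (i in which(!resid_row)) {
      rows[[length(rows) + 1]] <- tibble(
        effect = eff[i], df_num = tab$Df[i], df_den = df_den,
        statistic = tab$`F value`[i], p_value = tab$`Pr(>F)`[i]
      )
    }
  }
  out <- bind_rows(rows)

  k <- nlevels(d[[within]])
  eps <- NA_real_
  if (gg_correct && k > 2) {
    eps <- gg_epsilon(d, dv, id, between, within)
    is_within <- grepl(within, out$effect, fixed = TRUE)
    out <- out %>%
      mutate(
        epsilon = ifelse(is_within, eps, NA_real_),
        df_num = ifelse(is_within, .data$df_num * eps, .data$df_num),
        df_den = ifelse(is_within, .data$df_den * eps, .data$df_den),
        p_value = ifelse(
          is_within,
          stats::pf(.data$statistic, .data$df_num, .data$df_den,
            lower.tail = FALSE
          ),
          .data$p_value
        )
      )
  } else {
    out$epsilon <- NA_real_
  }
  class(out) <- c("anova_result", class(out))
  out
}

check_balanced_cells <- function(d, id, within) {
  counts <- table(d[[id]], d[[within]])
  if (any(counts != 1)) {
    abort("Repeated design needs exactly one observation per id x within cell.")
  }
  invisible(TRUE)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures, via normalized orthogonal contrasts.
gg_epsilon <- function(d, dv, id, between, within) {
  wide <- d %>%
    select(dplyr::all_of(c(id, between, within, dv))) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(within), values_from = dplyr::all_of(dv))
  k <- nlevels(d[[within]])
  y <- as.matrix(wide[, (ncol(wide) - k + 1):ncol(wide)])
  if (!is.null(between)) {
    groups <- wide[[between]]
    y <- y - apply(y, 2, stats::ave, groups)
    n_groups <- nlevels(factor(groups))
  } else {
    y <- scale(y, center = TRUE, scale = FALSE)
    n_groups <- 1
  }
  s <- crossprod(y) / (nrow(y) - n_groups)
  ctr <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
  m <- t(ctr) %*% s %*% ctr
  sum(diag(m))^2 / ((k - 1) * sum(m^2))
}

#' Bonferroni-adjusted per-level follow-up contrasts
#'
#' After a mixed ANOVA, tests the between-group difference separately at
#' each level of the repeated factor (one-way sequential ANOVA per level)
#' and Bonferroni-adjusts the p-values across levels.
#'
#' @param data long tibble.
#' @param dv,between,within column names (strings).
#' @return Tibble: `level`, `df_num`, `df_den`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
followup_by_level <- function(data, dv, between, within) {
  d <- as_tibble(data)
  levels_w <- unique(d[[within]])
  res <- purrr::map(levels_w, function(lv) {
    sub <- d[d[[within]] == lv, ]
    a <- mixed_anova(sub, dv = dv, id = NULL, between = between)
    tibble(
      level = lv, df_num = a$df_num[1], df_den = a$df_den[1],
      statistic = a$statistic[1], p_value = a$p_value[1]
    )
  })
  out <- bind_rows(res)
  out$p_adjusted <- pmin(1, out$p_value * length(levels_w))
  out
}

#' Tukey's fence outlier screen
#'
#' Removes observations outside `[Q1 - k IQR, Q3 + k IQR]`. Quartiles use
#' linear interpolation of order statistics (R's default type 7 quantile
#' convention); when IQR is zero the fences collapse onto the common
#' quartile value and equal observations are retained.
#'
#' @param x numeric vector, length >= 4.
#' @param k fence multiplier.
#' @return Numeric vector of retained values, with attributes `removed`
#'   (indices removed) and `fences`.
#' @export
#' @examples
#' tukey_fence(c(1, 2, 3, 4, 100))
tukey_fence <- function(x, k = pipeline_defaults()$tukey_k) {
  if (sum(is.finite(x)) < 4) abort("Tukey's fence needs at least 4 values.")
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  keep <- x >= fences[1] & x <= fences[2] & !is.na(x)
  out <- x[keep]
  attr(out, "removed") <- which(!keep)
  attr(out, "fences") <- fences
  out
}

#' Outlier-screened Pearson correlation
#'
#' Applies Tukey's fence to each variable, retains pairwise-complete
#' in-fence observations, and reports Pearson's r with the two-sided
#' t-transform p-value on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors.
#' @param screen apply the Tukey fence before correlating.
#' @param k fence multiplier.
#' @return One-row tibble: `r`, `df`, `p_value`, `n`, `n_removed_outliers`.
#' @export
#' @examples
#' pearson_cor(1:10, c(1:9, 40), screen = TRUE)
pearson_cor <- function(x, y, screen = TRUE,
                        k = pipeline_defaults()$tukey_k) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  removed <- 0L
  if (screen) {
    rx <- attr(tukey_fence(x, k), "removed")
    ry <- attr(tukey_fence(y, k), "removed")
    drop <- union(rx, ry)
    removed <- length(drop)
    if (removed > 0) {
      x <- x[-drop]
      y <- y[-drop]
    }
  }
  if (length(x) < 3) abort("Need at least 3 retained pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance after screening.")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n = length(x),
    n_removed_outliers = removed
  )
}

#' Elastic-net regression with grid cross-validation
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda * (alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2)` over an (alpha, lambda) grid, selecting the pair
#' that minimizes the 10-fold cross-validated out-of-sample RMSE.
#' Predictors are standardized internally; coefficients are reported on the
#' original scale. For each alpha the lambda path holds 100 log-spaced
#' values from the smallest lambda that zeroes every coefficient down four
#' decades. Fold assignment is seeded and stored for reproducibility.
#'
#' @param x numeric matrix or data frame of predictors (named columns).
#' @param y numeric outcome.
#' @param alpha_grid mixing values in `[0, 1]` (0 = ridge, 1 = lasso).
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param n_lambda,lambda_decades lambda path resolution and span.
#' @param fixed_lambda optional single lambda: skips cross-validation and
#'   fits at the given penalty (alpha taken from the first grid entry).
#' @return Object of class `"elnet_fit"`; see [tidy.elnet_fit()] and
#'   [glance.elnet_fit()].
#' @export
elastic_net_cv <- function(x, y,
                           alpha_grid = pipeline_defaults()$alpha_grid,
                           n_folds = pipeline_defaults()$n_folds,
                           seed = 1L,
                           n_lambda = pipeline_defaults()$n_lambda,
                           lambda_decades = pipeline_defaults()$lambda_decades,
                           fixed_lambda = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(apply(x, 2, sd) == 0)) {
    abort("Constant predictor: cannot standardize.")
  }
  n <- length(y)
  if (nrow(x) != n) abort("`x` and `y` sizes differ.")

  # glmnet standardizes the response internally, which rescales the l2
  # component of its penalty by sd(y); at alpha = 0 we convert lambda so the
  # fit solves the documented objective exactly (ridge closed form).
  lam_scale <- function(alpha) {
    if (alpha == 0) sqrt(mean((y - mean(y))^2)) else 1
  }

  if (!is.null(fixed_lambda)) {
    alpha <- alpha_grid[1]
    sc <- lam_scale(alpha)
    fit <- glmnet::glmnet(
      x, y,
      alpha = alpha,
      lambda = lambda_path(x, y, alpha, n_lambda, lambda_decades,
        floor_at = fixed_lambda
      ) * sc,
      thresh = 1e-12
    )
    return(new_elnet_fit(fit, x, y, alpha, fixed_lambda,
      cv_rmse = NA_real_, cv_pred = NULL, foldid = NULL,
      lambda_glmnet = fixed_lambda * sc
    ))
  }

  if (n <= n_folds) abort("Need more observations than folds.")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))

  best <- NULL
  for (alpha in alpha_grid) {
    sc <- lam_scale(alpha)
    lam <- lambda_path(x, y, alpha, n_lambda, lambda_decades) * sc
    cv <- glmnet::cv.glmnet(
      x, y,
      alpha = alpha, lambda = lam, foldid = foldid,
      type.measure = "mse", keep = TRUE, thresh = 1e-10
    )
    i <- which.min(cv$cvm)
    rmse <- sqrt(cv$cvm[i])
    if (is.null(best) || rmse < best$rmse) {
      best <- list(
        alpha = alpha, lambda = cv$lambda[i] / sc, rmse = rmse,
        lambda_glmnet = cv$lambda[i],
        cv_pred = cv$fit.preval[, i], glmnet_fit = cv$glmnet.fit
      )
    }
  }
  new_elnet_fit(
    best$glmnet_fit, x, y, best$alpha, best$lambda,
    cv_rmse = best$rmse, cv_pred = best$cv_pred, foldid = foldid,
    lambda_glmnet = best$lambda_glmnet
  )
}

# Lambda path: n_lambda log-spaced values from lambda_max (the smallest
# penalty zeroing all coefficients under the 1/(2n) objective) down the
# requested number of decades. For alpha near 0 lambda_max diverges, so the
# mixing weight is floored at 0.001 as in the reference implementation.
lambda_path <- function(x, y, alpha, n_lambda, lambda_decades,
                        floor_at = NULL) {
  n <- nrow(x)
  xs <- scale(x, center = TRUE, scale = apply(x, 2, function(c) {
    sqrt(mean((c - mean(c))^2))
  }))
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / (n * max(alpha, 1e-3))
  path <- 10^seq(log10(lmax), log10(lmax) - lambda_decades,
    length.out = n_lambda
  )
  if (!is.null(floor_at)) path <- unique(sort(c(path[path > floor_at], floor_at), decreasing = TRUE))
  path
}

new_elnet_fit <- function(fit, x, y, alpha, lambda, cv_rmse, cv_pred, foldid,
                          lambda_glmnet = lambda) {
  cf <- as.matrix(coef(fit, s = lambda_glmnet, exact = FALSE))
  pred <- as.numeric(predict(fit, newx = x, s = lambda_glmnet))
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  cv_r <- if (!is.null(cv_pred) && sd(cv_pred) > 0) cor(cv_pred, y) else NA_real_
  out <- list(
    alpha = alpha,
    lambda = lambda,
    coefficients = tibble(term = rownames(cf), estimate = cf[, 1]),
    selected_predictors = rownames(cf)[-1][cf[-1, 1] != 0],
    cv_rmse = cv_rmse,
    r_squared = r2,
    cv_r = cv_r,
    cv_pseudo_r2 = if (is.na(cv_r)) NA_real_ else cv_r^2,
    fitted = pred,
    cv_pred = cv_pred,
    y = y,
    model = fit,
    foldid = foldid
  )
  class(out) <- "elnet_fit"
  out
}

#' @export
print.elnet_fit <- function(x, ...) {
  cat(
    "<elnet_fit> alpha =", x$alpha, " lambda =", signif(x$lambda, 4),
    " cv RMSE =", signif(x$cv_rmse, 4), "\n",
    "selected:", paste(x$selected_predictors, collapse = ", "), "\n",
    "training R^2 =", signif(x$r_squared, 4),
    "; CV predicted-vs-observed r =", signif(x$cv_r, 3), "\n"
  )
  invisible(x)
}

#' Tidy an elastic-net fit
#'
#' @param x an `"elnet_fit"`.
#' @param ... unused.
#' @return Tibble `term`, `estimate`, `selected`.
#' @export
tidy.elnet_fit <- function(x, ...) {
  x$coefficients %>%
    mutate(selected = .data$term %in% x$selected_predictors |
      .data$term == "(Intercept)")
}

#' One-row summary of an elastic-net fit
#'
#' Reports both the training R-squared of the selected model and the
#' cross-validated predicted-vs-observed correlation (with its square as a
#' pseudo R-squared); the two answer different questions and are both
#' quoted in this literature.
#'
#' @inheritParams tidy.elnet_fit
#' @return One-row tibble.
#' @export
glance.elnet_fit <- function(x, ...) {
  tibble(
    alpha = x$alpha, lambda = x$lambda, cv_rmse = x$cv_rmse,
    r_squared = x$r_squared, cv_r = x$cv_r,
    cv_pseudo_r2 = x$cv_pseudo_r2,
    n_selected = length(x$selected_predictors)
  )
}

#' Assemble the predictor matrix and outcome for the association stage
#'
#' Joins subject-level tables into a design matrix with named columns -
#' `pta4k`, `efr_1024`, per-SNR listening and integration slopes, plus any
#' extra covariate columns - and the outcome `y`: keyword accuracy at 0 dB
#' SNR scaled to 0-100. Subjects with any missing value are dropped
#' (complete-case) and counted.
#'
#' @param cohort tibble with `id` and covariate columns.
#' @param efr_results tibble `id`, `am_rate_hz`, `amplitude`.
#' @param slopes tibble `id`, `window`, `snr`, `slope_pps`.
#' @param behavior tibble from [score_proportions()] with `id`.
#' @param covariates cohort columns to include as predictors.
#' @return List: `x` (matrix), `y`, `data` (the joined tibble), `n_dropped`.
#' @export
build_predictor_matrix <- function(cohort, efr_results, slopes, behavior,
                                   covariates = "pta4k") {
  efr_w <- efr_results %>%
    filter(.data$am_rate_hz == 1024) %>%
    select("id", efr_1024 = "amplitude")
  slopes_w <- slopes %>%
    mutate(col = paste0(
      ifelse(.data$window == "listening", "listen", "integ"),
      "_slope_", .data$snr
    )) %>%
    select("id", "col", "slope_pps") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "slope_pps")
  outcome <- behavior %>%
    filter(.data$snr == 0) %>%
    transmute(.data$id, quicksin0 = 100 * .data$proportion_correct)

  joined <- cohort %>%
    select("id", dplyr::all_of(covariates)) %>%
    left_join(efr_w, by = "id") %>%
    left_join(slopes_w, by = "id") %>%
    left_join(outcome, by = "id")
  if (nrow(joined) == 0) abort("Empty join: no common subjects.")
  complete <- complete.cases(joined)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped for missing data.")
  }
  joined <- joined[complete, ]
  pred_cols <- setdiff(names(joined), c("id", "quicksin0"))
  list(
    x = as.matrix(joined[, pred_cols]),
    y = joined$quicksin0,
    data = joined,
    n_dropped = n_dropped
  )
}
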