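test_that("between-group F matches a hand computation", {
  # two groups of three: {1, 2, 3} and {3, 4, 5}
  d <- tibble::tibble(
    y = c(1, 2, 3, 3, 4, 5),
    group = rep(c("a", "b"), each = 3)
  )
  a <- mixed_anova(d, dv = "y", id = NULL, between = "group")
  # MS_between = 6, MS_within = 1 -> F = 6 on (1, 4) df
  expect_equal(a$statistic, 6)
  expect_equal(a$df_num, 1)
  expect_equal(a$df_den, 4)
  expect_equal(a$p_value, stats::pf(6, 1, 4, lower.tail = FALSE))
})

test_that("identical group means give a null F", {
  d <- tibble::tibble(
    y = c(1, 2, 3, 2, 3, 1),
    group = rep(c("a", "b"), each = 3)
  )
  a <- mixed_anova(d, dv = "y", id = NULL, between = "group")
  expect_lt(a$statistic, 1e-10)
  expect_gt(a$p_value, 0.999)
})

test_that("compound-symmetric covariance yields epsilon of 1", {
  # craft data whose sample covariance is exactly compound symmetric
  set.seed(10)
  n <- 12
  k <- 4
  z <- qr.Q(qr(scale(matrix(rnorm(n * k), n, k), scale = FALSE)))
  z <- z * sqrt(n - 1) # exact identity sample covariance
  cs <- 1 * diag(k) + 2 # sigma^2 I + tau^2 J
  y <- z %*% chol(cs)
  d <- tidyr::expand_grid(id = seq_len(n), w = seq_len(k))
  d$y <- as.vector(t(y))
  a <- mixed_anova(d, dv = "y", id = "id", within = "w")
  expect_equal(a$epsilon[a$effect == "w"], 1, tolerance = 1e-8)
})

test_that("Greenhouse-Geisser output matches car::Anova", {
  skip_if_not_installed("car")
  set.seed(7)
  d <- tidyr::expand_grid(
    id = sprintf("s%02d", 1:12), rate = factor(c(40, 110, 512, 1024))
  )
  d$group <- ifelse(as.integer(sub("s", "", d$id)) <= 6, "YA", "MA")
  # heterogeneous correlation across rates -> epsilon < 1
  d$y <- rnorm(nrow(d)) + as.integer(d$rate) * 0.5 +
    rep(rnorm(12), each = 4) * as.integer(d$rate)
  a <- mixed_anova(d, dv = "y", id = "id", between = "group", within = "rate")

  wide <- tidyr::pivot_wider(d, names_from = rate, values_from = y)
  mlm <- lm(cbind(`40`, `110`, `512`, `1024`) ~ group, data = wide)
  ca <- summary(
    car::Anova(mlm,
      idata = data.frame(rate = factor(c(40, 110, 512, 1024))),
      idesign = ~rate
    ),
    multivariate = FALSE
  )
  eps_car <- ca$pval.adjustments["rate", "GG eps"]
  p_car <- ca$pval.adjustments["rate", "Pr(>F[GG])"]
  expect_equal(a$epsilon[a$effect == "rate"], eps_car, tolerance = 1e-8)
  expect_equal(a$p_value[a$effect == "rate"], p_car, tolerance = 1e-8)
  expect_lt(eps_car, 1)
})

test_that("repeated designs demand balanced cells", {
  d <- tidyr::expand_grid(id = 1:4, w = 1:3)
  d$y <- rnorm(12)
  expect_error(
    mixed_anova(d[-1, ], dv = "y", id = "id", within = "w"),
    "one observation per"
  )
})

test_that("tukey fence: worked example, ties, and identity", {
  kept <- tukey_fence(c(1, 2, 3, 4, 100))
  expect_equal(as.numeric(kept), c(1, 2, 3, 4))
  expect_equal(attr(kept, "removed"), 5L)
  expect_equal(unname(attr(kept, "fences")), c(2 - 3, 4 + 3))

  same <- tukey_fence(rep(7, 10))
  expect_equal(as.numeric(same), rep(7, 10))
  expect_length(attr(same, "removed"), 0)

  inside <- tukey_fence(c(10, 11, 12, 13, 14))
  expect_equal(as.numeric(inside), c(10, 11, 12, 13, 14))

  expect_error(tukey_fence(c(1, 2, 3)), "at least 4")
})

test_that("pearson: exact linearity, hand value, screening, errors", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1, screen = FALSE)$r, 1)

  res <- pearson_cor(c(1, 2, 3), c(2, 1, 3), screen = FALSE)
  expect_equal(res$r, 0.5)
  expect_equal(res$df, 1)

  # outlier pulled r negative; screening restores the positive trend
  xs <- c(1:9, 10)
  ys <- c(1:9 + 0.1 * rnorm(9, 0, 1e-6), -50)
  screened <- pearson_cor(xs, ys, screen = TRUE)
  expect_equal(screened$n_removed_outliers, 1)
  expect_gt(screened$r, 0.99)
  expect_equal(screened$df, 7)

  expect_error(pearson_cor(1:5, rep(2, 5), screen = FALSE), "variance")
  expect_error(pearson_cor(1:4, 1:5), "paired")
})

test_that("p-values are uniform under independence", {
  set.seed(2)
  ps <- vapply(1:200, function(i) {
    pearson_cor(rnorm(25), rnorm(25), screen = FALSE)$p_value
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

make_xy <- function(n = 60, p = 6, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- as.numeric(2 + x %*% c(1.5, -2, 0, 0.5, 0, 0) + rnorm(n, 0, 0.8))
  list(x = x, y = y)
}

test_that("lambda = 0 reproduces the normal-equations OLS solution", {
  d <- make_xy()
  fit <- elastic_net_cv(d$x, d$y, alpha_grid = 1, fixed_lambda = 0)
  xm <- cbind(1, d$x)
  ols <- solve(crossprod(xm), crossprod(xm, d$y))
  rel <- abs(fit$coefficients$estimate - ols) / pmax(abs(ols), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("alpha = 0 matches the closed-form ridge on standardized data", {
  d <- make_xy()
  sdn <- function(v) sqrt(mean((v - mean(v))^2))
  xs <- scale(d$x, center = TRUE, scale = apply(d$x, 2, sdn))
  for (lam in c(0.1, 0.7, 3)) {
    fit <- elastic_net_cv(xs, d$y, alpha_grid = 0, fixed_lambda = lam)
    closed <- solve(
      crossprod(xs) + nrow(xs) * lam * diag(ncol(xs)),
      crossprod(xs, d$y - mean(d$y))
    )
    rel <- abs(fit$coefficients$estimate[-1] - closed) / abs(closed)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("an overwhelming penalty returns the null model", {
  d <- make_xy()
  fit <- elastic_net_cv(d$x, d$y, alpha_grid = 0.5, fixed_lambda = 1e6)
  expect_true(all(fit$coefficients$estimate[-1] == 0))
  expect_equal(unname(fit$coefficients$estimate[1]), mean(d$y))
  expect_length(fit$selected_predictors, 0)
})

test_that("cross-validated selection is reproducible and sane", {
  d <- make_xy(seed = 9)
  f1 <- elastic_net_cv(d$x, d$y, seed = 5)
  f2 <- elastic_net_cv(d$x, d$y, seed = 5)
  expect_identical(tidy(f1), tidy(f2))
  expect_true(all(c("v1", "v2") %in% f1$selected_predictors))
  expect_gt(f1$r_squared, 0.7)
  g <- glance(f1)
  expect_true(g$cv_pseudo_r2 <= 1 && g$cv_r > 0)
  expect_error(elastic_net_cv(d$x[1:8, ], d$y[1:8]), "folds")
  xc <- d$x
  xc[, 3] <- 1
  expect_error(elastic_net_cv(xc, d$y), "Constant predictor")
})

test_that("predictor-column permutation leaves the selection unchanged", {
  d <- make_xy(seed = 13)
  f1 <- elastic_net_cv(d$x, d$y, seed = 5)
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- elastic_net_cv(d$x[, perm], d$y, seed = 5)
  expect_setequal(f1$selected_predictors, f2$selected_predictors)
})

test_that("predictor matrix assembly joins, names and drops correctly", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  efr <- tidyr::expand_grid(id = cohort$id, am_rate_hz = c(40, 1024))
  efr$amplitude <- runif(nrow(efr), 0.05, 0.2)
  slopes <- tidyr::expand_grid(
    id = cohort$id, window = c("listening", "integration"),
    snr = c(25, 20, 15, 10, 5, 0)
  )
  slopes$slope_pps <- rnorm(nrow(slopes), 2, 0.5)
  kw <- purrr::map_dfr(
    seq_len(nrow(cohort)),
    function(i) synthesize_quicksin(cohort[i, ], cfg, seed = i)
  )
  behavior <- score_proportions(kw)

  pm <- build_predictor_matrix(cohort, efr, slopes, behavior)
  expect_equal(nrow(pm$x), nrow(cohort))
  expect_true(all(
    c("pta4k", "efr_1024", "listen_slope_10", "integ_slope_0") %in%
      colnames(pm$x)
  ))
  expect_equal(pm$n_dropped, 0)
  expect_true(all(pm$y >= 0 & pm$y <= 100))

  # one subject without EFR -> complete-case drop of exactly one row
  efr_miss <- efr[efr$id != cohort$id[2], ]
  expect_message(
    pm2 <- build_predictor_matrix(cohort, efr_miss, slopes, behavior),
    "1 subject"
  )
  expect_equal(nrow(pm2$x), nrow(cohort) - 1)

  expect_error(
    build_predictor_matrix(cohort[0, ], efr, slopes, behavior),
    "Empty join"
  )
})
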