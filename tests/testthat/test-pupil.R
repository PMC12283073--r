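make_pupil_trial <- function(pupil, blink = NULL, saccade = NULL,
                             masker_onset = 2600, target_offset = 8600) {
  n <- length(pupil)
  structure(
    list(
      samples = tibble::tibble(
        time_ms = seq_len(n) - 1,
        pupil = pupil,
        blink = blink %||% rep(FALSE, n),
        saccade = saccade %||% rep(FALSE, n)
      ),
      events = c(
        masker_onset_ms = masker_onset, target_onset_ms = masker_onset + 3000,
        target_offset_ms = target_offset
      ),
      id = "T1", snr = 10, list_id = 1
    ),
    class = "pupil_trial"
  )
}

test_that("the 15% artifact rule uses strict inequality on window samples", {
  n <- 13000
  win <- 2600:8399 # listening window samples
  for (frac in c(0.149, 0.150, 0.151)) {
    blink <- rep(FALSE, n)
    blink[win[seq_len(round(frac * 5800))]] <- TRUE
    tr <- make_pupil_trial(rep(4000, n), blink = blink)
    expect_identical(
      reject_trial(tr, "listening"),
      frac > 0.15,
      info = paste("coverage", frac)
    )
  }
  expect_error(
    reject_trial(make_pupil_trial(numeric(0)), "listening"),
    "Empty"
  )
})

test_that("interpolation is exact on lines and constants", {
  n <- 13000
  ramp <- seq(4000, 4500, length.out = n)
  blink <- rep(FALSE, n)
  blink[3100:3200] <- TRUE
  tr <- make_pupil_trial(replace(ramp, blink, 0), blink = blink)
  out <- interpolate_artifacts(tr)
  expect_equal(out$samples$pupil, ramp, tolerance = 1e-12)

  const <- rep(4000, n)
  tr2 <- make_pupil_trial(replace(const, blink, 0), blink = blink)
  out2 <- interpolate_artifacts(tr2)
  expect_equal(out2$samples$pupil, const)
})

test_that("overlapping pads merge and match a brute-force oracle", {
  n <- 6000
  set.seed(8)
  x <- 4000 + cumsum(rnorm(n))
  blink <- rep(FALSE, n)
  blink[2000:2080] <- TRUE
  blink[2300:2360] <- TRUE # pads overlap: 2080+160 > 2300-60
  tr <- make_pupil_trial(replace(x, blink, 0), blink = blink)
  out <- interpolate_artifacts(tr)$samples$pupil

  # oracle: dilate the mask, then linearly interpolate each gap
  dil <- rep(FALSE, n)
  dil[(2000 - 60):(2080 + 160)] <- TRUE
  dil[(2300 - 60):(2360 + 160)] <- TRUE
  oracle <- replace(x, blink, 0)
  gaps <- split(which(dil), cumsum(c(1, diff(which(dil)) != 1))[])
  for (g in gaps) {
    a <- min(g) - 1
    b <- max(g) + 1
    oracle[g] <- oracle[a] + (oracle[b] - oracle[a]) * (g - a) / (b - a)
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # untouched samples are bit-identical
  expect_identical(out[!dil], replace(x, blink, 0)[!dil])
})

test_that("artifact spans touching the trace edge abort interpolation", {
  n <- 5000
  blink <- rep(FALSE, n)
  blink[1:30] <- TRUE
  tr <- make_pupil_trial(rep(4000, n), blink = blink)
  expect_error(interpolate_artifacts(tr), "boundary")
})

test_that("downsampling is 20-sample block means at block-mean times", {
  n <- 1000
  tr <- make_pupil_trial(rep(4000, n))
  down <- downsample_50hz(tr)
  expect_equal(nrow(down$samples), 50)
  expect_equal(down$samples$pupil, rep(4000, 50))

  ramp <- seq(0, 999, by = 1)
  tr2 <- make_pupil_trial(ramp)
  down2 <- downsample_50hz(tr2)
  # block means of a ramp are the ramp at the block-mean times
  expect_equal(down2$samples$pupil, down2$samples$time_ms)
  expect_equal(down2$samples$time_ms[1:2], c(9.5, 29.5))

  expect_error(
    downsample_50hz(tr, fs_hz = 990),
    "integer multiple"
  )
})

test_that("baseline normalization: identity, sign and failure cases", {
  n <- 13000
  tr <- make_pupil_trial(rep(4000, n))
  w <- baseline_normalize(downsample_50hz(tr), "listening")
  expect_equal(nrow(w), 290)
  expect_true(all(w$value == 0))
  expect_equal(w$baseline[1], 4000)

  stepped <- c(rep(4000, 2600), rep(4200, n - 2600))
  w_up <- baseline_normalize(
    downsample_50hz(make_pupil_trial(stepped)), "listening"
  )
  expect_equal(unique(w_up$value), 5)

  stepped_dn <- c(rep(4000, 2600), rep(3800, n - 2600))
  w_dn <- baseline_normalize(
    downsample_50hz(make_pupil_trial(stepped_dn)), "listening"
  )
  expect_equal(unique(w_dn$value), -5)

  zero <- make_pupil_trial(rep(0, n))
  expect_error(
    baseline_normalize(downsample_50hz(zero), "listening"),
    "positive"
  )
  short <- make_pupil_trial(rep(4000, 9000), masker_onset = 500)
  expect_error(
    baseline_normalize(downsample_50hz(short), "listening"),
    "1000 ms"
  )
})

test_that("normalization is invariant to overall trace scale", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  tr <- synthesize_pupil_trial(cohort[1, ], 5, 1, cfg, seed = 4)
  w1 <- process_pupil_trial(tr, "listening")
  tr$samples$pupil <- tr$samples$pupil * 3.7
  w2 <- process_pupil_trial(tr, "listening")
  expect_equal(w1$value, w2$value, tolerance = 1e-10)
})

test_that("noiseless programmed slopes are recovered from both windows", {
  cfg <- tiny_config(effort_quad_coef = 0)
  cohort <- simulate_cohort(cfg)
  p <- cohort[2, ]
  tr <- synthesize_pupil_trial(p, 10, 1, cfg, seed = 5, noise_scale = 0)
  for (w in c("listening", "integration")) {
    res <- process_pupil_trial(tr, w)
    slope <- coef(lm(value ~ t_rel_s, data = res))[2]
    truth <- p[[paste0(".latent_slope_", w, "_10")]]
    expect_equal(unname(slope), truth, tolerance = 1e-8)
  }
  # with curvature present, the window's least-squares slope still matches
  cfg_q <- tiny_config()
  cohort_q <- simulate_cohort(cfg_q)
  p_q <- cohort_q[2, ]
  tr_q <- synthesize_pupil_trial(p_q, 10, 1, cfg_q, seed = 5, noise_scale = 0)
  res_q <- process_pupil_trial(tr_q, "listening")
  slope_q <- coef(lm(value ~ t_rel_s, data = res_q))[2]
  expect_equal(
    unname(slope_q), p_q$.latent_slope_listening_10,
    tolerance = 1e-3
  )
})

test_that("a blink covering 20% of the window rejects the trial", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  tr <- synthesize_pupil_trial(cohort[1, ], 10, 1, cfg, seed = 6, noise_scale = 0)
  win <- tr$samples$time_ms >= 2600 & tr$samples$time_ms < 8400
  hit <- which(win)[seq_len(round(0.2 * sum(win)))]
  tr$samples$blink[hit] <- TRUE
  tr$samples$pupil[hit] <- 0
  expect_null(process_pupil_trial(tr, "listening"))
})

test_that("condition averaging matches direct recomputation", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  trials <- purrr::map(1:4, function(l) {
    synthesize_pupil_trial(cohort[1, ], 10, l, cfg, seed = 100 + l)
  })
  windows <- preprocess_pupil(trials, cohort, "listening")
  avg <- average_by_condition(windows)

  direct <- windows |>
    dplyr::group_by(t_rel_s) |>
    dplyr::summarise(value = mean(value))
  joined <- dplyr::left_join(avg, direct, by = "t_rel_s")
  expect_equal(joined$value.x, joined$value.y)
  expect_true(all(avg$n_trials == length(unique(windows$list_id))))

  # four identical trials average to each trial
  trials_same <- purrr::map(1:4, function(l) {
    t1 <- synthesize_pupil_trial(cohort[1, ], 10, 1, cfg,
      seed = 7, noise_scale = 0
    )
    t1$list_id <- l
    t1
  })
  w_same <- preprocess_pupil(trials_same, cohort, "listening")
  avg_same <- average_by_condition(w_same)
  one <- w_same[w_same$list_id == 1, ]
  expect_equal(avg_same$value, one$value)
})

test_that("flag_artifacts detects dropout and fast transients", {
  x <- rep(4000, 500)
  x[100:120] <- 0
  x[300] <- 4100
  s <- flag_artifacts(tibble::tibble(time_ms = 0:499, pupil = x))
  expect_true(all(s$blink[100:120]))
  expect_true(s$saccade[300])
  expect_false(any(s$saccade[c(99, 121)] & !s$blink[c(99, 121)] == FALSE))
})
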