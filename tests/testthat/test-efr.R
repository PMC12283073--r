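make_recording <- function(samples, fs = 8192, n_epochs = NULL,
                           am_rate = 1024, mode = "human") {
  epoch_len <- round(fs / 3.1)
  n_epochs <- n_epochs %||% floor(length(samples) / epoch_len)
  structure(
    list(
      samples = samples, fs = fs,
      events = tibble::tibble(
        onset = (seq_len(n_epochs) - 1L) * epoch_len + 1L,
        polarity = rep_len(c("+", "-"), n_epochs)
      ),
      stimulus = list(
        carrier_hz = 3000, am_rate_hz = am_rate, duration_s = 0.25,
        rise_fall_s = 0.005, rep_rate_hz = 3.1, mode = mode
      )
    ),
    class = "efr_recording"
  )
}

test_that("band-pass keeps in-band tones, kills out-of-band tones and DC", {
  fs <- 8192
  t <- (0:(fs * 2 - 1)) / fs
  mid <- (fs / 2):(fs * 3 / 2) # avoid edge transients

  rec <- make_recording(sin(2 * pi * 1024 * t), fs = fs)
  filt <- bandpass_filter(rec, 1024)
  expect_equal(max(abs(filt$samples[mid])), 1, tolerance = 0.01)

  rec_lo <- make_recording(sin(2 * pi * 10 * t), fs = fs)
  filt_lo <- bandpass_filter(rec_lo, 1024)
  atten <- 20 * log10(max(abs(filt_lo$samples[mid])))
  expect_lt(atten, -40)

  rec_dc <- make_recording(rep(5, fs * 2), fs = fs)
  filt_dc <- bandpass_filter(rec_dc, 1024)
  expect_lt(abs(mean(filt_dc$samples[mid])), 1e-6)

  expect_error(bandpass_filter(rec, 999), "No high-pass cutoff")
})

test_that("squared Butterworth magnitude matches the analytic response", {
  # |H(f)|^2 for one forward-backward pass of a 4th-order high-pass at fc:
  # 1 / (1 + (fc/f)^8), squared analog prototype; the digital design warps
  # frequencies, so compare against the bilinear-transform response of the
  # same butter() design evaluated independently via freqz.
  fs <- 8192
  hp <- signal::butter(4, 300 / (fs / 2), type = "high")
  f_probe <- c(10, 100, 300, 1024)
  h <- signal::freqz(hp$b, hp$a, 2 * pi * f_probe / fs)
  g_pkg <- earpipe:::bandpass_gain(f_probe, fs, hp = 300, lp = 3000) /
    earpipe:::bandpass_gain(f_probe, fs, hp = 0, lp = 3000)
  expect_equal(g_pkg, Mod(h$h)^2, tolerance = 1e-8)
})

test_that("epoch rejection: 37 hot epochs out of 500 leaves 463", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  samples <- rep(0, 500 * epoch_len)
  hot <- seq(5, by = 13, length.out = 37)
  for (e in hot) samples[(e - 1) * epoch_len + 100] <- 201
  rec <- make_recording(samples, fs = fs, n_epochs = 500)
  ep <- epoch_and_reject(rec, reject_uv = 200, mode = "human")
  expect_equal(ep$n_retained_pos + ep$n_retained_neg, 463)
  expect_equal(ep$n_rejected_pos + ep$n_rejected_neg, 37)
})

test_that("an epoch peaking exactly at 200 uV is retained", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  samples <- rep(0, 4 * epoch_len)
  samples[10] <- 200 # epoch 1: exactly at threshold
  samples[epoch_len + 10] <- 200.0001 # epoch 2: exceeds
  rec <- make_recording(samples, fs = fs, n_epochs = 4)
  ep <- epoch_and_reject(rec, reject_uv = 200, mode = "human")
  expect_equal(ep$n_retained_pos + ep$n_retained_neg, 3)
})

test_that("gerbil mode caps retention at 250 per polarity", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  rec <- make_recording(rep(0, 600 * epoch_len), fs = fs, n_epochs = 600)
  ep <- epoch_and_reject(rec, mode = "gerbil")
  expect_equal(ep$n_retained_pos, 250)
  expect_equal(ep$n_retained_neg, 250)
})

test_that("cross-polarity averaging cancels carrier, keeps envelope", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  t <- (0:(epoch_len - 1)) / fs
  carrier <- sin(2 * pi * 3000 * t)
  env <- 0.3 * sin(2 * pi * 512 * t)

  flip <- rep(c(1, -1), 10)
  samples <- as.vector(vapply(flip, function(s) s * carrier, numeric(epoch_len)))
  ep <- epoch_and_reject(make_recording(samples, fs, 20, am_rate = 512))
  expect_lt(max(abs(average_response(ep))), 1e-12)

  samples2 <- rep(env, 20)
  ep2 <- epoch_and_reject(make_recording(samples2, fs, 20, am_rate = 512))
  expect_equal(average_response(ep2), env, tolerance = 1e-12)
})

test_that("unbalanced polarity counts average as mean of polarity means", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  n_pos <- 5
  n_neg <- 2
  set.seed(1)
  pos <- matrix(rnorm(epoch_len * n_pos), epoch_len)
  neg <- matrix(rnorm(epoch_len * n_neg), epoch_len)
  ep <- structure(
    list(pos = pos, neg = neg),
    class = "efr_epochs"
  )
  expect_equal(
    average_response(ep),
    (rowMeans(pos) + rowMeans(neg)) / 2
  )
  ep_single <- structure(
    list(pos = pos, neg = neg[, 0, drop = FALSE]),
    class = "efr_epochs"
  )
  expect_error(average_response(ep_single), "polarity")
})

test_that("spectrum windowing and scaling follow the stated rules", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  t <- (0:(epoch_len - 1)) / fs
  stim <- list(am_rate_hz = 1024, duration_s = 0.25, mode = "human")

  spec <- efr_spectrum(0.2 * sin(2 * pi * 1024 * t), stim, fs, "human")
  expect_equal(attr(spec, "bin_width_hz"), 4, tolerance = 1e-9)
  expect_equal(attr(spec, "window_s"), c(0.01, 0.26), tolerance = 1e-3)
  expect_equal(efr_amplitude(spec, 1024), 0.2, tolerance = 0.002)

  spec_g <- efr_spectrum(0.2 * sin(2 * pi * 1024 * t), stim, fs, "gerbil")
  expect_equal(attr(spec_g, "bin_width_hz"), fs / round(0.24 * fs),
    tolerance = 1e-9
  )

  # a tone midway between grid bins scallops by the Dirichlet-kernel factor
  df <- 4
  off_tone <- sin(2 * pi * (1024 + df / 2) * t)
  spec_off <- efr_spectrum(off_tone, stim, fs, "human")
  n <- round(0.25 * fs)
  scallop <- abs(sin(pi * 0.5) / (n * sin(pi * 0.5 / n)))
  got <- max(spec_off$amplitude[abs(spec_off$freq - 1024) <= df])
  expect_equal(got, scallop, tolerance = 0.01)
  expect_lt(got, 0.65)

  expect_error(
    efr_spectrum(numeric(100), stim, fs, "human"),
    "past the end"
  )
})

test_that("3-bin peak rule matches an exhaustive scan", {
  fs <- 8192
  epoch_len <- round(fs / 3.1)
  stim <- list(am_rate_hz = 512, duration_s = 0.25, mode = "human")
  set.seed(4)
  spec <- efr_spectrum(rnorm(epoch_len), stim, fs, "human")
  i0 <- which.min(abs(spec$freq - 512))
  expect_equal(
    efr_amplitude(spec, 512),
    max(spec$amplitude[(i0 - 1):(i0 + 1)])
  )
  # peak placed one bin above the modulation frequency is still captured
  df <- attr(spec, "bin_width_hz")
  t <- (0:(epoch_len - 1)) / fs
  spec_hi <- efr_spectrum(
    0.5 * sin(2 * pi * (512 + df) * t), stim, fs, "human"
  )
  expect_equal(efr_amplitude(spec_hi, 512), 0.5, tolerance = 0.01)
})

test_that("noise floor arithmetic and the 6 dB significance boundary", {
  # constructed spectrum: peak 0.1, all flanks 0.01
  freq <- 1024 + (-30:30) * 4
  amplitude <- rep(0.01, 61)
  amplitude[31] <- 0.1
  spec <- tibble::tibble(freq = freq, amplitude = amplitude)
  nf <- noise_floor(spec, 1024)
  expect_equal(nf, 0.01)
  snr_db <- 20 * log10(efr_amplitude(spec, 1024) / nf)
  expect_equal(snr_db, 20, tolerance = 1e-12)
  expect_true(snr_db >= 6)

  # amplitude ratio straddling 10^(6/20) flips the significance flag
  for (eps in c(-1e-4, 1e-4)) {
    ratio <- 10^(6 / 20) * (1 + eps)
    amp2 <- amplitude
    amp2[31] <- 0.01 * ratio
    spec2 <- tibble::tibble(freq = freq, amplitude = amp2)
    snr2 <- 20 * log10(efr_amplitude(spec2, 1024) / noise_floor(spec2, 1024))
    expect_equal(snr2 >= 6, eps > 0)
  }

  # insufficient flanking bins near the spectrum edge
  spec_edge <- tibble::tibble(freq = (0:4) * 4, amplitude = rep(0.01, 5))
  expect_error(noise_floor(spec_edge, 8), "Too few bins")
})

test_that("full pipeline recovers noiseless amplitudes at every rate", {
  cfg <- tiny_config()
  for (mode in c("human", "gerbil")) {
    rates <- if (mode == "human") c(40, 1024) else c(16, 724)
    for (rate in rates) {
      rec <- synthesize_efr_recording(
        NULL, rate, cfg,
        mode = mode, seed = 1, noise_scale = 0
      )
      res <- suppressWarnings(analyze_efr(rec))
      truth <- cfg$efr_amp_by_rate[[as.character(rate)]] +
        if (rate == 1024) cfg$efr_gain else 0
      expect_equal(res$amplitude, truth, tolerance = 0.01 * truth)
      expect_true(res$significant)
    }
  }
})

test_that("SNR is monotone in embedded amplitude at fixed noise", {
  cfg <- tiny_config(noise_spectrum_level = 0.1, n_epochs = 30)
  snrs <- vapply(c(0.3, 0.6, 1.2), function(gain) {
    cfg2 <- tiny_config(
      noise_spectrum_level = 0.1, n_epochs = 30, efr_gain = gain
    )
    rec <- synthesize_efr_recording(NULL, 1024, cfg2, seed = 77)
    analyze_efr(rec)$snr_db
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("noise-only recordings rarely clear the 6 dB criterion", {
  cfg0 <- tiny_config(
    n_epochs = 60,
    efr_amp_by_rate = c(
      "16" = 0, "40" = 0, "110" = 0, "256" = 0,
      "512" = 0, "724" = 0, "1024" = 0
    ),
    carrier_amp_uv = 0, efr_gain = 0
  )
  hits <- vapply(1:12, function(s) {
    rec <- synthesize_efr_recording(NULL, 512, cfg0, seed = s)
    analyze_efr(rec)$significant
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})
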