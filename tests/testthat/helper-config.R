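# Small configurations used across tests. Sizes are deliberately tiny;
# study-scale conditions are exercised in test-acceptance.R.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_per_group = c(YA = 3, MA = 3),
      fs_hz = 8192,
      n_epochs = 20,
      artifact_rate = 0,
      seed = 42L
    ),
    list(...)
  )
  do.call(cohort_config, args)
}

# direct discrete Fourier amplitude at a single frequency (independent of
# the package's spectrum path)
dft_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f * t))) / n
}

# brute-force averaged analysis window of a recording (no filtering):
# cross-polarity mean of the time-locked epochs, cut to [10, 260] ms
window_of <- function(rec) {
  fs <- rec$fs
  epoch_len <- round(fs / 3.1)
  idx <- outer(0:(epoch_len - 1L), rec$events$onset, "+")
  m <- matrix(rec$samples[idx], nrow = epoch_len)
  pol <- rec$events$polarity
  avg <- (rowMeans(m[, pol == "+", drop = FALSE]) +
    rowMeans(m[, pol == "-", drop = FALSE])) / 2
  start <- round(0.010 * fs)
  avg[start + seq_len(round(0.25 * fs))]
}
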