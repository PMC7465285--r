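test_that("band-pass filter passes the EEG band and kills line noise", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  x50 <- sin(2 * pi * 50 * t)
  x10 <- sin(2 * pi * 10 * t)
  mid <- seq(fs, length(t) - fs)  # ignore filter edge transients
  expect_lt(rms(bandpass_filter(x50)[mid]), 0.01 * rms(x50[mid]))
  expect_gt(rms(bandpass_filter(x10)[mid]), 0.95 * rms(x10[mid]))
  expect_equal(bandpass_filter(numeric(1000)), numeric(1000))
  expect_equal(length(bandpass_filter(x10)), length(x10))
  expect_error(bandpass_filter(c(1, NA, 3)), "non-finite")
  expect_error(bandpass_filter(x10, high_hz = 200), "Nyquist")
})

test_that("blink correction attenuates blink intervals and is a no-op without blinks", {
  cfg <- sim_config(seed = 21, blink_rate_hz = 0.3, artifact_rate_hz = 0,
                    lap_plan = data.frame(lap = 1, segment = "Easy",
                                          duration_s = 60))
  eeg <- bandpass_filter(synthesize_eeg(simulate_workload_trace(cfg), cfg))
  corrected <- remove_blinks(eeg)
  mask <- attr(corrected, "blink_mask")
  expect_true(any(mask))
  for (ch in c("AF3", "F3")) {
    expect_lt(var(corrected[ch, mask]), 0.5 * var(eeg[ch, mask]))
  }
  expect_equal(ncol(corrected), ncol(eeg))  # no samples dropped
  # blink-free input passes through unchanged
  cfg0 <- sim_config(seed = 22, blink_rate_hz = 0, artifact_rate_hz = 0,
                     lap_plan = data.frame(lap = 1, segment = "Easy",
                                           duration_s = 30))
  e0 <- bandpass_filter(synthesize_eeg(simulate_workload_trace(cfg0), cfg0))
  expect_equal(remove_blinks(e0), e0, ignore_attr = TRUE)
  expect_error(remove_blinks(e0, reference_channel = "Fp1"), "Fp1")
})

test_that("epoch grid follows the 2 s / 0.125 s convention", {
  x <- matrix(rnorm(15 * 2560), 15,
              dimnames = list(mwl_channels(), NULL))  # 10 s
  ep <- segment_epochs(x)
  expect_equal(ep$n_epochs, 65)                       # (10-2)/0.125 + 1
  expect_equal(ep$start_times_s[1], 0)
  expect_equal(ep$start_times_s[2], 0.125)
  expect_equal(diff(ep$start_times_s), rep(0.125, 64))
  expect_equal(segment_epochs(x[, 1:512])$n_epochs, 1) # exactly one epoch
  expect_error(segment_epochs(x[, 1:100]), "shorter")
  # count formula over a range of durations
  for (T in c(2, 2.125, 5.5, 30)) {
    n <- round(T * 256)
    expect_equal(segment_epochs(matrix(0, 1, n))$n_epochs,
                 floor((T - 2) / 0.125) + 1)
  }
})

test_that("the three artifact criteria fire exactly on constructed fixtures", {
  fs <- 256
  base <- matrix(0, 1, 512, dimnames = list("Fz", NULL))
  wrap <- function(m) reject_artifacts(segment_epochs(m))
  # amplitude: smooth 150 uV bump (no step, no trend by symmetry)
  bump <- base; bump[1, ] <- 75 * (1 - cos(2 * pi * (0:511) / 511))
  r <- wrap(bump)
  expect_false(r$keep[1]); expect_equal(r$reasons[[1]], "threshold")
  # trend: ramp rising 30 uV over 2 s (slope 15 uV/s)
  ramp <- base; ramp[1, ] <- seq(0, 30, length.out = 512)
  r <- wrap(ramp)
  expect_false(r$keep[1]); expect_equal(r$reasons[[1]], "trend")
  # step: 30 uV rectangular pulse (zero OLS slope, amplitude below 100)
  pulse <- base; pulse[1, 200:210] <- 30
  r <- wrap(pulse)
  expect_false(r$keep[1]); expect_equal(r$reasons[[1]], "step")
  # clean epoch is kept
  r <- wrap(base)
  expect_true(r$keep[1]); expect_length(r$reasons[[1]], 0)
  # rejection is per-epoch deterministic and order-independent: the same
  # epoch embedded in a longer recording gets the same verdict
  long <- cbind(base, bump, base)
  rl <- reject_artifacts(segment_epochs(long))
  bad_epochs <- which(!rl$keep)
  expect_true(length(bad_epochs) > 0)
  # epochs fully inside the flat leading segment are kept
  expect_true(all(rl$keep[rl$start_samp + 512 <= 512]))
})

test_that("rejected fraction responds to the artifact rate", {
  frac_at <- function(rate) {
    cfg <- sim_config(seed = 30, blink_rate_hz = 0,
                      artifact_rate_hz = rate,
                      lap_plan = data.frame(lap = 1, segment = "Easy",
                                            duration_s = 120))
    ses <- make_session(cfg)
    ep <- reject_artifacts(segment_epochs(bandpass_filter(ses$eeg)))
    attr(ep, "rejected_fraction")
  }
  f <- vapply(c(0, 0.05, 0.3), frac_at, numeric(1))
  expect_equal(f[1], 0)
  expect_true(all(diff(f) > 0))      # more artifacts, more rejection
  expect_gt(f[3], 0.05)              # the ~9% regime sits inside this range
  expect_lt(f[2], 0.09)
})

test_that("PSD is a calibrated Hann periodogram", {
  fs <- 256
  t <- (0:511) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1, dimnames = list("Pz", NULL))
  psd <- compute_psd(segment_epochs(x))
  expect_equal(psd$freqs_hz[which.max(psd$psd[1, 1, ])], 10)
  expect_equal(diff(psd$freqs_hz)[1], 0.5)
  expect_true(all(psd$psd >= 0))
  # zero signal: all-zero PSD
  expect_true(all(compute_psd(segment_epochs(x * 0))$psd == 0))
  # Parseval: sum(psd) * df equals the window-normalized time-domain power
  set.seed(3)
  y <- matrix(rnorm(512), 1, dimnames = list("Pz", NULL))
  pz <- compute_psd(segment_epochs(y), max_freq_hz = 128)
  w <- 0.5 * (1 - cos(2 * pi * (0:511) / 511))
  expect_equal(sum(pz$psd[1, 1, ]) * 0.5,
               sum((y[1, ] * w)^2) / sum(w^2), tolerance = 1e-10)
})

test_that("IAF estimation picks the resting alpha peak and derives the bands", {
  cfg <- sim_config(seed = 12, iaf_hz = 10.5)
  psd <- compute_psd(segment_epochs(bandpass_filter(make_resting(cfg))))
  iaf <- estimate_iaf(psd)
  expect_lte(abs(iaf$iaf_hz - 10.5), 0.5)
  bands <- iaf_bands(10)
  expect_equal(bands$theta, c(4, 8))
  expect_equal(bands$alpha, c(8, 12))
  expect_equal(bands$beta, c(12, 28))
  # a flat spectrum in 8-12 Hz has no unique peak
  flat <- psd
  flat$psd[] <- 1
  expect_error(estimate_iaf(flat), "tied maxima")
  # too-short resting recordings are refused
  short <- compute_psd(segment_epochs(bandpass_filter(
    make_resting(cfg, duration_s = 10))))
  expect_error(estimate_iaf(short), "shorter")
})

test_that("the 45-feature band matrix follows the canonical column map", {
  map <- band_feature_map()
  expect_equal(map$id[map$rhythm == "theta" & map$channel == "Fz"], 4)
  expect_equal(map$id[map$rhythm == "alpha" & map$channel == "P4"], 32)
  expect_equal(nrow(map), 45)
  # pure 10 Hz sinusoid with IAF 10: alpha dominates theta and beta
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  x <- matrix(sin(2 * pi * 10 * t), 15, length(t), byrow = TRUE,
              dimnames = list(mwl_channels(), NULL))
  psd <- compute_psd(segment_epochs(x))
  iaf <- structure(c(list(iaf_hz = 10), iaf_bands(10)), class = "mwl_iaf")
  b45 <- band_features_45(psd, iaf)
  expect_equal(ncol(b45), 45)
  expect_true(all(b45 >= 0))
  for (ch in c("Pz", "Fz")) {
    ids <- band_feature_map()
    a <- b45[1, ids$id[ids$channel == ch & ids$rhythm == "alpha"]]
    th <- b45[1, ids$id[ids$channel == ch & ids$rhythm == "theta"]]
    be <- b45[1, ids$id[ids$channel == ch & ids$rhythm == "beta"]]
    expect_gt(a, th); expect_gt(a, be)
  }
  # missing channel is an error
  psd_drop <- psd
  psd_drop$channels <- setdiff(psd$channels, "Oz")
  psd_drop$psd <- psd$psd[, psd_drop$channels, , drop = FALSE]
  expect_error(band_features_45(psd_drop, iaf), "Oz")
})

test_that("the ROI matrix has 187 columns with 99 eligible", {
  tc <- two_class_fixture()
  roi <- tc$roi
  expect_equal(ncol(roi$roi187), 187)   # 11 channels x 17 bins
  expect_equal(sum(roi$eligible99), 99) # 45 frontal theta + 54 parietal alpha
  expect_true(all(roi$roi187 >= 0))
  ci <- roi$col_info
  expect_equal(sum(ci$region == "frontal" & roi$eligible99), 45)
  expect_equal(sum(ci$region == "parietal" & roi$eligible99), 54)
  # the IAF-2 bin is eligible on both frontal and parietal channels
  edge <- tc$iaf$iaf_hz - 2
  expect_true(all(roi$eligible99[ci$freq_hz == edge]))
  expect_setequal(unique(ci$channel[ci$region == "frontal"]),
                  mwl_roi_channels("frontal"))
  expect_false("Fpz" %in% ci$channel)   # consumed by blink correction
  # 17 bins from IAF-6 to IAF+2 at 0.5 Hz per channel
  expect_equal(unname(table(ci$channel)["Pz"]), 17L)
})
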