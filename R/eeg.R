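#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth IIR band-pass (1--30 Hz by default), applied
#' forward and backward ([signal::filtfilt()]) so the net filter has zero
#' phase. Operates per channel on a `channels x samples` matrix or on a
#' vector.
#'
#' @param x Numeric vector or `channels x samples` matrix.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Filter order of each (low/high) Butterworth section.
#' @param fs Sampling rate in Hz.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, low_hz = 1, high_hz = 30, order = 4,
                            fs = 256) {
  check_finite(x, "signal")
  if (low_hz <= 0 || high_hz <= low_hz) stopf("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2) stopf("high cutoff must be below Nyquist (%g Hz)",
                               fs / 2)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  apply_rows(x, function(v) as.numeric(signal::filtfilt(bf, v)))
}

# apply f over rows of a matrix, or to a plain vector
apply_rows <- function(x, f) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f))
    dimnames(out) <- dimnames(x)
    out
  } else {
    f(x)
  }
}

#' Regression-based blink correction
#'
#' Blink intervals are detected on the low-pass-filtered reference channel
#' (amplitude criterion); within each interval the least-squares projection
#' of every channel onto the filtered reference is subtracted. Samples
#' outside blink intervals are untouched and no samples are dropped.
#'
#' @param eeg `channels x samples` matrix with channel rownames.
#' @param reference_channel Ocular reference channel, default `"Fpz"`.
#' @param fs Sampling rate in Hz.
#' @param threshold_uv Detection threshold on the low-passed reference.
#' @param lowpass_hz Cut-off of the detection low-pass filter.
#' @param pad_s Padding added around each detected interval.
#' @return Corrected matrix, same shape; attribute `"blink_mask"` holds the
#'   logical per-sample detection mask.
#' @export
remove_blinks <- function(eeg, reference_channel = "Fpz", fs = 256,
                          threshold_uv = 40, lowpass_hz = 4, pad_s = 0.1) {
  if (!is.matrix(eeg) || is.null(rownames(eeg)))
    stopf("eeg must be a matrix with channel rownames")
  if (!reference_channel %in% rownames(eeg))
    stopf("reference channel '%s' not present", reference_channel)
  bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
  ref <- as.numeric(signal::filtfilt(bf, eeg[reference_channel, ]))
  mask <- abs(ref) > threshold_uv
  if (any(mask)) {
    pad <- round(pad_s * fs)
    # dilate the mask by `pad` samples on both sides
    csum <- cumsum(mask)
    n <- length(mask)
    lo <- pmax(1, seq_len(n) - pad)
    hi <- pmin(n, seq_len(n) + pad)
    mask <- (csum[hi] - c(0, csum)[lo]) > 0
    denom <- sum(ref[mask]^2)
    if (denom > 0) {
      for (ch in rownames(eeg)) {
        beta <- sum(eeg[ch, mask] * ref[mask]) / denom
        eeg[ch, mask] <- eeg[ch, mask] - beta * ref[mask]
      }
    }
  }
  attr(eeg, "blink_mask") <- mask
  eeg
}

#' Segment a recording into overlapping epochs
#'
#' Epoch `k` (1-based) covers the half-open window
#' `[(k-1) * shift_s, (k-1) * shift_s + length_s)` seconds; with the default
#' 2 s length and 0.125 s shift, contiguous epochs overlap by 1.875 s and the
#' epoch count is `floor((T - length_s) / shift_s) + 1`.
#'
#' @param x Numeric vector or `channels x samples` matrix.
#' @param fs Sampling rate in Hz.
#' @param length_s Epoch length in seconds.
#' @param shift_s Shift between contiguous epochs in seconds.
#' @return An object of class `mwl_epochs` referencing the signal: fields
#'   `signal`, `fs`, `length_samp`, `shift_samp`, `start_samp` (0-based),
#'   `start_times_s`, `keep` (logical), `reasons` (list of character
#'   vectors), `n_epochs`.
#' @export
segment_epochs <- function(x, fs = 256, length_s = 2, shift_s = 0.125) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list("ch1", NULL))
  n <- ncol(x)
  len <- round(length_s * fs)
  step <- round(shift_s * fs)
  if (n < len) stopf("signal (%g s) shorter than one epoch (%g s)",
                     n / fs, length_s)
  n_epochs <- floor((n - len) / step) + 1
  start_samp <- (seq_len(n_epochs) - 1) * step
  structure(
    list(signal = x, fs = fs, length_s = length_s, shift_s = shift_s,
         length_samp = len, shift_samp = step, start_samp = start_samp,
         start_times_s = start_samp / fs, keep = rep(TRUE, n_epochs),
         reasons = vector("list", n_epochs), n_epochs = n_epochs),
    class = "mwl_epochs"
  )
}

#' @export
print.mwl_epochs <- function(x, ...) {
  cat(sprintf("<mwl_epochs> %d epochs of %g s (shift %g s), %d kept (%.1f%% rejected)\n",
              x$n_epochs, x$length_s, x$shift_s, sum(x$keep),
              100 * mean(!x$keep)))
  invisible(x)
}

# samples x epochs matrix of one channel's epochs
epoch_matrix <- function(epochs, channel, kept_only = FALSE) {
  starts <- epochs$start_samp
  if (kept_only) starts <- starts[epochs$keep]
  idx <- outer(seq_len(epochs$length_samp), starts, `+`)
  m <- matrix(epochs$signal[channel, idx], nrow = epochs$length_samp)
  m
}

#' Three-criteria artifact rejection
#'
#' An epoch is rejected when any channel violates any of: (i) threshold --
#' absolute amplitude exceeding `amp_uv` (100 uV); (ii) trend -- absolute
#' slope of the ordinary least-squares line over the epoch exceeding
#' `slope_uv_s` (10 uV/s); (iii) step -- maximum absolute sample-to-sample
#' difference exceeding `step_uv` (25 uV). The reasons for each rejection are
#' recorded per epoch.
#'
#' @param epochs An `mwl_epochs` object (signal in uV).
#' @param amp_uv,slope_uv_s,step_uv The three criteria thresholds.
#' @return The `mwl_epochs` object with updated `keep` and `reasons`;
#'   attribute `"rejected_fraction"` reports the rejected share.
#' @export
reject_artifacts <- function(epochs, amp_uv = 100, slope_uv_s = 10,
                             step_uv = 25) {
  stopifnot(inherits(epochs, "mwl_epochs"))
  ne <- epochs$n_epochs
  amp_bad <- trend_bad <- step_bad <- rep(FALSE, ne)
  tc <- (seq_len(epochs$length_samp) - 1) / epochs$fs
  tc <- tc - mean(tc)
  stc <- sum(tc^2)
  for (ch in rownames(epochs$signal)) {
    m <- epoch_matrix(epochs, ch)
    amp_bad <- amp_bad | (col_max(abs(m)) > amp_uv)
    slopes <- as.numeric(crossprod(tc, m)) / stc
    trend_bad <- trend_bad | (abs(slopes) > slope_uv_s)
    step_bad <- step_bad | (col_max(abs(diff(m))) > step_uv)
  }
  epochs$keep <- !(amp_bad | trend_bad | step_bad)
  epochs$reasons <- lapply(seq_len(ne), function(i) {
    c(if (amp_bad[i]) "threshold", if (trend_bad[i]) "trend",
      if (step_bad[i]) "step")
  })
  attr(epochs, "rejected_fraction") <- mean(!epochs$keep)
  epochs
}

#' Per-epoch power spectral density
#'
#' Hann-windowed periodogram of each kept epoch and channel via the FFT.
#' With 2 s epochs at 256 Hz the frequency resolution is 0.5 Hz. The PSD is
#' one-sided and normalized so that `sum(psd) * 0.5 Hz` equals the
#' window-weighted signal power (Parseval).
#'
#' @param epochs An `mwl_epochs` object.
#' @param max_freq_hz Highest retained bin (default 40 Hz covers the beta
#'   band up to IAF + 18 for any admissible IAF).
#' @return An object of class `mwl_psd`: `psd` array
#'   `(kept epochs) x channels x bins` in uV^2/Hz, `freqs_hz`, `channels`,
#'   `epoch_start_s`, `kept_index`.
#' @export
compute_psd <- function(epochs, max_freq_hz = 40) {
  stopifnot(inherits(epochs, "mwl_epochs"))
  len <- epochs$length_samp
  fs <- epochs$fs
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))  # Hann
  s2 <- sum(w^2)
  freqs <- (seq_len(len) - 1) * fs / len
  keep_bins <- freqs <= max_freq_hz & seq_len(len) <= len / 2 + 1
  fr <- freqs[keep_bins]
  chans <- rownames(epochs$signal)
  nk <- sum(epochs$keep)
  psd <- array(0, dim = c(nk, length(chans), length(fr)),
               dimnames = list(NULL, chans, NULL))
  for (ci in seq_along(chans)) {
    m <- epoch_matrix(epochs, chans[ci], kept_only = TRUE) * w
    p2 <- Mod(mvfft(m))^2 / (fs * s2)          # two-sided density
    p1 <- p2[keep_bins, , drop = FALSE]
    dbl <- fr > 0 & fr < fs / 2
    p1[dbl, ] <- 2 * p1[dbl, ]
    psd[, ci, ] <- t(p1)
  }
  structure(
    list(psd = psd, freqs_hz = fr, channels = chans,
         epoch_start_s = epochs$start_times_s[epochs$keep],
         kept_index = which(epochs$keep), fs = fs),
    class = "mwl_psd"
  )
}

#' Frequency bands anchored at the individual alpha frequency
#'
#' @param iaf_hz Alpha-peak frequency in Hz.
#' @return List with `theta = c(IAF-6, IAF-2)`, `alpha = c(IAF-2, IAF+2)`,
#'   `beta = c(IAF+2, IAF+18)` (Hz).
#' @export
#' @examples
#' iaf_bands(10) # theta 4-8, alpha 8-12, beta 12-28 Hz
iaf_bands <- function(iaf_hz) {
  list(theta = c(iaf_hz - 6, iaf_hz - 2),
       alpha = c(iaf_hz - 2, iaf_hz + 2),
       beta = c(iaf_hz + 2, iaf_hz + 18))
}

#' Estimate the individual alpha frequency
#'
#' The IAF is the frequency of the maximum of the epoch- and
#' channel-averaged PSD restricted to 8--12 Hz, computed on a closed-eyes
#' resting recording over posterior channels.
#'
#' @param resting_psd An `mwl_psd` from the resting recording (>= 30 s).
#' @param channels Channels to average (default posterior set).
#' @param min_duration_s Minimum resting span required.
#' @return An object of class `mwl_iaf`: `iaf_hz` plus the derived `theta`,
#'   `alpha`, `beta` band edges.
#' @export
estimate_iaf <- function(resting_psd,
                         channels = mwl_roi_channels("posterior"),
                         min_duration_s = 30) {
  stopifnot(inherits(resting_psd, "mwl_psd"))
  span <- max(resting_psd$epoch_start_s) + 2
  if (span < min_duration_s)
    stopf("resting recording (%.1f s) shorter than %g s", span,
          min_duration_s)
  missing <- setdiff(channels, resting_psd$channels)
  if (length(missing)) stopf("channels absent: %s",
                             paste(missing, collapse = ", "))
  spec <- apply(resting_psd$psd[, channels, , drop = FALSE], 3, mean)
  in_band <- resting_psd$freqs_hz >= 8 & resting_psd$freqs_hz <= 12
  s <- spec[in_band]
  f <- resting_psd$freqs_hz[in_band]
  top <- which(s == max(s))
  if (length(top) > 1)
    stopf("no unique alpha peak: tied maxima at %s Hz",
          paste(f[top], collapse = ", "))
  iaf <- f[top]
  structure(c(list(iaf_hz = iaf), iaf_bands(iaf)), class = "mwl_iaf")
}

#' @export
print.mwl_iaf <- function(x, ...) {
  cat(sprintf("<mwl_iaf> IAF %.1f Hz | theta %g-%g | alpha %g-%g | beta %g-%g Hz\n",
              x$iaf_hz, x$theta[1], x$theta[2], x$alpha[1], x$alpha[2],
              x$beta[1], x$beta[2]))
  invisible(x)
}

# mean PSD over [lo, hi] Hz, edges inclusive at the 0.5 Hz grid
band_mean <- function(psd, lo, hi) {
  sel <- psd$freqs_hz >= lo - 1e-9 & psd$freqs_hz <= hi + 1e-9
  if (!any(sel)) stopf("band %g-%g Hz outside computed PSD range", lo, hi)
  apply(psd$psd[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Feature ID map of the 45-column band matrix
#'
#' Three rhythms per channel, channels in montage order: feature 1 is theta
#' at Fpz, feature 4 theta at Fz, feature 32 alpha at P4, feature 45 beta at
#' O2.
#'
#' @return Data frame with columns `id`, `channel`, `rhythm`.
#' @export
band_feature_map <- function() {
  chans <- mwl_channels()
  data.frame(
    id = seq_len(45),
    channel = rep(chans, each = 3),
    rhythm = rep(c("theta", "alpha", "beta"), times = length(chans)),
    stringsAsFactors = FALSE
  )
}

#' The 45-column band-power feature matrix
#'
#' Per epoch and channel, the mean PSD over the IAF-anchored theta, alpha
#' and beta bands (band edges inclusive at the 0.5 Hz bins). Columns follow
#' [band_feature_map()].
#'
#' @param psd An `mwl_psd` with all 15 montage channels.
#' @param iaf An `mwl_iaf`.
#' @return `epochs x 45` matrix with columns `f1..f45`.
#' @export
band_features_45 <- function(psd, iaf) {
  stopifnot(inherits(psd, "mwl_psd"), inherits(iaf, "mwl_iaf"))
  missing <- setdiff(mwl_channels(), psd$channels)
  if (length(missing)) stopf("channels absent: %s",
                             paste(missing, collapse = ", "))
  bands <- list(theta = iaf$theta, alpha = iaf$alpha, beta = iaf$beta)
  bm <- lapply(bands, function(b) band_mean(psd, b[1], b[2]))
  map <- band_feature_map()
  out <- matrix(0, dim(psd$psd)[1], 45,
                dimnames = list(NULL, paste0("f", seq_len(45))))
  for (i in seq_len(45)) {
    out[, i] <- bm[[map$rhythm[i]]][, map$channel[i]]
  }
  attr(out, "feature_map") <- map
  out
}

#' The 187-bin region-of-interest PSD matrix and its 99 eligible columns
#'
#' Eleven ROI channels (5 frontal + 6 parietal) by 17 PSD bins at 0.5 Hz
#' from IAF-6 to IAF+2 Hz inclusive. The eligibility mask marks the columns
#' a workload discriminant may select: frontal channels restricted to the 9
#' theta bins (IAF-6..IAF-2, 45 columns) and parietal channels to the 9
#' alpha bins (IAF-2..IAF+2, 54 columns); the IAF-2 bin is eligible on both
#' sets as the shared band edge.
#'
#' @param psd An `mwl_psd` containing the ROI channels.
#' @param iaf An `mwl_iaf`.
#' @return List: `roi187` (`epochs x 187` matrix), `eligible99` (logical
#'   187-vector summing to 99), `col_info` (data frame `channel`, `freq_hz`,
#'   `region`).
#' @export
roi_psd_matrix_187 <- function(psd, iaf) {
  stopifnot(inherits(psd, "mwl_psd"), inherits(iaf, "mwl_iaf"))
  frontal <- mwl_roi_channels("frontal")
  parietal <- mwl_roi_channels("parietal")
  chans <- c(frontal, parietal)
  missing <- setdiff(chans, psd$channels)
  if (length(missing)) stopf("ROI channels absent: %s",
                             paste(missing, collapse = ", "))
  bins <- seq(iaf$iaf_hz - 6, iaf$iaf_hz + 2, by = 0.5)
  bin_idx <- match(bins, psd$freqs_hz)
  if (anyNA(bin_idx)) stopf("ROI bins missing from the PSD grid")
  col_info <- data.frame(
    channel = rep(chans, each = length(bins)),
    freq_hz = rep(bins, times = length(chans)),
    region = rep(c(rep("frontal", length(frontal)),
                   rep("parietal", length(parietal))), each = length(bins)),
    stringsAsFactors = FALSE
  )
  ne <- dim(psd$psd)[1]
  roi <- matrix(0, ne, nrow(col_info),
                dimnames = list(NULL, paste0(col_info$channel, "_",
                                             col_info$freq_hz)))
  for (j in seq_len(nrow(col_info))) {
    roi[, j] <- psd$psd[, col_info$channel[j],
                        bin_idx[match(col_info$freq_hz[j], bins)]]
  }
  eligible <- (col_info$region == "frontal" &
                 col_info$freq_hz <= iaf$iaf_hz - 2 + 1e-9) |
    (col_info$region == "parietal" &
       col_info$freq_hz >= iaf$iaf_hz - 2 - 1e-9)
  list(roi187 = roi, eligible99 = eligible, col_info = col_info)
}
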