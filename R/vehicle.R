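#' Resample 10 Hz vehicular signals to the 256 Hz EEG rate
#'
#' Rational 256/10 resampling implemented as a zero-phase polyphase
#' interpolator: a symmetric Kaiser-windowed sinc kernel (anti-aliasing
#' cut-off 4.8 Hz, just below the 5 Hz input Nyquist; half-width 1 s, i.e.
#' 10 input samples or 513 taps on the 256 Hz output grid) is evaluated at
#' the exact fractional offsets of each output sample and the weights are
#' renormalized per output sample, which preserves constants exactly. Edges
#' are handled by replication.
#'
#' @param x Numeric vector or `channels x samples` matrix at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @param cutoff_hz Anti-aliasing cut-off.
#' @param half_width_s Kernel half-width in seconds.
#' @param kaiser_beta Kaiser window shape parameter.
#' @return Resampled signal with `ceiling(n * fs_out / fs_in)` samples.
#' @export
resample_to_eeg_rate <- function(x, fs_in = 10, fs_out = 256,
                                 cutoff_hz = 4.8, half_width_s = 1,
                                 kaiser_beta = 6) {
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, nrow = 1)
  check_finite(x, "signal")
  n_in <- ncol(x)
  w_samp <- half_width_s * fs_in              # kernel half-width, input samples
  if (n_in < 2 * w_samp + 1)
    stopf("need at least %d samples (filter length) at %g Hz",
          2 * w_samp + 1, fs_in)
  n_out <- ceiling(n_in * fs_out / fs_in)
  centre <- (seq_len(n_out) - 1) * fs_in / fs_out   # 0-based input units
  offsets <- seq(-floor(w_samp), floor(w_samp) + 1)
  base <- floor(centre)
  # taps and weights: n_out x n_taps
  taps <- outer(base, offsets, `+`)
  u <- taps - centre                               # signed distance, input samples
  theta <- cutoff_hz / fs_in
  kern <- 2 * theta * sinc_fun(2 * theta * u) * kaiser_win(u / w_samp,
                                                           kaiser_beta)
  kern[abs(u) > w_samp] <- 0
  taps <- pmin(pmax(taps, 0), n_in - 1) + 1        # replicate edges, 1-based
  wsum <- rowSums(kern)
  out <- matrix(0, nrow(x), n_out, dimnames = list(rownames(x), NULL))
  for (r in seq_len(nrow(x))) {
    v <- matrix(x[r, taps], nrow = n_out)
    out[r, ] <- rowSums(v * kern) / wsum
  }
  if (vec_in) out[1, ] else out
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

kaiser_win <- function(u, beta) {
  w <- numeric(length(u))
  inside <- abs(u) <= 1
  w[inside] <- besselI(beta * sqrt(1 - u[inside]^2), 0) / besselI(beta, 0)
  dim(w) <- dim(u)
  w
}

#' Min-max feature scaling to [0, 1]
#'
#' Column-wise `(x - min) / (max - min)`. When `ranges` (learned on a
#' training split) are supplied they are applied and the result clipped to
#' `[0, 1]`; otherwise ranges are learned from the data and returned, and a
#' constant column is an error.
#'
#' @param m Numeric matrix (rows = observations).
#' @param ranges Optional `2 x p` matrix (rows: min, max) from a previous
#'   call.
#' @return List with `values` (scaled matrix) and `ranges` (the ranges
#'   used).
#' @export
minmax_normalize <- function(m, ranges = NULL) {
  m <- as.matrix(m)
  check_finite(m, "matrix")
  if (is.null(ranges)) {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    if (any(hi - lo == 0)) {
      bad <- which(hi - lo == 0)
      stopf("constant column(s) with no supplied range: %s",
            paste(bad, collapse = ", "))
    }
    ranges <- rbind(min = lo, max = hi)
    values <- sweep(sweep(m, 2, lo), 2, hi - lo, `/`)
  } else {
    if (ncol(ranges) != ncol(m)) stopf("ranges/matrix column mismatch")
    values <- sweep(sweep(m, 2, ranges[1, ]), 2,
                    ranges[2, ] - ranges[1, ], `/`)
    values[values < 0] <- 0
    values[values > 1] <- 1
  }
  dimnames(values) <- dimnames(m)
  list(values = values, ranges = ranges)
}

#' Epoch-align a 256 Hz signal to an EEG epoch grid
#'
#' Per kept epoch and channel, the arithmetic mean over the 512-sample
#' epoch window, producing one row per kept EEG epoch so that EEG and
#' vehicular feature rows refer to identical time windows.
#'
#' @param x `channels x samples` matrix (or vector) at the epoch grid's
#'   sampling rate, aligned to time 0.
#' @param epochs An `mwl_epochs` object defining the grid (typically after
#'   [reject_artifacts()]).
#' @return `kept epochs x channels` matrix.
#' @export
epoch_align <- function(x, epochs) {
  stopifnot(inherits(epochs, "mwl_epochs"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list("ch1", NULL))
  len <- epochs$length_samp
  starts <- epochs$start_samp[epochs$keep]
  if (max(starts) + len > ncol(x))
    stopf("epoch grid extends beyond the signal (%d > %d samples)",
          max(starts) + len, ncol(x))
  out <- matrix(0, length(starts), nrow(x),
                dimnames = list(NULL, rownames(x)))
  for (r in seq_len(nrow(x))) {
    cs <- c(0, cumsum(x[r, ]))
    out[, r] <- (cs[starts + len + 1] - cs[starts + 1]) / len
  }
  out
}
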