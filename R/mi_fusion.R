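# histogram utilities ------------------------------------------------------

hist_breaks <- function(x, bins, range = NULL) {
  lo <- if (is.null(range)) min(x) else range[1]
  hi <- if (is.null(range)) max(x) else range[2]
  if (hi <= lo) return(NULL)   # degenerate sample
  seq(lo, hi, length.out = bins + 1)
}

hist_bin <- function(x, breaks) {
  b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  b
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Estimate the entropy of a sample
#'
#' Shannon entropy in bits. The `histogram` estimator is the plug-in entropy
#' of the empirical distribution over `bins` equal-width bins spanning the
#' sample range (or the supplied `range`); the `knn` estimator is the
#' Kozachenko-Leonenko differential entropy (k-th nearest neighbour,
#' converted from nats to bits).
#'
#' @param x Numeric sample, `n >= 2`, finite.
#' @param estimator `"histogram"` or `"knn"`.
#' @param bins Number of equal-width bins (histogram).
#' @param k Neighbour order (knn).
#' @param range Optional `c(lo, hi)` fixing the histogram support.
#' @return Entropy in bits (differential entropy may be negative for the
#'   knn estimator).
#' @export
#' @examples
#' estimate_entropy(rep(c(1, 2, 3, 4), 25), bins = 4) # 2 bits
estimate_entropy <- function(x, estimator = c("histogram", "knn"),
                             bins = 16, k = 3, range = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) < 2) stopf("need at least 2 samples")
  check_finite(x, "samples")
  if (estimator == "histogram") {
    breaks <- hist_breaks(x, bins, range)
    if (is.null(breaks)) return(0)   # constant sample: no uncertainty
    entropy_from_counts(tabulate(hist_bin(x, breaks), nbins = bins))
  } else {
    .kl_entropy_1d_nats(as.numeric(x), as.integer(k)) / log(2)
  }
}

#' Estimate the conditional entropy H(Y | X)
#'
#' Computed as `H(X, Y) - H(X)` with both terms from the same estimator;
#' for the histogram path the marginal is the row sum of the joint binning,
#' which guarantees the plug-in inequality `H(Y|X) <= H(Y)`.
#'
#' @param x,y Paired numeric samples of equal length.
#' @inheritParams estimate_entropy
#' @param range_x,range_y Optional fixed histogram supports.
#' @return Conditional entropy in bits.
#' @export
estimate_conditional_entropy <- function(x, y,
                                         estimator = c("histogram", "knn"),
                                         bins = 16, k = 3, range_x = NULL,
                                         range_y = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 samples")
  check_finite(x, "x"); check_finite(y, "y")
  if (estimator == "histogram") {
    jt <- joint_counts(x, y, bins, range_x, range_y)
    entropy_from_counts(jt) - entropy_from_counts(rowSums(jt))
  } else {
    .kl_entropy_2d_nats(as.numeric(x), as.numeric(y), as.integer(k)) /
      log(2) -
      .kl_entropy_1d_nats(as.numeric(x), as.integer(k)) / log(2)
  }
}

joint_counts <- function(x, y, bins, range_x = NULL, range_y = NULL) {
  bx <- hist_breaks(x, bins, range_x)
  by <- hist_breaks(y, bins, range_y)
  ix <- if (is.null(bx)) rep(1L, length(x)) else hist_bin(x, bx)
  iy <- if (is.null(by)) rep(1L, length(y)) else hist_bin(y, by)
  m <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  m[] <- as.numeric(tab)
  m
}

#' Estimate the mutual information between two samples
#'
#' In bits. The `histogram` path computes the plug-in
#' `I = H(X) + H(Y) - H(X, Y)` from a joint equal-width binning (exactly
#' symmetric and always non-negative). The `knn` path is the
#' Kraskov-Stoegbauer-Grassberger estimator (k = 3 by default); small
#' negative estimates are clamped to zero and flagged via the `"clamped"`
#' attribute.
#'
#' @inheritParams estimate_conditional_entropy
#' @return Mutual information in bits.
#' @export
estimate_mutual_information <- function(x, y,
                                        estimator = c("histogram", "knn"),
                                        bins = 16, k = 3, range_x = NULL,
                                        range_y = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  check_finite(x, "x"); check_finite(y, "y")
  if (estimator == "histogram") {
    if (length(x) < 2) stopf("need at least 2 samples")
    jt <- joint_counts(x, y, bins, range_x, range_y)
    entropy_from_counts(rowSums(jt)) + entropy_from_counts(colSums(jt)) -
      entropy_from_counts(jt)
  } else {
    if (length(x) < k + 1) stopf("need at least k + 1 samples for KSG")
    mi <- .ksg_mi_nats(as.numeric(x), as.numeric(y), as.integer(k)) / log(2)
    clamped <- mi < 0
    mi <- max(0, mi)
    attr(mi, "clamped") <- clamped
    mi
  }
}

#' Empirical bias floor of a mutual-information estimate
#'
#' Plug-in MI estimates on finite samples are positive even under
#' independence, and temporal autocorrelation (e.g. heavily overlapping
#' epochs) inflates that floor well beyond the i.i.d. value. This helper
#' measures the floor empirically with circular-shift surrogates: `y` is
#' rotated by large offsets, which destroys the pairing while preserving
#' both marginals and both autocorrelation structures.
#'
#' @inheritParams estimate_mutual_information
#' @param n_shifts Number of circular shifts (spread over the series).
#' @return Median surrogate MI in bits; attribute `"surrogates"` holds all
#'   values.
#' @export
mi_bias_floor <- function(x, y, estimator = c("histogram", "knn"),
                          bins = 16, k = 3, range_x = NULL, range_y = NULL,
                          n_shifts = 7) {
  n <- length(x)
  shifts <- round(seq(0.2, 0.8, length.out = n_shifts) * n)
  vals <- vapply(shifts, function(s) {
    ys <- y[((seq_len(n) - 1 + s) %% n) + 1]
    as.numeric(estimate_mutual_information(x, ys, estimator = estimator,
                                           bins = bins, k = k,
                                           range_x = range_x,
                                           range_y = range_y))
  }, numeric(1))
  out <- median(vals)
  attr(out, "surrogates") <- vals
  out
}

#' Build the mutual-information template
#'
#' Estimates the pairwise mutual information between every vehicular feature
#' (rows) and every EEG band feature (columns), both expected min-max scaled
#' to `[0, 1]` on row-aligned kept epochs, and summarizes each row by its
#' norm. The row norms are the deployable weights: they quantify how much
#' information each vehicular feature shares with the EEG workload
#' signature.
#'
#' @param vehicular `epochs x p` scaled vehicular feature matrix.
#' @param eeg45 `epochs x q` scaled EEG band feature matrix (row-aligned).
#' @param estimator,bins,k Passed to [estimate_mutual_information()];
#'   histogram supports are fixed to `[0, 1]`.
#' @param norm `"l2"` (Euclidean, default) or `"l1"` row norm.
#' @param veh_ranges Optional scaling ranges (from [minmax_normalize()]) to
#'   carry along for deployment.
#' @return An object of class `mi_template`: `mi_matrix` (`p x q`, bits),
#'   `row_norms` (p-vector), `estimator_meta`, `veh_ranges`.
#' @export
build_template <- function(vehicular, eeg45, estimator = "histogram",
                           bins = 16, k = 3, norm = c("l2", "l1"),
                           veh_ranges = NULL) {
  norm <- match.arg(norm)
  vehicular <- as.matrix(vehicular)
  eeg45 <- as.matrix(eeg45)
  if (nrow(vehicular) != nrow(eeg45))
    stopf("row misalignment: %d vehicular vs %d EEG epochs",
          nrow(vehicular), nrow(eeg45))
  if (min(vehicular) < -1e-6 || max(vehicular) > 1 + 1e-6 ||
      min(eeg45) < -1e-6 || max(eeg45) > 1 + 1e-6)
    warning("inputs are expected min-max scaled to [0, 1]")
  p <- ncol(vehicular); q <- ncol(eeg45)
  mi <- matrix(0, p, q,
               dimnames = list(colnames(vehicular), colnames(eeg45)))
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      mi[i, j] <- as.numeric(estimate_mutual_information(
        vehicular[, i], eeg45[, j], estimator = estimator, bins = bins,
        k = k, range_x = c(0, 1), range_y = c(0, 1)))
    }
  }
  rn <- if (norm == "l2") sqrt(rowSums(mi^2)) else rowSums(abs(mi))
  structure(
    list(mi_matrix = mi, row_norms = rn,
         estimator_meta = list(estimator = estimator, bins = bins, k = k,
                               norm = norm, n = nrow(vehicular)),
         veh_ranges = veh_ranges),
    class = "mi_template"
  )
}

#' @export
print.mi_template <- function(x, ...) {
  cat(sprintf("<mi_template> %d x %d MI matrix (%s, n=%d); row norms: %s\n",
              nrow(x$mi_matrix), ncol(x$mi_matrix),
              x$estimator_meta$estimator, x$estimator_meta$n,
              paste(sprintf("%.3f", x$row_norms), collapse = ", ")))
  invisible(x)
}

#' Project vehicular features through an MI template
#'
#' Produces the MI-based feature matrix from vehicular features alone:
#' each scaled vehicular feature is weighted by its template row norm
#' (elementwise product), keeping one feature per vehicular channel. A
#' scalar dot-product variant (`mode = "dot"`) collapsing each epoch to a
#' single weighted sum is provided for comparison.
#'
#' @param vehicular_new `epochs x p` vehicular feature matrix scaled with
#'   the template's training ranges.
#' @param template An `mi_template`.
#' @param mode `"elementwise"` (default) or `"dot"`.
#' @return `epochs x p` matrix (`epochs x 1` for `"dot"`).
#' @export
project_features <- function(vehicular_new, template,
                             mode = c("elementwise", "dot")) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "mi_template"))
  vehicular_new <- as.matrix(vehicular_new)
  if (ncol(vehicular_new) != length(template$row_norms))
    stopf("vehicular matrix has %d columns, template expects %d",
          ncol(vehicular_new), length(template$row_norms))
  if (mode == "elementwise") {
    sweep(vehicular_new, 2, template$row_norms, `*`)
  } else {
    vehicular_new %*% matrix(template$row_norms, ncol = 1)
  }
}

#' Serialize an MI template to JSON
#' @param template An `mi_template`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "mi_template"))
  obj <- list(mi_matrix = template$mi_matrix,
              row_norms = template$row_norms,
              estimator_meta = template$estimator_meta,
              veh_ranges = template$veh_ranges)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read an MI template written by [write_template()]
#' @param path JSON file.
#' @return An `mi_template`.
#' @export
read_template <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(
    list(mi_matrix = as.matrix(obj$mi_matrix),
         row_norms = as.numeric(obj$row_norms),
         estimator_meta = obj$estimator_meta,
         veh_ranges = if (is.null(obj$veh_ranges)) NULL
                      else as.matrix(obj$veh_ranges)),
    class = "mi_template"
  )
}
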