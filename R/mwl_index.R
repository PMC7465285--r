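# ordinary least squares RSS of y on [1, X]; returns NULL on rank deficiency
ols_rss <- function(X, y) {
  fit <- lm.fit(cbind(1, X), y)
  if (fit$rank < ncol(X) + 1) return(NULL)
  sum(fit$residuals^2)
}

#' Train the stepwise linear discriminant workload index
#'
#' Forward-backward stepwise least-squares selection over the eligible
#' region-of-interest PSD columns against 0/1 class labels (Easy = 0,
#' Hard = 1), the classical SWLDA formulation: at each step the candidate
#' minimizing the residual sum of squares is added if its partial-F p-value
#' is at most `p_enter`, then any included feature whose partial-F p-value
#' is at least `p_remove` is dropped. Selection stops automatically when no
#' candidate qualifies or (with `bic_guard`) when the Bayesian information
#' criterion would not improve. Final weights and bias come from the least
#' squares fit on the selected columns, so the discriminant is centred on 0
#' for the easy class and 1 for the hard class.
#'
#' @param roi `epochs x p` feature matrix (training epochs).
#' @param labels 0/1 vector (or 2-level factor, second level = 1).
#' @param eligible Logical p-vector (or integer indices) of selectable
#'   columns.
#' @param p_enter,p_remove Partial-F entry/removal thresholds.
#' @param bic_guard Require each addition to improve the BIC.
#' @param max_steps Hard cap on additions.
#' @return An object of class `asswlda`: `selected` (column indices, in
#'   selection order), `weights`, `bias`, `p` (total column count),
#'   `training_meta` (stopping trace data frame).
#' @export
train_asswlda <- function(roi, labels, eligible = NULL, p_enter = 0.05,
                          p_remove = 0.10, bic_guard = TRUE,
                          max_steps = 30) {
  roi <- as.matrix(roi)
  if (is.factor(labels)) labels <- as.numeric(labels) - 1
  labels <- as.numeric(labels)
  if (length(labels) != nrow(roi)) stopf("labels/rows mismatch")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  p <- ncol(roi)
  eligible <- eligible %||% rep(TRUE, p)
  if (!is.logical(eligible)) {
    el <- rep(FALSE, p); el[eligible] <- TRUE; eligible <- el
  }
  if (!any(eligible)) stopf("no eligible features")
  n <- nrow(roi)
  selected <- integer(0)
  rss_cur <- sum((labels - mean(labels))^2)
  bic_cur <- n * log(rss_cur / n) + 1 * log(n)
  trace <- list()
  partial_p <- function(rss0, rss1, k1) {
    # F-test for one added coefficient; k1 = number of model columns incl.
    # intercept after addition
    df2 <- n - k1
    if (df2 <= 0 || !is.finite(rss1)) return(1)
    if (rss1 <= 0) return(0)
    f <- (rss0 - rss1) / (rss1 / df2)
    if (!is.finite(f) || f < 0) return(1)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  repeat {
    if (length(selected) >= max_steps) break
    cand <- which(eligible)
    cand <- setdiff(cand, selected)
    if (!length(cand)) break
    rss_c <- vapply(cand, function(j) {
      r <- ols_rss(roi[, c(selected, j), drop = FALSE], labels)
      if (is.null(r)) Inf else r
    }, numeric(1))
    best <- which.min(rss_c)
    p_best <- partial_p(rss_cur, rss_c[best], length(selected) + 2)
    bic_new <- n * log(max(rss_c[best], 1e-300) / n) +
      (length(selected) + 2) * log(n)
    if (p_best > p_enter || (bic_guard && bic_new >= bic_cur)) {
      trace[[length(trace) + 1]] <- data.frame(
        action = "stop", feature = NA_integer_, p_value = p_best,
        rss = rss_cur, bic = bic_cur)
      break
    }
    selected <- c(selected, cand[best])
    rss_cur <- rss_c[best]
    bic_cur <- bic_new
    trace[[length(trace) + 1]] <- data.frame(
      action = "add", feature = cand[best], p_value = p_best,
      rss = rss_cur, bic = bic_cur)
    # backward pass: drop features that no longer pull their weight
    repeat {
      if (length(selected) < 2) break
      p_drop <- vapply(seq_along(selected), function(i) {
        r0 <- ols_rss(roi[, selected[-i], drop = FALSE], labels)
        if (is.null(r0)) return(0)
        partial_p(r0, rss_cur, length(selected) + 1)
      }, numeric(1))
      worst <- which.max(p_drop)
      if (p_drop[worst] < p_remove) break
      dropped <- selected[worst]
      selected <- selected[-worst]
      rss_cur <- ols_rss(roi[, selected, drop = FALSE], labels)
      bic_cur <- n * log(max(rss_cur, 1e-300) / n) +
        (length(selected) + 1) * log(n)
      trace[[length(trace) + 1]] <- data.frame(
        action = "remove", feature = dropped, p_value = p_drop[worst],
        rss = rss_cur, bic = bic_cur)
    }
    if (rss_cur <= 1e-12) break   # perfect separation
  }
  if (!length(selected)) {
    # nothing passed the entry test; fall back to the single best candidate
    # so the model is usable (|selected| >= 1), flagged in the trace
    cand <- which(eligible)
    rss_c <- vapply(cand, function(j) {
      r <- ols_rss(roi[, j, drop = FALSE], labels)
      if (is.null(r)) Inf else r
    }, numeric(1))
    selected <- cand[which.min(rss_c)]
    trace[[length(trace) + 1]] <- data.frame(
      action = "fallback_single", feature = selected, p_value = NA_real_,
      rss = min(rss_c), bic = NA_real_)
  }
  fit <- lm.fit(cbind(1, roi[, selected, drop = FALSE]), labels)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(
    list(selected = selected, weights = unname(coefs[-1]),
         bias = unname(coefs[1]), p = p,
         training_meta = do.call(rbind, trace)),
    class = "asswlda"
  )
}

#' @export
print.asswlda <- function(x, ...) {
  cat(sprintf("<asswlda> %d selected feature(s) of %d columns; bias %.3f\n",
              length(x$selected), x$p, x$bias))
  invisible(x)
}

#' Apply a trained workload discriminant
#'
#' `y(t) = sum_i w_i f_i(t) + b` over the selected features. The output
#' tends to lie near 0 for easy-condition epochs and near 1 for hard ones
#' but is not clipped.
#'
#' @param model An `asswlda` model.
#' @param roi `epochs x p` feature matrix with the same column count as the
#'   training matrix.
#' @return Numeric vector of per-epoch discriminant values.
#' @export
apply_discriminant <- function(model, roi) {
  stopifnot(inherits(model, "asswlda"))
  roi <- as.matrix(roi)
  if (ncol(roi) != model$p)
    stopf("feature matrix has %d columns, model expects %d", ncol(roi),
          model$p)
  as.numeric(roi[, model$selected, drop = FALSE] %*% model$weights +
               model$bias)
}

#' Smooth the discriminant into the workload score
#'
#' Trailing (causal) moving average spanning `window_s` seconds of epochs
#' (64 epochs at the default 0.125 s shift); the first values use the
#' available prefix (expanding window).
#'
#' @param y Per-epoch discriminant values at uniform epoch spacing.
#' @param shift_s Epoch shift in seconds.
#' @param window_s Averaging window in seconds.
#' @return Numeric vector, same length as `y`.
#' @export
smooth_mwl_score <- function(y, shift_s = 0.125, window_s = 8) {
  if (!length(y)) stopf("empty score series")
  w <- max(1L, round(window_s / shift_s))
  cs <- cumsum(y)
  i <- seq_along(y)
  lo <- pmax(0L, i - w)
  (cs[i] - c(0, cs)[lo + 1]) / (i - lo)
}

#' Serialize a workload index model to JSON
#' @param model An `asswlda` model.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_asswlda <- function(model, path) {
  stopifnot(inherits(model, "asswlda"))
  obj <- list(selected = model$selected, weights = model$weights,
              bias = model$bias, p = model$p)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a workload index model written by [write_asswlda()]
#' @param path JSON file.
#' @return An `asswlda` model.
#' @export
read_asswlda <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(selected = as.integer(obj$selected),
                 weights = as.numeric(obj$weights),
                 bias = as.numeric(obj$bias), p = as.integer(obj$p),
                 training_meta = NULL),
            class = "asswlda")
}
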