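#' Cross-validation and holdout splits
#'
#' `kfold10`: ten disjoint near-equal random folds. `loo_subject`: one fold
#' per subject (all of a subject's rows are left out together).
#' `holdout10`: a stratified 10% holdout preserving class proportions within
#' one sample per class.
#'
#' @param n Number of rows.
#' @param scheme `"kfold10"`, `"loo_subject"` or `"holdout10"`.
#' @param seed Integer seed.
#' @param labels Class labels (required for `holdout10`).
#' @param subjects Subject identifiers (required for `loo_subject`).
#' @return For CV schemes, a list of test-index vectors; for `holdout10`, a
#'   list with elements `holdout` and `rest`.
#' @export
split_scheme <- function(n, scheme = c("kfold10", "loo_subject",
                                       "holdout10"),
                         seed = 1, labels = NULL, subjects = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    kfold10 = with_seed(seed, {
      # assign shuffled rows round-robin: folds differ by at most 1 in size
      ord <- sample.int(n)
      unname(split(ord, rep(seq_len(10), length.out = n)))
    }),
    loo_subject = {
      if (is.null(subjects)) stopf("loo_subject requires subject IDs")
      if (length(subjects) != n) stopf("subjects/rows mismatch")
      unname(split(seq_len(n), subjects))
    },
    holdout10 = {
      if (is.null(labels)) stopf("holdout10 requires labels")
      if (length(labels) != n) stopf("labels/rows mismatch")
      hold <- with_seed(seed, {
        unlist(lapply(split(seq_len(n), labels), function(idx) {
          k <- round(0.10 * length(idx))
          sample(idx, k)
        }), use.names = FALSE)
      })
      hold <- sort(hold)
      list(holdout = hold, rest = setdiff(seq_len(n), hold))
    }
  )
}

#' Regression error metrics
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return List with `mae` (mean absolute error) and `mse` (mean squared
#'   error).
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (!length(y_true)) stopf("empty input")
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  d <- y_true - y_pred
  list(mae = mean(abs(d)), mse = mean(d^2))
}

#' Confusion matrix from predicted and true labels
#'
#' @param truth,pred Label vectors.
#' @param positive The positive class label.
#' @return An object of class `mwl_confusion` with counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion_matrix <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (!positive %in% c(truth, pred)) stopf("positive class '%s' not found",
                                           positive)
  structure(
    list(tp = sum(truth == positive & pred == positive),
         fn = sum(truth == positive & pred != positive),
         fp = sum(truth != positive & pred == positive),
         tn = sum(truth != positive & pred != positive),
         positive = positive),
    class = "mwl_confusion"
  )
}

#' Confusion matrix from raw counts
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param positive Positive class label (informational).
#' @return An object of class `mwl_confusion`.
#' @export
confusion_counts <- function(tp, fn, fp, tn, positive = "positive") {
  if (any(c(tp, fn, fp, tn) < 0)) stopf("counts must be non-negative")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
            class = "mwl_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity (= recall), specificity, precision, F1, accuracy and
#' balanced accuracy. Ratios with a zero denominator are reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm An `mwl_confusion`.
#' @return Named list of metrics at full precision.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "mwl_confusion"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stopf("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec,
       recall = sens, f1 = f1,
       accuracy = (cm$tp + cm$tn) / total,
       balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                           else (sens + spec) / 2)
}

#' ROC curve and AUC
#'
#' The AUC is the normalized Mann-Whitney statistic (probability that a
#' random positive outscores a random negative, ties counted half), computed
#' from ranks; the curve lists (FPR, TPR) at every distinct threshold.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Class labels.
#' @param positive The positive class.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = levels(as.factor(labels))[2]) {
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(threshold = c(Inf, s[last]),
                      fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  list(auc = auc, curve = curve)
}

# exact null pmf of the positive-rank sum for doubled ranks 2*r (integer),
# by convolution; returns P(W2 = 0..sum(2r)) where W2 = 2*W+
signed_rank_null_pmf <- function(ranks2) {
  total <- sum(ranks2)
  pmf <- numeric(total + 1)
  pmf[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1 - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Wilcoxon signed-rank test
#'
#' Paired test on `x - y`. Zero differences are dropped; ranks of the
#' absolute differences use midranks for ties. For `n <= 12` pairs (or
#' `mode = "exact"`) the null distribution of the positive-rank sum is
#' enumerated exactly; otherwise a normal approximation with tie correction
#' and continuity correction is used. The reported statistic is
#' `min(W+, W-)` for the two-sided test and `W+` (the positive-rank sum)
#' for `alternative = "greater"` (median of `x - y` greater than zero).
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"two_sided"` or `"greater"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic`, `p`, `n` (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two_sided", "greater"),
                                 mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) != length(y)) stopf("length mismatch")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  exact <- mode == "exact" || (mode == "auto" && n <= 12)
  if (exact) {
    pmf <- signed_rank_null_pmf(round(2 * r))
    w2 <- round(2 * w_pos)
    p_le <- sum(pmf[seq_len(w2 + 1)])
    p_ge <- sum(pmf[(w2 + 1):length(pmf)])
    p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sig <- sqrt(sig2)
    if (alternative == "greater") {
      z <- (w_pos - mu - 0.5) / sig
      p <- pnorm(z, lower.tail = FALSE)
    } else {
      z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sig
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  statistic <- if (alternative == "greater") w_pos else min(w_pos, w_neg)
  list(statistic = statistic, p = p, n = n, method = method)
}

# placement values: per positive case, the fraction of negatives it
# outscores (ties half); and symmetrically per negative case
placements <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  v10 <- vapply(sp, function(s) (sum(s > sn) + 0.5 * sum(s == sn)) /
                  length(sn), numeric(1))
  v01 <- vapply(sn, function(s) (sum(sp > s) + 0.5 * sum(sp == s)) /
                  length(sp), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same labelled cases via
#' the placement-value (structural component) covariance estimate. The
#' one-sided alternative is that the first AUC exceeds the second. 95%
#' confidence intervals for each AUC use its DeLong variance.
#'
#' @param scores_a,scores_b Score vectors over the same cases.
#' @param labels Class labels shared by both.
#' @param positive The positive class.
#' @param alternative `"greater"` (default, AUC_a > AUC_b) or
#'   `"two_sided"`.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `ci95_a`, `ci95_b`.
#' @export
delong_auc_test <- function(scores_a, scores_b, labels,
                            positive = levels(as.factor(labels))[2],
                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) stopf("length mismatch")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stopf("both classes must be present")
  pa <- placements(scores_a, pos)
  pb <- placements(scores_b, pos)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- if (var_diff <= 0) 0 else (auc_a - auc_b) / sqrt(var_diff)
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
       else min(1, 2 * pnorm(-abs(z)))
  ci <- function(auc, i) {
    se <- sqrt(s10[i, i] / m + s01[i, i] / n)
    z975 <- stats::qnorm(0.975)
    c(max(0, auc - z975 * se), min(1, auc + z975 * se))
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = p,
       ci95_a = ci(auc_a, 1), ci95_b = ci(auc_b, 2))
}

#' Run a full evaluation experiment
#'
#' Trains and evaluates every model specification under a validation
#' scheme. Numeric targets give a regression experiment (per-fold MAE/MSE);
#' factor targets give classification (per-fold confusion metrics and AUC,
#' predicted class at score threshold 0.5 of the positive-class score, or 0
#' for SVM decision values). Deterministic given `seed`.
#'
#' @param features Numeric feature matrix.
#' @param targets Numeric vector (regression) or 2-level factor
#'   (classification).
#' @param specs List of [model_spec()] objects.
#' @param scheme `"kfold10"`, `"loo_subject"` or `"holdout10"`.
#' @param seed Integer seed.
#' @param subjects Subject IDs for `loo_subject`.
#' @param positive Positive class (classification); defaults to the second
#'   factor level.
#' @return An object of class `mwl_eval_report`: per-model fold metric data
#'   frames, pooled scores/labels, AUCs, and a `summary` data frame with
#'   min/max/mean of each metric per model.
#' @export
run_experiment <- function(features, targets, specs,
                           scheme = c("kfold10", "loo_subject",
                                      "holdout10"),
                           seed = 1, subjects = NULL, positive = NULL) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  n <- nrow(features)
  classify <- is.factor(targets) || is.character(targets)
  if (classify) {
    targets <- as.factor(targets)
    if (is.null(positive)) positive <- levels(targets)[2]
    # relevel so the positive class is the second level (score orientation)
    targets <- stats::relevel(targets, ref = setdiff(levels(targets),
                                                     positive)[1])
  }
  if (length(targets) != n) stopf("features/targets mismatch")
  folds <- if (scheme == "holdout10") {
    sp <- split_scheme(n, "holdout10", seed = seed, labels = targets)
    list(sp$holdout)   # single evaluation fold; train on the rest
  } else {
    split_scheme(n, scheme, seed = seed, labels = targets,
                 subjects = subjects)
  }
  models <- list()
  for (spec in specs) {
    if (classify && spec$task != "classification")
      stopf("model %s is not a classification model", spec$name)
    if (!classify && spec$task != "regression")
      stopf("model %s is not a regression model", spec$name)
    fold_rows <- list()
    all_scores <- numeric(0)
    all_truth <- character(0)
    for (fi in seq_along(folds)) {
      test <- folds[[fi]]
      train <- setdiff(seq_len(n), test)
      fit <- build_model(spec, features[train, , drop = FALSE],
                         targets[train],
                         seed = child_seed(seed, paste0(spec$name, fi)))
      pred <- predict(fit, features[test, , drop = FALSE])
      if (classify) {
        thr <- if (spec$name == "SVM") 0 else 0.5
        pred_lab <- ifelse(pred > thr, positive,
                           setdiff(levels(targets), positive))
        cm <- confusion_matrix(targets[test], pred_lab, positive)
        met <- classification_metrics(cm)
        auc <- if (length(unique(targets[test])) == 2)
          roc_auc(pred, targets[test], positive)$auc else NA_real_
        fold_rows[[fi]] <- data.frame(fold = fi, as.data.frame(met),
                                      auc = auc)
        all_scores <- c(all_scores, pred)
        all_truth <- c(all_truth, as.character(targets[test]))
      } else {
        met <- regression_metrics(targets[test], pred)
        fold_rows[[fi]] <- data.frame(fold = fi, mae = met$mae,
                                      mse = met$mse)
      }
    }
    fold_df <- do.call(rbind, fold_rows)
    entry <- list(folds = fold_df)
    if (classify) {
      entry$pooled_scores <- all_scores
      entry$pooled_truth <- all_truth
      entry$roc <- roc_auc(all_scores, all_truth, positive)
    }
    models[[spec$name]] <- entry
  }
  metric_cols <- setdiff(colnames(models[[1]]$folds), "fold")
  summary <- do.call(rbind, lapply(names(models), function(nm) {
    fd <- models[[nm]]$folds
    do.call(rbind, lapply(metric_cols, function(mc) {
      v <- fd[[mc]]
      data.frame(model = nm, metric = mc, min = min(v, na.rm = TRUE),
                 max = max(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE))
    }))
  }))
  structure(list(models = models, summary = summary, scheme = scheme,
                 seed = seed,
                 positive = if (classify) positive else NULL),
            class = "mwl_eval_report")
}

#' @export
print.mwl_eval_report <- function(x, ...) {
  cat(sprintf("<mwl_eval_report> scheme=%s seed=%d models=%s\n", x$scheme,
              x$seed, paste(names(x$models), collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Published holdout confusion tables
#'
#' The printed holdout-set confusion counts and derived metrics of the two
#' reference classification tasks (Low/High workload over 1710 observations
#' and Car/Pedestrian events over 738 observations) for the four
#' classifiers under EEG-based and MI-based feature sets. Used to verify
#' that [classification_metrics()] reproduces every derived table cell from
#' the raw counts.
#'
#' @return Data frame with columns `task`, `features`, `model`, the counts
#'   `tp`, `fn`, `fp`, `tn`, and the printed two-decimal metrics.
#' @export
mwl_confusion_tables <- function() {
  path <- system.file("extdata", "holdout_confusion_tables.csv",
                      package = "miwl")
  read.csv(path, stringsAsFactors = FALSE)
}
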