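#' Model specification
#'
#' The five model families of the evaluation harness with their default
#' hyperparameters: linear regression (LnR), logistic regression (LgR,
#' balanced class weights, L2 regularization), multilayer perceptron (MLP,
#' hidden layers 32/16/4, ReLU, Adam, batch size 128), random forest (RF,
#' 100 bootstrapped trees of maximum depth 5) and support vector machine
#' (SVM, RBF kernel, degree 3, C = 1.0, epsilon = 0.2).
#'
#' @param name One of `"LnR"`, `"LgR"`, `"MLP"`, `"RF"`, `"SVM"`.
#' @param task `"regression"` or `"classification"`.
#' @param ... Overrides of the default hyperparameters.
#' @return An object of class `mwl_model_spec`.
#' @export
model_spec <- function(name, task = c("regression", "classification"), ...) {
  task <- match.arg(task)
  known <- c("LnR", "LgR", "MLP", "RF", "SVM")
  if (!name %in% known)
    stopf("unknown model '%s' (use one of %s)", name,
          paste(known, collapse = ", "))
  if (name == "LnR" && task != "regression")
    stopf("LnR is a regression model")
  if (name == "LgR" && task != "classification")
    stopf("LgR is a classification model")
  defaults <- switch(name,
    LnR = list(fit_intercept = TRUE),
    LgR = list(fit_intercept = TRUE, class_weight = "balanced",
               penalty = "l2"),
    MLP = list(hidden = c(32, 16, 4), activation = "relu",
               optimizer = "adam", batch_size = 128, epochs = 500,
               lr = 1e-3, tol = 1e-4),
    RF  = list(n_estimators = 100, max_depth = 5, bootstrap = TRUE),
    SVM = list(kernel = "radial", degree = 3, C = 1.0, epsilon = 0.2)
  )
  over <- list(...)
  defaults[names(over)] <- over
  structure(list(name = name, task = task, params = defaults),
            class = "mwl_model_spec")
}

#' Fit a model from its specification
#'
#' Dispatches to the backing implementation (stats::lm for LnR, glmnet
#' ridge for LgR, the package's Adam-trained MLP, ranger for RF, e1071 for
#' SVM), seeded for reproducibility.
#'
#' @param spec An [model_spec()].
#' @param x Numeric feature matrix.
#' @param y Numeric target (regression) or 2-level factor
#'   (classification; second level is the positive class).
#' @param seed Integer seed.
#' @return An object of class `mwl_fit`; use [predict()] to obtain
#'   predictions (regression values, or positive-class scores for
#'   classification).
#' @export
build_model <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "mwl_model_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  task <- spec$task
  if (task == "classification") {
    y <- as.factor(y)
    if (nlevels(y) != 2) stopf("classification needs exactly 2 classes")
  } else {
    y <- as.numeric(y)
  }
  pr <- spec$params
  fit <- switch(spec$name,
    LnR = {
      cf <- lm.fit(cbind(1, x), y)$coefficients
      cf[is.na(cf)] <- 0
      list(kind = "lnr", coef = cf)
    },
    LgR = {
      n <- nrow(x)
      wts <- rep(1, n)
      if (identical(pr$class_weight, "balanced")) {
        tab <- table(y)
        wts <- n / (2 * as.numeric(tab[y]))
      }
      gm <- with_seed(seed, glmnet::glmnet(
        x, y, family = "binomial", alpha = 0, lambda = 1 / n,
        weights = wts, standardize = TRUE,
        intercept = isTRUE(pr$fit_intercept)))
      list(kind = "lgr", model = gm, levels = levels(y))
    },
    MLP = {
      m <- mlp_fit(x, if (task == "classification") as.numeric(y) - 1 else y,
                   hidden = pr$hidden, task = task,
                   batch_size = pr$batch_size, epochs = pr$epochs,
                   lr = pr$lr, tol = pr$tol, seed = seed)
      list(kind = "mlp", model = m, levels = if (task == "classification")
        levels(y) else NULL)
    },
    RF = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      m <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = pr$n_estimators, max.depth = pr$max_depth,
        replace = isTRUE(pr$bootstrap),
        probability = task == "classification", seed = seed,
        num.threads = 1)
      list(kind = "rf", model = m, levels = if (task == "classification")
        levels(y) else NULL)
    },
    SVM = {
      m <- with_seed(seed, e1071::svm(
        x, y,
        type = if (task == "classification") "C-classification"
               else "eps-regression",
        kernel = pr$kernel, degree = pr$degree, cost = pr$C,
        epsilon = pr$epsilon, scale = FALSE))
      list(kind = "svm", model = m, levels = if (task == "classification")
        levels(y) else NULL)
    }
  )
  structure(c(fit, list(task = task, spec = spec)), class = "mwl_fit")
}

#' @export
predict.mwl_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  pos <- if (!is.null(object$levels)) object$levels[2] else NULL
  switch(object$kind,
    lnr = as.numeric(cbind(1, x) %*% object$coef),
    lgr = as.numeric(predict(object$model, newx = x, type = "response")),
    mlp = mlp_predict(object$model, x),
    rf = {
      p <- predict(object$model, data = data.frame(x, check.names = FALSE),
                   num.threads = 1)$predictions
      if (object$task == "classification") as.numeric(p[, pos])
      else as.numeric(p)
    },
    svm = {
      if (object$task == "classification") {
        p <- predict(object$model, x, decision.values = TRUE)
        dv <- attr(p, "decision.values")
        # e1071 orients decision values toward the first named class
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        s <- as.numeric(dv[, 1])
        if (first == pos) s else -s
      } else {
        as.numeric(predict(object$model, x))
      }
    }
  )
}

# ---- multilayer perceptron (ReLU, Adam) ----------------------------------
# Compact in-package implementation of the standard feed-forward network:
# linear output + squared error for regression, sigmoid output + log loss
# for binary classification. Stops early when the epoch loss improves by
# less than `tol` for 10 consecutive epochs.

mlp_fit <- function(x, y, hidden = c(32, 16, 4), task = "regression",
                    batch_size = 128, epochs = 500, lr = 1e-3, tol = 1e-4,
                    seed = 1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  sizes <- c(d, hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                   sqrt(2 / sizes[l])), sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    step <- 0L
    no_improve <- 0L
    best <- Inf
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        # forward
        a <- vector("list", L + 1)
        a[[1]] <- xb
        for (l in seq_len(L)) {
          z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
          a[[l + 1]] <- if (l < L) pmax(z, 0) else z
        }
        out <- a[[L + 1]][, 1]
        if (task == "classification") {
          p <- 1 / (1 + exp(-out))
          loss_sum <- loss_sum - sum(log(pmax(ifelse(yb == 1, p, 1 - p),
                                              1e-12)))
          delta <- matrix((p - yb) / m, ncol = 1)
        } else {
          loss_sum <- loss_sum + 0.5 * sum((out - yb)^2)
          delta <- matrix((out - yb) / m, ncol = 1)
        }
        # backward
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
          W[[l]] <- W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          b[[l]] <- b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      loss <- loss_sum / n
      if (loss < best - tol) { best <- loss; no_improve <- 0L }
      else no_improve <- no_improve + 1L
      if (no_improve >= 10L) break
    }
    list(W = W, b = b, task = task)
  })
}

mlp_predict <- function(model, x) {
  a <- x
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], `+`)
    a <- if (l < L) pmax(z, 0) else z
  }
  out <- a[, 1]
  if (model$task == "classification") 1 / (1 + exp(-out)) else out
}
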