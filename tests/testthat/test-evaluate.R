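test_that("model specifications carry the reference hyperparameters", {
  svm <- model_spec("SVM", "classification")
  expect_equal(svm$params$kernel, "radial")
  expect_equal(svm$params$C, 1.0)
  expect_equal(svm$params$epsilon, 0.2)
  expect_equal(svm$params$degree, 3)
  mlp <- model_spec("MLP", "regression")
  expect_equal(mlp$params$hidden, c(32, 16, 4))
  expect_equal(mlp$params$batch_size, 128)
  rf <- model_spec("RF", "classification")
  expect_equal(rf$params$n_estimators, 100)
  expect_equal(rf$params$max_depth, 5)
  expect_true(rf$params$bootstrap)
  lgr <- model_spec("LgR", "classification")
  expect_equal(lgr$params$class_weight, "balanced")
  expect_equal(lgr$params$penalty, "l2")
  expect_error(model_spec("XGB", "classification"), "unknown model")
  expect_error(model_spec("LnR", "classification"), "regression model")
})

test_that("validation splits have the prescribed structure", {
  f <- split_scheme(1000, "kfold10", seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 100))
  expect_equal(sort(unlist(f)), 1:1000)
  subj <- rep(paste0("s", 1:9), length.out = 450)
  fl <- split_scheme(450, "loo_subject", subjects = subj)
  expect_length(fl, 9)
  expect_true(all(vapply(fl, function(i) length(unique(subj[i])) == 1,
                         logical(1))))
  expect_error(split_scheme(450, "loo_subject"), "subject IDs")
  # stratified holdout: 738 rows with 241 positives -> ~24 positive held out
  labs <- rep(c("pos", "neg"), c(241, 497))
  h <- split_scheme(738, "holdout10", seed = 3, labels = labs)
  expect_equal(sum(labs[h$holdout] == "pos"), 24)
  expect_equal(sum(labs[h$holdout] == "neg"), 50)
  expect_equal(sort(c(h$holdout, h$rest)), 1:738)
})

test_that("regression metrics are the mean absolute and squared errors", {
  expect_equal(regression_metrics(c(0, 1), c(0.5, 0.5)),
               list(mae = 0.5, mse = 0.25))
  expect_equal(regression_metrics(1:5, 1:5), list(mae = 0, mse = 0))
  expect_error(regression_metrics(numeric(0), numeric(0)), "empty")
  # |err| <= 1 everywhere implies mse <= mae
  set.seed(1)
  y <- runif(50); p <- y + runif(50, -0.5, 0.5)
  m <- regression_metrics(y, p)
  expect_lte(m$mse, m$mae)
})

test_that("classification metrics reproduce hand-computed confusion tables", {
  m <- classification_metrics(confusion_counts(209, 32, 12, 485))
  expect_equal(round(m$sensitivity, 2), 0.87)
  expect_equal(round(m$specificity, 2), 0.98)
  expect_equal(round(m$accuracy, 2), 0.94)
  expect_equal(round(m$balanced_accuracy, 2), 0.92)
  expect_equal(round(m$f1, 2), 0.90)
  m2 <- classification_metrics(confusion_counts(864, 53, 157, 636))
  expect_equal(round(m2$accuracy, 2), 0.88)
  expect_equal(round(m2$balanced_accuracy, 2), 0.87)
  # zero denominators are undefined, not zero
  m3 <- classification_metrics(confusion_counts(0, 0, 0, 10))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$balanced_accuracy))
  expect_equal(m3$accuracy, 1)
  # counts route equals the label-counting route
  truth <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "b", "a")
  cm <- confusion_matrix(truth, pred, positive = "a")
  expect_equal(cm$tp, 1); expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1); expect_equal(cm$tn, 2)
})

test_that("AUC equals brute-force pair counting", {
  pair_auc <- function(scores, labels, positive) {
    sp <- scores[labels == positive]; sn <- scores[labels != positive]
    cnt <- 0
    for (a in sp) for (b in sn) cnt <- cnt + (a > b) + 0.5 * (a == b)
    cnt / (length(sp) * length(sn))
  }
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                       positive = "1")$auc, 0.75)
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    labels <- c("n", "p")[rbinom(n, 1, 0.5) + 1]
    if (length(unique(labels)) < 2) labels[1:2] <- c("n", "p")
    scores <- round(rnorm(n), 1)       # induce ties
    expect_equal(roc_auc(scores, labels, positive = "p")$auc,
                 pair_auc(scores, labels, "p"), tolerance = 1e-12)
  }
  # perfect separation and label-independent scores
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1),
                       positive = "1")$auc, 1)
  set.seed(8)
  big <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5), positive = "1")$auc
  expect_lt(abs(big - 0.5), 0.05)
  expect_error(roc_auc(1:4, rep("a", 4)), "both classes")
  # curve endpoints
  cv <- roc_auc(c(0.2, 0.7, 0.5), c("n", "p", "p"), positive = "p")$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[nrow(cv)], 1)
})

test_that("exact Wilcoxon matches full enumeration for n <= 12", {
  brute_p <- function(d, alternative) {
    d <- d[d != 0]; r <- rank(abs(d)); wobs <- sum(r[d > 0])
    W <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d)))) %*% r
    if (alternative == "greater") mean(W >= wobs - 1e-9)
    else min(1, 2 * min(mean(W <= wobs + 1e-9), mean(W >= wobs - 1e-9)))
  }
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)  # ties likely
    if (all(x == y)) x[1] <- x[1] + 1
    for (alt in c("two_sided", "greater")) {
      got <- wilcoxon_signed_rank(x, y, alt)
      expect_equal(got$p, brute_p(x - y, alt), tolerance = 1e-12)
    }
  }
  # all-positive differences at n = 9: statistic 0, p = 2/512
  r9 <- wilcoxon_signed_rank(1:9, rep(0, 9))
  expect_equal(r9$statistic, 0)
  expect_equal(r9$p, 2 / 512)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all differences")
  # the normal approximation tracks the exact tail for moderate n
  set.seed(12)
  x <- rnorm(12, 0.5); y <- rnorm(12)
  pe <- wilcoxon_signed_rank(x, y, "greater", mode = "exact")$p
  pn <- wilcoxon_signed_rank(x, y, "greater", mode = "normal")$p
  expect_lt(abs(pe - pn), 0.02)
})

test_that("DeLong test matches its definition and a paired bootstrap", {
  set.seed(21)
  n <- 500
  lab <- rbinom(n, 1, 0.45)
  sa <- lab + rnorm(n)
  sb <- 0.85 * lab + rnorm(n)
  d <- delong_auc_test(sa, sb, lab, positive = "1")
  expect_equal(d$auc_a, roc_auc(sa, lab, positive = "1")$auc)
  expect_equal(sign(d$z), sign(d$auc_a - d$auc_b))
  # identical score vectors: z = 0, one-sided p = 0.5
  di <- delong_auc_test(sa, sa, lab, positive = "1")
  expect_equal(di$z, 0); expect_equal(di$p, 0.5)
  # independent implementation (pROC) agrees to full precision
  pr <- pROC::roc.test(pROC::roc(lab, sa, quiet = TRUE),
                       pROC::roc(lab, sb, quiet = TRUE), method = "delong",
                       alternative = "two.sided")
  d2 <- delong_auc_test(sa, sb, lab, positive = "1",
                        alternative = "two_sided")
  expect_equal(d2$z, unname(pr$statistic), tolerance = 1e-10)
  expect_equal(d2$p, pr$p.value, tolerance = 1e-10)
  ci <- pROC::ci.auc(pROC::roc(lab, sa, quiet = TRUE), method = "delong")
  expect_equal(d2$ci95_a, c(ci[1], ci[3]), tolerance = 1e-10)
  # paired bootstrap of the AUC difference agrees within 0.02
  B <- 2000
  auc_fast <- function(s, l) {
    r <- rank(s); np <- sum(l == 1)
    (sum(r[l == 1]) - np * (np + 1) / 2) / (np * (n - np))
  }
  set.seed(22)
  diffs <- vapply(1:B, function(b) {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(lab[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    auc_fast(sa[idx], lab[idx]) - auc_fast(sb[idx], lab[idx])
  }, numeric(1))
  p_boot <- mean(diffs <= 0)
  expect_lt(abs(d$p - p_boot), 0.02)
  expect_error(delong_auc_test(sa, sb[1:10], lab), "length mismatch")
  expect_error(delong_auc_test(sa, sb, rep(1, n)), "both classes")
})

test_that("DeLong confidence intervals cover the true AUC at the nominal rate", {
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  covered <- 0L
  for (rep in 1:200) {
    set.seed(3000 + rep)
    lab <- rep(c(0, 1), each = 100)
    s <- rnorm(200) + mu * lab
    d <- delong_auc_test(s, s + rnorm(200, 0, 1e-6), lab, positive = "1")
    covered <- covered + (true_auc >= d$ci95_a[1] && true_auc <= d$ci95_a[2])
  }
  expect_gte(covered / 200, 0.90)
  expect_lte(covered / 200, 0.99)
})

test_that("run_experiment is deterministic and matches the scheme shape", {
  set.seed(2)
  n <- 400
  x <- matrix(runif(n * 4), n, 4)
  y <- pmin(1, pmax(0, 0.2 + 0.6 * x[, 1] + rnorm(n, 0, 0.05)))
  specs <- list(model_spec("LnR"), model_spec("RF"))
  r1 <- run_experiment(x, y, specs, "kfold10", seed = 42)
  expect_equal(nrow(r1$models$LnR$folds), 10)  # 10 MAE values per model
  expect_true(all(c("mae", "mse") %in% names(r1$models$RF$folds)))
  r2 <- run_experiment(x, y, specs, "kfold10", seed = 42)
  expect_identical(r1$summary, r2$summary)
  expect_setequal(unique(r1$summary$metric), c("mae", "mse"))
  # classification under a stratified holdout
  yc <- factor(ifelse(x[, 1] + rnorm(n, 0, 0.3) > 0.5, "High", "Low"))
  rc <- run_experiment(x, yc,
                       list(model_spec("LgR", "classification"),
                            model_spec("SVM", "classification")),
                       "holdout10", seed = 7, positive = "Low")
  expect_equal(nrow(rc$models$LgR$folds), 1)
  expect_gt(rc$models$LgR$folds$auc, 0.7)
  expect_gt(rc$models$SVM$folds$auc, 0.7)
  # task/spec mismatch is an error
  expect_error(run_experiment(x, yc, specs, "kfold10", seed = 1),
               "not a classification model")
})
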