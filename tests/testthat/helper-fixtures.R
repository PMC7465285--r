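# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full EEG chain on a session: filter, blink-correct, epoch, reject, PSD
process_eeg <- function(session) {
  eeg <- bandpass_filter(session$eeg)
  eeg <- remove_blinks(eeg)
  epochs <- reject_artifacts(segment_epochs(eeg))
  psd <- compute_psd(epochs)
  iaf <- estimate_iaf(compute_psd(reject_artifacts(segment_epochs(
    bandpass_filter(make_resting(session$config))))))
  list(epochs = epochs, psd = psd, iaf = iaf)
}

# a two-class (Easy/Hard) driving session with the default generator
# settings, processed end to end; used by index-recovery tests
two_class_fixture <- function() fixture("two_class", {
  cfg <- sim_config(seed = 11,
                    lap_plan = lap_plan(n_laps = 2, easy_s = 60,
                                        hard_s = 60))
  ses <- make_session(cfg)
  pr <- process_eeg(ses)
  roi <- roi_psd_matrix_187(pr$psd, pr$iaf)
  labels <- epoch_labels(ses, pr$epochs)
  trace_ep <- epoch_align(matrix(ses$trace$values, nrow = 1),
                          pr$epochs)[, 1]
  c(list(session = ses, roi = roi, labels = labels,
         trace_epoch = trace_ep), pr)
})

# Easy-only sessions with events at three coupling strengths, processed to
# epoch-level vehicular + EEG band features; used by coupling-monotonicity
# checks (simulate and fusion modules)
coupling_fixture <- function() fixture("coupling", {
  run_one <- function(coupling) {
    dur <- 420
    onsets <- seq(20, dur - 30, by = 40)
    events <- data.frame(
      type = rep(c("Car", "Pedestrian"), length.out = length(onsets)),
      onset_s = onsets, duration_s = 10)
    cfg <- sim_config(seed = 31, coupling = coupling,
                      lap_plan = data.frame(lap = 1, segment = "Easy",
                                            duration_s = dur),
                      events = events)
    ses <- make_session(cfg)
    pr <- process_eeg(ses)
    b45 <- band_features_45(pr$psd, pr$iaf)
    veh256 <- resample_to_eeg_rate(ses$vehicular)
    veh_ep <- epoch_align(veh256, pr$epochs)
    vn <- minmax_normalize(veh_ep)
    en <- minmax_normalize(b45)
    trace_ep <- epoch_align(matrix(ses$trace$values, nrow = 1),
                            pr$epochs)[, 1]
    labels <- epoch_labels(ses, pr$epochs)
    list(session = ses, veh_epoch = veh_ep, veh_scaled = vn$values,
         eeg_scaled = en$values, b45 = b45, trace_epoch = trace_ep,
         labels = labels)
  }
  lapply(stats::setNames(c(0, 0.5, 1), c("c0", "c05", "c1")), run_one)
})

# temporally blocked train/test split: contiguous blocks assigned
# alternately, so heavily overlapping epochs never straddle the split
blocked_split <- function(n, n_blocks = 20) {
  block <- ceiling(seq_len(n) / (n / n_blocks))
  test <- which(block %% 2 == 0)
  list(train = setdiff(seq_len(n), test), test = test)
}

# RF AUC for event detection from MI-projected vehicular features on a long
# Easy-only session with periodic events, two-fold blocked CV (averaged)
coupling_event_auc <- function(coupling, seed, dur = 840) {
  key <- sprintf("cauc_%g_%d", coupling, seed)
  fixture(key, {
    onsets <- seq(20, dur - 30, by = 40)
    events <- data.frame(
      type = rep(c("Car", "Pedestrian"), length.out = length(onsets)),
      onset_s = onsets, duration_s = 10)
    cfg <- sim_config(seed = seed, coupling = coupling,
                      lap_plan = data.frame(lap = 1, segment = "Easy",
                                            duration_s = dur),
                      events = events)
    ses <- make_session(cfg)
    pr <- process_eeg(ses)
    b45 <- band_features_45(pr$psd, pr$iaf)
    veh <- epoch_align(resample_to_eeg_rate(ses$vehicular), pr$epochs)
    vn <- minmax_normalize(veh); en <- minmax_normalize(b45)
    tpl <- build_template(vn$values, en$values)
    mif <- project_features(vn$values, tpl)
    lab <- epoch_labels(ses, pr$epochs)
    yev <- factor(ifelse(lab$event == "None", "None", "Event"),
                  levels = c("None", "Event"))
    sp <- blocked_split(nrow(mif))
    auc1 <- {
      fit <- build_model(model_spec("RF", "classification"),
                         mif[sp$train, ], yev[sp$train], seed = 99)
      roc_auc(predict(fit, mif[sp$test, ]), yev[sp$test],
              positive = "Event")$auc
    }
    auc2 <- {
      fit <- build_model(model_spec("RF", "classification"),
                         mif[sp$test, ], yev[sp$test], seed = 99)
      roc_auc(predict(fit, mif[sp$train, ]), yev[sp$train],
              positive = "Event")$auc
    }
    (auc1 + auc2) / 2
  })
}

expect_rounded_equal <- function(x, printed, digits = 2) {
  expect_equal(miwl:::round_half_up(x, digits), printed, tolerance = 1e-9)
}
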