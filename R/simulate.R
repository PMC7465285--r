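#' Build a lap plan
#'
#' Helper constructing the segment schedule of a simulated drive: `n_laps`
#' laps, each an Easy segment followed by a Hard segment. Durations default
#' to 90 s per segment (roughly 1000 m of urban road at 40 km/h).
#'
#' @param n_laps Number of laps.
#' @param easy_s,hard_s Segment durations in seconds. `hard_s = 0` produces an
#'   Easy-only plan.
#' @return A data frame with columns `lap`, `segment`, `duration_s`.
#' @export
lap_plan <- function(n_laps = 3, easy_s = 90, hard_s = 90) {
  segs <- if (hard_s > 0) c("Easy", "Hard") else "Easy"
  durs <- if (hard_s > 0) c(easy_s, hard_s) else easy_s
  data.frame(
    lap = rep(seq_len(n_laps), each = length(segs)),
    segment = rep(segs, n_laps),
    duration_s = rep(durs, n_laps),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a synthetic driving session: the segment schedule, traffic hour,
#' on-road events, how strongly vehicular behaviour is coupled to the latent
#' workload, and the EEG generation parameters. Baseline workload levels and
#' velocities are fixed at the group means observed on real urban drives
#' (Easy workload 0.42 vs Hard 0.51; Easy velocity 44.69 km/h vs Hard
#' 37.81 km/h); Rush hour adds 0.05 workload and events add 0.10 while
#' active.
#'
#' @param seed Integer seed; every generated quantity is a deterministic
#'   function of the configuration including this seed.
#' @param lap_plan Data frame with columns `lap`, `segment`
#'   (`"Easy"`/`"Hard"`), `duration_s` (see [lap_plan()]).
#' @param hour `"Normal"` or `"Rush"`.
#' @param events Data frame with columns `type` (`"Car"`/`"Pedestrian"`),
#'   `onset_s`, `duration_s`; may be empty. Events must lie inside the
#'   session timeline.
#' @param coupling Strength in `[0, 1]` of the dependence of vehicular
#'   signals on the latent workload trace. At 0 the vehicular channels are
#'   statistically independent of the trace.
#' @param iaf_hz Individual alpha frequency in `[8, 12]` Hz.
#' @param blink_rate_hz Mean blink rate (events per second), `>= 0`.
#' @param artifact_rate_hz Mean rate of high-amplitude artifact bursts, `>= 0`.
#' @param eeg_noise_scale Multiplier (> 0) on the 1/f background noise
#'   (baseline standard deviation 10 uV).
#' @param trace_noise_sd Stationary standard deviation of the AR(1) workload
#'   fluctuation around the scheduled baseline (0 gives the deterministic
#'   baseline).
#' @param trace_ar AR(1) coefficient of the workload fluctuation at 256 Hz;
#'   the default 0.999 gives a correlation time of a few seconds, slow
#'   relative to the 0.125 s epoch shift.
#' @param theta_gain,alpha_gain Amplitude (uV) by which frontal theta grows
#'   and parietal alpha shrinks per unit workload.
#' @param vel_gain km/h of velocity drop per unit workload excursion (scaled
#'   by `coupling`).
#' @return An object of class `mwl_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       lap_plan = miwl::lap_plan(),
                       hour = c("Normal", "Rush"),
                       events = NULL,
                       coupling = 1,
                       iaf_hz = 10,
                       blink_rate_hz = 0.2,
                       artifact_rate_hz = 0.02,
                       eeg_noise_scale = 1,
                       trace_noise_sd = 0.15,
                       trace_ar = 0.999,
                       theta_gain = 6,
                       alpha_gain = 6,
                       vel_gain = 30) {
  hour <- match.arg(hour)
  if (is.null(events)) {
    events <- data.frame(type = character(), onset_s = numeric(),
                         duration_s = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(lap_plan) || nrow(lap_plan) == 0)
    stopf("lap_plan must be a non-empty data frame")
  if (!all(c("lap", "segment", "duration_s") %in% names(lap_plan)))
    stopf("lap_plan needs columns lap, segment, duration_s")
  if (!all(lap_plan$segment %in% c("Easy", "Hard")))
    stopf("segments must be 'Easy' or 'Hard'")
  if (any(lap_plan$duration_s <= 0)) stopf("segment durations must be > 0")
  total_s <- sum(lap_plan$duration_s)
  if (nrow(events)) {
    if (!all(events$type %in% c("Car", "Pedestrian")))
      stopf("event types must be 'Car' or 'Pedestrian'")
    if (any(events$duration_s <= 0)) stopf("event durations must be > 0")
    if (any(events$onset_s < 0 | events$onset_s + events$duration_s > total_s))
      stopf("events must lie within the session timeline (0..%g s)", total_s)
  }
  if (coupling < 0 || coupling > 1) stopf("coupling must be in [0, 1]")
  if (iaf_hz < 8 || iaf_hz > 12) stopf("iaf_hz must be in [8, 12]")
  if (blink_rate_hz < 0 || artifact_rate_hz < 0)
    stopf("blink and artifact rates must be >= 0")
  if (eeg_noise_scale <= 0) stopf("eeg_noise_scale must be > 0")
  if (trace_noise_sd < 0) stopf("trace_noise_sd must be >= 0")
  structure(
    list(seed = seed, lap_plan = lap_plan, hour = hour, events = events,
         coupling = coupling, iaf_hz = iaf_hz, blink_rate_hz = blink_rate_hz,
         artifact_rate_hz = artifact_rate_hz,
         eeg_noise_scale = eeg_noise_scale, trace_noise_sd = trace_noise_sd,
         trace_ar = trace_ar, theta_gain = theta_gain,
         alpha_gain = alpha_gain, vel_gain = vel_gain,
         duration_s = total_s),
    class = "mwl_sim_config"
  )
}

# workload baselines; segment-level group means from real urban driving
.mwl_base <- c(Easy = 0.42, Hard = 0.51)
.vel_base <- c(Easy = 44.69, Hard = 37.81)
.rush_offset <- 0.05
.event_offset <- 0.10

# per-sample segment/lap/event indices at rate fs for a config timeline
schedule_at <- function(config, fs) {
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ends <- cumsum(config$lap_plan$duration_s)
  row <- findInterval(t, c(0, ends), rightmost.closed = TRUE,
                      left.open = TRUE)
  row[row < 1] <- 1
  row[row > nrow(config$lap_plan)] <- nrow(config$lap_plan)
  ev <- rep("None", n)
  if (nrow(config$events)) {
    for (i in seq_len(nrow(config$events))) {
      on <- t >= config$events$onset_s[i] &
        t < config$events$onset_s[i] + config$events$duration_s[i]
      ev[on] <- config$events$type[i]
    }
  }
  list(t = t, segment = config$lap_plan$segment[row],
       lap = config$lap_plan$lap[row], event = ev)
}

#' Simulate the latent workload trace
#'
#' The trace is a piecewise baseline determined by the schedule (Easy 0.42,
#' Hard 0.51, +0.05 during Rush hour, +0.10 while an event is active) plus
#' seeded AR(1) noise, clipped to `[0, 1]`, sampled at 256 Hz.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `mwl_trace`: list with `values` (in `[0, 1]`),
#'   `sample_rate_hz`, `baseline` (full scheduled baseline) and
#'   `schedule_baseline` (segment + hour part only, used by the vehicular
#'   generator so that event-driven excursions propagate through coupling).
#' @export
simulate_workload_trace <- function(config) {
  stopifnot(inherits(config, "mwl_sim_config"))
  fs <- 256
  sch <- schedule_at(config, fs)
  base_seg <- .mwl_base[sch$segment] +
    if (config$hour == "Rush") .rush_offset else 0
  base <- base_seg + ifelse(sch$event == "None", 0, .event_offset)
  n <- length(base)
  noise <- if (config$trace_noise_sd > 0) {
    phi <- config$trace_ar
    innov_sd <- config$trace_noise_sd * sqrt(1 - phi^2)
    with_seed(child_seed(config$seed, "trace"), {
      x0 <- rnorm(1, 0, config$trace_noise_sd)
      as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                               method = "recursive", init = x0))
    })
  } else {
    numeric(n)
  }
  structure(
    list(values = clip01(base + noise), sample_rate_hz = fs,
         baseline = unname(base), schedule_baseline = unname(base_seg),
         schedule = sch),
    class = "mwl_trace"
  )
}

# 1/f-amplitude background noise via spectral synthesis, unit variance
pink_noise <- function(n) {
  nf <- ceiling(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec[seq_len(nf)]
  if (n > 2) {
    hi <- n - seq_len(ceiling(n / 2) - 1) + 1
    full[hi] <- Conj(full[2:ceiling(n / 2)])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(x / sd(x))
}

# raised-cosine transient of `dur_s` seconds
raised_cosine <- function(dur_s, fs) {
  m <- round(dur_s * fs)
  0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
}

# blink propagation topography: maximal at Fpz, decaying towards the back
blink_topography <- function() {
  c(Fpz = 1, Fz = 0.5, Pz = 0.12, POz = 0.1, Oz = 0.05, AF3 = 0.6,
    AF4 = 0.6, F3 = 0.4, F4 = 0.4, P3 = 0.1, P4 = 0.1, P5 = 0.08,
    P6 = 0.08, O1 = 0.05, O2 = 0.05)
}

#' Synthesize the 15-channel EEG of a session
#'
#' Each channel is 1/f background noise plus a theta oscillation (centred at
#' IAF - 4 Hz) whose amplitude on frontal channels grows affinely with the
#' workload trace, an alpha oscillation (centred at IAF) whose amplitude on
#' parietal/occipital channels shrinks affinely with the trace, seeded blink
#' transients (400 ms raised cosine, 80 uV at Fpz, scaled by a fixed frontal
#' topography) and sparse high-amplitude artifact bursts.
#'
#' @param trace An `mwl_trace` at 256 Hz.
#' @param config The [sim_config()] used to generate the trace.
#' @param mode `"driving"` for a task recording, `"closed_eyes"` for a
#'   resting recording with boosted posterior alpha (used for alpha-peak
#'   estimation).
#' @return `channels x samples` matrix in uV with channel rownames.
#' @export
synthesize_eeg <- function(trace, config, mode = c("driving", "closed_eyes")) {
  stopifnot(inherits(trace, "mwl_trace"), inherits(config, "mwl_sim_config"))
  mode <- match.arg(mode)
  fs <- trace$sample_rate_hz
  w <- trace$values
  n <- length(w)
  chans <- mwl_channels()
  t <- (seq_len(n) - 1) / fs
  frontal <- c("Fpz", mwl_roi_channels("frontal"))
  posterior <- mwl_roi_channels("posterior")
  theta_hz <- config$iaf_hz - 4
  alpha_hz <- config$iaf_hz
  alpha_boost <- if (mode == "closed_eyes") 3 else 1
  eeg <- with_seed(child_seed(config$seed, paste0("eeg_", mode)), {
    out <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
    for (ch in chans) {
      bg <- pink_noise(n) * 10 * config$eeg_noise_scale
      th_amp <- if (ch %in% frontal) 2 + config$theta_gain * w else
        rep(1, n)
      al_amp <- if (ch %in% posterior)
        (2 + config$alpha_gain * (1 - w)) * alpha_boost else rep(1, n)
      ph <- runif(2, 0, 2 * pi)
      out[ch, ] <- bg +
        th_amp * sin(2 * pi * theta_hz * t + ph[1]) +
        al_amp * sin(2 * pi * alpha_hz * t + ph[2])
    }
    # blinks: Poisson onsets, common transient scaled per channel
    n_blinks <- rpois(1, config$blink_rate_hz * n / fs)
    if (n_blinks > 0) {
      tmpl <- raised_cosine(0.4, fs) * 80
      topo <- blink_topography()[chans]
      onsets <- sort(sample.int(n - length(tmpl), n_blinks, replace = TRUE))
      for (o in onsets) {
        idx <- o + seq_along(tmpl) - 1
        out[, idx] <- out[, idx] + outer(topo, tmpl)
      }
    }
    # artifact bursts: enveloped wideband noise on one random channel
    n_art <- rpois(1, config$artifact_rate_hz * n / fs)
    if (n_art > 0) {
      m <- round(0.5 * fs)
      env <- raised_cosine(0.5, fs)
      for (a in seq_len(n_art)) {
        ch <- sample(chans, 1)
        o <- sample.int(n - m, 1)
        out[ch, o + seq_len(m) - 1] <- out[ch, o + seq_len(m) - 1] +
          env * rnorm(m, 0, 80) + env * 120
      }
    }
    out
  })
  eeg
}

# AR(1)-smoothed gaussian noise with stationary sd `s`
smooth_noise <- function(n, s, phi = 0.9) {
  if (s <= 0) return(numeric(n))
  as.numeric(stats::filter(rnorm(n, 0, s * sqrt(1 - phi^2)), phi,
                           method = "recursive", init = rnorm(1, 0, s)))
}

#' Synthesize vehicular telemetry
#'
#' Velocity follows the segment baseline (Easy 44.69 km/h, Hard 37.81 km/h)
#' minus `coupling * vel_gain` times the workload excursion above the
#' scheduled segment/hour baseline, plus smoothed noise, sampled at 10 Hz.
#' Acceleration is the first difference of velocity (m/s^2); lateral and
#' longitudinal accelerations are coupling-weighted smoothed functions of the
#' workload excursion plus noise. With `coupling = 0` every channel is
#' statistically independent of the latent trace.
#'
#' @inheritParams synthesize_eeg
#' @param vel_noise_sd,lat_noise_sd Noise levels (km/h and m/s^2).
#' @return `4 x samples` matrix at 10 Hz with rows
#'   `velocity, acceleration, lateral_acceleration, longitudinal_acceleration`.
#' @export
synthesize_vehicular <- function(trace, config, vel_noise_sd = 3,
                                 lat_noise_sd = 0.3) {
  stopifnot(inherits(trace, "mwl_trace"), inherits(config, "mwl_sim_config"))
  fs_v <- 10
  n10 <- round(config$duration_s * fs_v)
  t10 <- (seq_len(n10) - 1) / fs_v
  idx <- pmin(length(trace$values), round(t10 * trace$sample_rate_hz) + 1)
  dev <- trace$values[idx] - trace$schedule_baseline[idx]
  seg <- trace$schedule$segment[idx]
  with_seed(child_seed(config$seed, "vehicular"), {
    vel <- .vel_base[seg] - config$coupling * config$vel_gain * dev +
      smooth_noise(n10, vel_noise_sd)
    acc <- c(0, diff(vel / 3.6)) * fs_v
    lat <- config$coupling * 1.5 *
      as.numeric(stats::filter(dev, 0.8, method = "recursive", init = dev[1])) *
      (1 - 0.8) + smooth_noise(n10, lat_noise_sd, phi = 0.7)
    lon <- -config$coupling * 1.0 *
      as.numeric(stats::filter(dev, 0.6, method = "recursive", init = dev[1])) *
      (1 - 0.6) + smooth_noise(n10, lat_noise_sd, phi = 0.7)
    out <- rbind(velocity = unname(vel), acceleration = acc,
                 lateral_acceleration = lat, longitudinal_acceleration = lon)
    colnames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic session
#'
#' Composes the workload trace, EEG, vehicular and annotation generators.
#' Identical configurations (including the seed) produce identical sessions.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `mwl_session`: `eeg` (15 x samples, 256 Hz),
#'   `vehicular` (4 x samples, 10 Hz), `annotations` (interval data frame
#'   with columns `start_s`, `end_s`, `lap`, `segment`, `hour`, `event`),
#'   `trace` (the latent `mwl_trace` ground truth) and `config`.
#' @export
make_session <- function(config) {
  stopifnot(inherits(config, "mwl_sim_config"))
  trace <- simulate_workload_trace(config)
  eeg <- synthesize_eeg(trace, config)
  veh <- synthesize_vehicular(trace, config)
  structure(
    list(eeg = eeg, vehicular = veh,
         annotations = annotation_intervals(config), trace = trace,
         config = config),
    class = "mwl_session"
  )
}

#' Generate a closed-eyes resting recording
#'
#' One-minute (by default) eyes-closed recording with boosted posterior
#' alpha at the configured individual alpha frequency, used to estimate the
#' alpha peak before processing the task data.
#'
#' @param config An [sim_config()] object (its lap plan is ignored).
#' @param duration_s Recording length in seconds.
#' @return `channels x samples` EEG matrix at 256 Hz.
#' @export
make_resting <- function(config, duration_s = 60) {
  rest_cfg <- sim_config(
    seed = child_seed(config$seed, "resting"),
    lap_plan = data.frame(lap = 1, segment = "Easy",
                          duration_s = duration_s),
    hour = "Normal", coupling = 0, iaf_hz = config$iaf_hz,
    blink_rate_hz = 0, artifact_rate_hz = 0,
    eeg_noise_scale = config$eeg_noise_scale, trace_noise_sd = 0,
    theta_gain = config$theta_gain, alpha_gain = config$alpha_gain
  )
  trace <- simulate_workload_trace(rest_cfg)
  trace$values[] <- 0
  synthesize_eeg(trace, rest_cfg, mode = "closed_eyes")
}

#' Annotation intervals of a configuration
#'
#' Flattens the lap plan, traffic hour and event schedule into disjoint
#' labelled intervals covering the session.
#'
#' @param config An [sim_config()] object.
#' @return Data frame with columns `start_s`, `end_s`, `lap`, `segment`,
#'   `hour`, `event`.
#' @export
annotation_intervals <- function(config) {
  ends <- cumsum(config$lap_plan$duration_s)
  starts <- c(0, head(ends, -1))
  cuts <- sort(unique(c(starts, ends,
                        config$events$onset_s,
                        config$events$onset_s + config$events$duration_s)))
  s <- head(cuts, -1)
  e <- tail(cuts, -1)
  mid <- (s + e) / 2
  row <- findInterval(mid, c(0, ends), rightmost.closed = TRUE)
  ev <- rep("None", length(mid))
  if (nrow(config$events)) {
    for (i in seq_len(nrow(config$events))) {
      on <- mid >= config$events$onset_s[i] &
        mid < config$events$onset_s[i] + config$events$duration_s[i]
      ev[on] <- config$events$type[i]
    }
  }
  data.frame(start_s = s, end_s = e,
             lap = config$lap_plan$lap[row],
             segment = config$lap_plan$segment[row],
             hour = config$hour, event = ev, stringsAsFactors = FALSE)
}

#' Label each epoch from the session annotations
#'
#' Epochs are labelled by the annotation interval containing their midpoint.
#'
#' @param session An `mwl_session`.
#' @param epochs An `mwl_epochs` object on the session's EEG.
#' @param kept_only Restrict to kept epochs (default).
#' @return Data frame with one row per (kept) epoch: `epoch`, `start_s`,
#'   `lap`, `segment`, `hour`, `event`.
#' @export
epoch_labels <- function(session, epochs, kept_only = TRUE) {
  stopifnot(inherits(session, "mwl_session"), inherits(epochs, "mwl_epochs"))
  idx <- if (kept_only) which(epochs$keep) else seq_len(epochs$n_epochs)
  mids <- epochs$start_times_s[idx] + epochs$length_s / 2
  ann <- session$annotations
  row <- findInterval(mids, c(ann$start_s, tail(ann$end_s, 1)),
                      rightmost.closed = TRUE)
  row <- pmin(pmax(row, 1), nrow(ann))
  data.frame(epoch = idx, start_s = epochs$start_times_s[idx],
             lap = ann$lap[row], segment = ann$segment[row],
             hour = ann$hour[row], event = ann$event[row],
             stringsAsFactors = FALSE)
}

#' Write a session to plain-text files
#'
#' Writes `eeg.csv` (time_s + 15 channel columns), `vehicular.csv`
#' (time_s, velocity, acceleration, lateral_acceleration,
#' longitudinal_acceleration), `annotations.csv` and `config.json` into
#' `dir`. Identical sessions produce byte-identical files.
#'
#' @param session An `mwl_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "mwl_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- 256
  eeg_df <- data.frame(time_s = (seq_len(ncol(session$eeg)) - 1) / fs,
                       t(session$eeg), check.names = FALSE)
  veh_df <- data.frame(time_s = (seq_len(ncol(session$vehicular)) - 1) / 10,
                       t(session$vehicular), check.names = FALSE)
  paths <- file.path(dir, c("eeg.csv", "vehicular.csv", "annotations.csv",
                            "config.json"))
  write.csv(eeg_df, paths[1], row.names = FALSE)
  write.csv(veh_df, paths[2], row.names = FALSE)
  write.csv(session$annotations, paths[3], row.names = FALSE)
  cfg <- session$config
  cfg_json <- list(seed = cfg$seed, lap_plan = cfg$lap_plan, hour = cfg$hour,
                   events = cfg$events, coupling = cfg$coupling,
                   iaf_hz = cfg$iaf_hz, blink_rate_hz = cfg$blink_rate_hz,
                   artifact_rate_hz = cfg$artifact_rate_hz,
                   eeg_noise_scale = cfg$eeg_noise_scale,
                   trace_noise_sd = cfg$trace_noise_sd)
  writeLines(jsonlite::toJSON(cfg_json, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[4])
  invisible(paths)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `eeg.csv`, `vehicular.csv`,
#'   `annotations.csv`.
#' @return A list with `eeg`, `vehicular` (channels x samples matrices) and
#'   `annotations`.
#' @export
read_session <- function(dir) {
  eeg_df <- read.csv(file.path(dir, "eeg.csv"), check.names = FALSE)
  veh_df <- read.csv(file.path(dir, "vehicular.csv"), check.names = FALSE)
  ann <- read.csv(file.path(dir, "annotations.csv"))
  eeg <- t(as.matrix(eeg_df[, -1]))
  veh <- t(as.matrix(veh_df[, -1]))
  list(eeg = eeg, vehicular = veh, annotations = ann)
}

#' @export
print.mwl_session <- function(x, ...) {
  cat(sprintf(
    "<mwl_session> %.1f s | EEG %d ch x %d samples @256 Hz | vehicular %d x %d @10 Hz\n",
    x$config$duration_s, nrow(x$eeg), ncol(x$eeg), nrow(x$vehicular),
    ncol(x$vehicular)))
  cat(sprintf("  hour=%s coupling=%.2f iaf=%.1f Hz events=%d\n",
              x$config$hour, x$config$coupling, x$config$iaf_hz,
              nrow(x$config$events)))
  invisible(x)
}
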