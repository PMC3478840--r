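# Seeded generator of synthetic waist-mounted accelerometer recordings for
# the 21 scripted ADL classes and for continuous unscripted sessions.
#
# The kinematic model is deliberately simple: the sensor reads
#   a(t) = gm(t) * g_dir(theta(t), phi) + dynamics(t) + noise,
# where g_dir is the gravity direction in the sensor frame (theta = tilt
# from upright, phi = azimuth), gm is the gravity magnitude seen by the
# sensor (ramping toward 0.2-0.5 g during free fall), and dynamics adds
# gait oscillations, impact spikes (half-sine, 30-80 ms), post-impact
# slump ringing and sit-down bumps. Output is clipped to +/-2 g and
# quantized to a 12-bit grid, emulating the target device.

QUANT_STEP <- 4 / 4096   # 12-bit resolution over +/-2 g
IMPACT_FLOOR <- 1.2      # g; non-fall bumps stay strictly below this

g_dir <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

smoothstep <- function(n) {
  if (n <= 1) return(rep(1, n))
  u <- (seq_len(n) - 1) / (n - 1)
  u * u * (3 - 2 * u)
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Motion profiles of the 21 ADL classes
#'
#' Each profile is an ordered phase list (static, oscillation, tilt,
#' free_fall, impact, slump) with duration, amplitude and orientation
#' ranges. Fall profiles (ids 1-10) contain a free-fall and an impact
#' phase; non-fall profiles contain neither a free-fall phase nor any bump
#' reaching the 1.2 g impact floor. Soft falls (ids 5, 6, 7, 9: the bed and
#' wheelchair classes) have impact amplitudes (1.2-1.6 g) strictly below
#' the hard stand-height falls (ids 3, 4, 8, 10: 1.7-2.0 g), so their
#' signatures overlap energetic non-fall activities — the designed hard
#' case for threshold classifiers. All ranges are package choices; no
#' kinematic reference data exists for these activities.
#'
#' @return Named list of 21 profiles (`adl_id`, `name`, `is_fall`,
#'   `severity`, `start_theta`, `phases`).
#' @export
adl_profiles <- function() {
  st <- function(dur = c(2.5, 3.5)) list(kind = "static", dur = dur)
  endst <- function() list(kind = "static", dur = c(2, 3))
  osc <- function(dur, amp, freq) list(kind = "oscillation", dur = dur,
                                       amp = amp, freq = freq)
  tilt <- function(dur, to) list(kind = "tilt", dur = dur, to = to)
  ff <- function(dur, level, to) list(kind = "free_fall", dur = dur,
                                      level = level, to = to)
  imp <- function(amp) list(kind = "impact", dur = c(0.03, 0.08), amp = amp)
  slump <- function() list(kind = "slump", dur = c(0.3, 0.6),
                           amp = c(0.1, 0.25))
  cat <- adl_catalog_df()
  pr <- list()
  mk <- function(id, severity, start_theta, phases) {
    list(adl_id = id, name = cat$name[id], is_fall = cat$is_fall[id],
         severity = severity, start_theta = start_theta, phases = phases)
  }
  # falling ADLs -------------------------------------------------------
  pr[[1]] <- mk(1, "hard", c(0, 0), list(
    st(), osc(c(1.5, 2.5), c(0.3, 0.5), c(1.6, 2.2)),
    ff(c(0.3, 0.35), c(0.45, 0.5), c(60, 80)), imp(c(1.4, 1.7)),
    slump(), endst()))
  pr[[2]] <- mk(2, "hard", c(0, 0), list(
    st(), osc(c(1.5, 2.5), c(0.35, 0.55), c(1.7, 2.3)),
    ff(c(0.3, 0.4), c(0.35, 0.45), c(60, 85)), imp(c(1.5, 1.8)),
    slump(), endst()))
  pr[[3]] <- mk(3, "hard", c(0, 0), list(
    st(), osc(c(0.5, 1), c(0.25, 0.4), c(1.5, 2)),
    ff(c(0.35, 0.5), c(0.2, 0.35), c(85, 95)), imp(c(1.7, 2.0)),
    slump(), endst()))
  pr[[4]] <- mk(4, "hard", c(0, 0), list(
    st(), ff(c(0.35, 0.5), c(0.2, 0.35), c(85, 95)), imp(c(1.7, 2.0)),
    slump(), endst()))
  pr[[5]] <- mk(5, "soft", c(85, 95), list(
    st(), ff(c(0.3, 0.4), c(0.3, 0.45), c(80, 100)), imp(c(1.2, 1.6)),
    slump(), endst()))
  pr[[6]] <- mk(6, "soft", c(15, 30), list(
    st(), ff(c(0.3, 0.38), c(0.3, 0.45), c(80, 95)), imp(c(1.2, 1.6)),
    slump(), endst()))
  pr[[7]] <- mk(7, "soft", c(85, 95), list(
    st(), tilt(c(0.8, 1.5), c(70, 110)),
    ff(c(0.3, 0.35), c(0.35, 0.5), c(80, 100)), imp(c(1.2, 1.5)),
    slump(), endst()))
  pr[[8]] <- mk(8, "hard", c(0, 0), list(
    st(), ff(c(0.35, 0.5), c(0.2, 0.35), c(85, 95)), imp(c(1.7, 2.0)),
    slump(), endst()))
  pr[[9]] <- mk(9, "soft", c(0, 0), list(
    st(), ff(c(0.3, 0.45), c(0.25, 0.4), c(80, 95)), imp(c(1.2, 1.6)),
    slump(), endst()))
  pr[[10]] <- mk(10, "hard", c(0, 0), list(
    st(), ff(c(0.3, 0.5), c(0.3, 0.5), c(75, 90)), imp(c(1.7, 1.9)),
    slump(), endst()))
  # non-falling ADLs ----------------------------------------------------
  pr[[11]] <- mk(11, NA, c(0, 0), list(
    st(), osc(c(4, 6), c(0.3, 0.55), c(1.5, 2.0)), endst()))
  pr[[12]] <- mk(12, NA, c(0, 0), list(
    st(), osc(c(4, 6), c(0.35, 0.6), c(1.7, 2.3)), endst()))
  pr[[13]] <- mk(13, NA, c(0, 0), list(
    st(), tilt(c(1, 2), c(10, 25)), imp(c(0.8, 1.15)), endst()))
  pr[[14]] <- mk(14, NA, c(10, 25), list(
    st(), tilt(c(1, 2), c(0, 5)), imp(c(0.4, 0.8)), endst()))
  pr[[15]] <- mk(15, NA, c(0, 0), list(
    st(), tilt(c(1, 2), c(10, 25)), imp(c(0.8, 1.15)), endst()))
  pr[[16]] <- mk(16, NA, c(10, 25), list(
    st(), tilt(c(1, 2), c(0, 5)), imp(c(0.4, 0.8)), endst()))
  pr[[17]] <- mk(17, NA, c(0, 0), list(
    st(), osc(c(4, 6), c(0.2, 0.6), c(1.5, 2.5)), endst()))
  pr[[18]] <- mk(18, NA, c(0, 0), list(
    st(), tilt(c(2, 3), c(80, 95)), imp(c(0.4, 0.8)), endst()))
  pr[[19]] <- mk(19, NA, c(80, 95), list(
    st(), tilt(c(2, 3), c(0, 10)), endst()))
  pr[[20]] <- mk(20, NA, c(0, 0), list(
    st(), osc(c(1, 2), c(0.3, 0.5), c(0.8, 1.2)), tilt(c(0.5, 1), c(5, 15)),
    endst()))
  pr[[21]] <- mk(21, NA, c(5, 15), list(
    st(), osc(c(1, 2), c(0.3, 0.5), c(0.8, 1.2)), tilt(c(0.5, 1), c(0, 5)),
    endst()))
  names(pr) <- sprintf("adl%02d", 1:21)
  pr
}

# Draw concrete phase parameters (RNG state of the caller).
instantiate_phases <- function(profile, severity = NULL, amp_scale = 1,
                               dur_scale = 1) {
  sev <- if (!is.null(severity)) severity else profile$severity
  lapply(profile$phases, function(ph) {
    out <- list(kind = ph$kind, dur = runif1(ph$dur) * dur_scale)
    out$in_fall <- ph$kind %in% c("free_fall", "impact", "slump") &&
      isTRUE(profile$is_fall)
    if (ph$kind == "oscillation") {
      out$amp <- runif1(ph$amp) * amp_scale
      out$freq <- runif1(ph$freq)
      out$phase0 <- stats::runif(1, 0, 2 * pi)
    } else if (ph$kind == "tilt") {
      out$to <- runif1(ph$to)
    } else if (ph$kind == "free_fall") {
      out$level <- runif1(ph$level)
      out$to <- runif1(ph$to)
      out$dur <- max(out$dur, 0.16)  # falls keep a detectable drop
    } else if (ph$kind == "impact") {
      amp <- ph$amp
      if (isTRUE(profile$is_fall) && !is.null(sev) && !is.na(sev))
        amp <- switch(sev, hard = c(1.7, 2.0), soft = c(1.2, 1.6), ph$amp)
      a <- runif1(amp)
      # the class contract holds at profile level (base amplitude): non-fall
      # bumps below the impact floor, fall impacts at or above it. Subject
      # amplitude scaling applies afterwards, so a heavy subject's sit-down
      # can overlap a light subject's soft fall in the recorded signal.
      if (isTRUE(profile$is_fall)) a <- max(a, IMPACT_FLOOR)
      else a <- min(a, IMPACT_FLOOR - 0.05)
      out$amp <- a * amp_scale
    } else if (ph$kind == "slump") {
      out$amp <- runif1(ph$amp) * amp_scale
    }
    out
  })
}

# Render concrete phases into a raw (unquantized) signal matrix.
render_phases <- function(phases, theta0, phi, fs, noise_sd = 0.02) {
  segs <- vector("list", length(phases))
  theta_cur <- theta0
  gm_cur <- 1
  lat <- c(cos(phi * pi / 180 + pi / 2), sin(phi * pi / 180 + pi / 2), 0)
  t_acc <- 0
  fall_start <- NA_real_
  fall_end <- NA_real_
  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    n <- max(1L, as.integer(round(ph$dur * fs)))
    theta <- rep(theta_cur, n)
    gm <- rep(1, n)
    dyn <- matrix(0, n, 3)
    if (ph$kind == "tilt") {
      theta <- theta_cur + (ph$to - theta_cur) * smoothstep(n)
    } else if (ph$kind == "free_fall") {
      theta <- theta_cur + (ph$to - theta_cur) * smoothstep(n)
      gm <- 1 + (ph$level - 1) * smoothstep(n)
    } else if (ph$kind == "oscillation") {
      tt <- (seq_len(n) - 1) / fs
      sv <- ph$amp * sin(2 * pi * ph$freq * tt + ph$phase0)
      sl <- 0.4 * ph$amp * sin(pi * ph$freq * tt + ph$phase0 / 2)
      gd <- g_dir(theta, phi)
      dyn <- sv * gd + outer(sl, lat)
    } else if (ph$kind == "impact") {
      u <- g_dir(theta_cur, phi)[1, ] + 0.35 * c(lat[1], lat[2], 0.1)
      u <- u / sqrt(sum(u^2))
      uu <- (seq_len(n) - 0.5) / n
      spike <- ph$amp * sin(pi * uu)
      if (gm_cur < 1) {
        # impact ending a fall: the ground-contact deceleration is what
        # restores gravity, so the magnitude ramps from the free-fall level
        # through the spike back to 1 g (restoration weighted to the phase
        # end). The fast-changed vector then measures the spike excursion
        # itself, not excursion + a 1 g restoration step.
        gm <- gm_cur + (1 - gm_cur) * uu^3
        dyn <- outer(spike, u)
      } else {
        dyn <- outer(spike, u)
      }
    } else if (ph$kind == "slump") {
      tt <- (seq_len(n) - 1) / fs
      u <- g_dir(theta_cur, phi)[1, ]
      env <- ph$amp * exp(-tt / (ph$dur / 3)) * sin(2 * pi * 3 * tt)
      dyn <- outer(env, u)
    }
    if (isTRUE(ph$in_fall)) {
      if (is.na(fall_start)) fall_start <- t_acc
      fall_end <- t_acc + n / fs
    }
    gd <- g_dir(theta, phi)
    seg <- gm * gd + dyn
    if (noise_sd > 0) seg <- seg + matrix(stats::rnorm(3 * n, 0, noise_sd),
                                          n, 3)
    segs[[k]] <- seg
    theta_cur <- theta[n]
    gm_cur <- if (ph$kind == "free_fall") ph$level else 1
    t_acc <- t_acc + n / fs
  }
  list(acc = do.call(rbind, segs), theta_end = theta_cur,
       fall_start = fall_start, fall_end = fall_end, duration = t_acc)
}

quantize_12bit <- function(x) {
  q <- pmin(2, pmax(-2, round(x / QUANT_STEP) * QUANT_STEP))
  if (is.matrix(x)) dim(q) <- dim(x)
  q
}

#' Generate one synthetic ADL trial
#'
#' Deterministic given `(adl_id, seed)`: phase durations, amplitudes,
#' orientations and sensor noise are all drawn from one seeded stream. Falls
#' are annotated with the time interval spanning free fall through the
#' post-impact slump.
#'
#' @param adl_id ADL class, 1-21 (see [adl_catalog()]).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param severity `"hard"` or `"soft"` to override a fall profile's impact
#'   severity; `NULL` uses the profile default.
#' @param amp_scale,dur_scale multiplicative subject-variation factors on
#'   dynamic amplitudes and phase durations.
#' @param noise_sd additive Gaussian sensor noise, g.
#' @param quantize clip to +/-2 g and snap to the 12-bit grid (device
#'   acquisition model).
#' @return List with `trace` (an [accel_trace()]) and `annotation` (data
#'   frame `start_s, end_s, adl_id, is_fall`; zero rows for non-falls).
#' @export
generate_trial <- function(adl_id, fs = 200, seed = 1, severity = NULL,
                           amp_scale = 1, dur_scale = 1, noise_sd = 0.02,
                           quantize = TRUE) {
  if (!adl_id %in% 1:21) stop("adl_id must be in 1..21")
  if (fs <= 0) stop("fs must be positive")
  profile <- adl_profiles()[[adl_id]]
  with_seed(seed, {
    phases <- instantiate_phases(profile, severity, amp_scale, dur_scale)
    theta0 <- runif1(profile$start_theta)
    phi <- stats::runif(1, 0, 360)
    r <- render_phases(phases, theta0, phi, fs, noise_sd)
  })
  acc <- if (quantize) quantize_12bit(r$acc) else r$acc
  trace <- accel_trace(acc[, 1], acc[, 2], acc[, 3], fs = fs,
                       meta = list(adl_id = adl_id,
                                   is_fall = profile$is_fall, seed = seed))
  ann <- if (profile$is_fall)
    data.frame(start_s = r$fall_start, end_s = r$fall_end, adl_id = adl_id,
               is_fall = TRUE)
  else data.frame(start_s = numeric(0), end_s = numeric(0),
                  adl_id = integer(0), is_fall = logical(0))
  list(trace = trace, annotation = ann)
}

#' Generate a full scripted-trial protocol
#'
#' Emulates the scripted experiment: every subject repeats all 21 ADLs
#' `trials_per_adl` times. Subjects differ by a multiplicative amplitude
#' factor (lognormal, sdlog 0.1) and a duration jitter (+/-20%). With
#' `out_dir` set, traces are written as CSV files and the manifest as
#' `manifest.csv`; otherwise everything stays in memory and manifest paths
#' are symbolic keys.
#'
#' @param subjects number of subjects.
#' @param trials_per_adl trials per (subject, ADL) cell.
#' @param fs sampling rate in Hz.
#' @param seed root seed; all per-trial seeds derive from it.
#' @param out_dir optional output directory.
#' @return List with `manifest` (a [trial_manifest()]), `traces` (named list
#'   keyed by manifest path; `NULL` entries when written to disk),
#'   `annotations` (named list of per-trial annotation frames).
#' @export
generate_protocol <- function(subjects = 10, trials_per_adl = 10, fs = 200,
                              seed = 1, out_dir = NULL) {
  if (subjects < 1 || trials_per_adl < 1) stop("counts must be >= 1")
  subj_amp <- with_seed(derive_seed(seed, 77),
                        stats::rlnorm(subjects, 0, 0.1))
  subj_dur <- with_seed(derive_seed(seed, 78),
                        stats::runif(subjects, 0.8, 1.2))
  rows <- expand.grid(trial = seq_len(trials_per_adl), adl_id = 1:21,
                      subject = seq_len(subjects))
  paths <- sprintf("s%02d_adl%02d_t%02d.csv", rows$subject, rows$adl_id,
                   rows$trial)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  traces <- stats::setNames(vector("list", nrow(rows)), paths)
  anns <- stats::setNames(vector("list", nrow(rows)), paths)
  for (i in seq_len(nrow(rows))) {
    s <- rows$subject[i]
    tr <- generate_trial(rows$adl_id[i], fs = fs,
                         seed = derive_seed(seed, s, rows$adl_id[i],
                                            rows$trial[i]),
                         amp_scale = subj_amp[s], dur_scale = subj_dur[s])
    attr(tr$trace, "meta")$subject <- s
    attr(tr$trace, "meta")$trial <- rows$trial[i]
    anns[[i]] <- tr$annotation
    if (is.null(out_dir)) {
      traces[[i]] <- tr$trace
    } else {
      write_trace(tr$trace, file.path(out_dir, paths[i]))
    }
  }
  mpaths <- if (is.null(out_dir)) paths else file.path(out_dir, paths)
  manifest <- trial_manifest(mpaths, rows$subject, rows$adl_id, rows$trial)
  if (!is.null(out_dir)) {
    names(traces) <- mpaths
    names(anns) <- mpaths
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(manifest = manifest, traces = traces, annotations = anns)
}

# Session building blocks that start and end upright (single classes or
# sit-down/stand-up style pairs).
session_units <- function() {
  list(11L, 12L, 17L, 17L, 20L, c(13L, 14L), c(15L, 16L), c(18L, 19L), 21L)
}

#' Generate a continuous unscripted session
#'
#' A random walk over non-fall activity units (each returning to upright),
#' separated by standing pauses, for `duration_s` seconds. With
#' `embed_falls = 3`, three falling ADLs are inserted at times at least 20 s
#' apart (followed by a get-up recovery); the ground-truth annotation track
#' records each fall's interval.
#'
#' @param duration_s session length in seconds (>= 60).
#' @param embed_falls number of embedded falls, 0 or 3.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param fall_ids pool of fall classes to draw embedded falls from.
#' @return List with `trace`, `annotation` (fall truth intervals:
#'   `start_s, end_s, adl_id, is_fall`) and `script` (the full activity
#'   tiling: `start_s, end_s, adl_id`).
#' @export
generate_session <- function(duration_s, embed_falls = 0, fs = 200, seed = 1,
                             fall_ids = 1:10) {
  if (duration_s < 60) stop("sessions must be at least 60 s")
  if (!embed_falls %in% c(0, 3)) stop("embed_falls must be 0 or 3")
  if (embed_falls == 3 && duration_s < 3 * 20 + 30)
    stop("session too short to place 3 falls 20 s apart")
  profiles <- adl_profiles()
  with_seed(seed, {
    fall_times <- numeric(0)
    if (embed_falls == 3) {
      repeat {
        cand <- sort(stats::runif(3, 15, duration_s - 20))
        if (min(diff(cand)) >= 20) { fall_times <- cand; break }
      }
    }
    segs <- list()
    script <- list()
    ann <- list()
    t_cur <- 0
    theta_cur <- 0
    k_fall <- 1
    session_phi <- stats::runif(1, 0, 360)
    add_unit <- function(phases, theta0, adl, is_fall_unit) {
      # one azimuth for the whole session: a fresh azimuth per unit would
      # rotate the gravity vector discontinuously while the wearer is lying
      r <- render_phases(phases, theta0, session_phi, fs)
      segs[[length(segs) + 1]] <<- r$acc
      script[[length(script) + 1]] <<-
        data.frame(start_s = t_cur, end_s = t_cur + r$duration, adl_id = adl)
      if (is_fall_unit)
        ann[[length(ann) + 1]] <<-
          data.frame(start_s = t_cur + r$fall_start,
                     end_s = t_cur + r$fall_end, adl_id = adl,
                     is_fall = TRUE)
      t_cur <<- t_cur + r$duration
      theta_cur <<- r$theta_end
    }
    while (t_cur < duration_s) {
      if (k_fall <= length(fall_times) && t_cur >= fall_times[k_fall]) {
        id <- sample(fall_ids, 1)
        pr <- profiles[[id]]
        # full scripted phases, entered via a tilt to the start posture:
        # the lead-in static is kept so the posture filter settles to the
        # start posture before the fall, as in the scripted trials
        phases <- instantiate_phases(pr)
        start_th <- runif1(pr$start_theta)
        pre <- list(list(kind = "tilt", dur = stats::runif(1, 1, 2),
                         to = start_th, in_fall = FALSE))
        post <- list(list(kind = "static", dur = stats::runif(1, 2, 3),
                          in_fall = FALSE),
                     list(kind = "tilt", dur = stats::runif(1, 1.5, 2.5),
                          to = 0, in_fall = FALSE))
        add_unit(c(pre, phases, post), theta_cur, id, TRUE)
        k_fall <- k_fall + 1
        # keep the >= 20 s separation even when insertion lags the schedule
        if (k_fall <= length(fall_times))
          fall_times[k_fall] <- max(fall_times[k_fall], t_cur + 20)
      } else {
        unit <- session_units()[[sample.int(length(session_units()), 1)]]
        for (id in unit) {
          pr <- profiles[[id]]
          phases <- instantiate_phases(pr)
          add_unit(phases, theta_cur, id, FALSE)
          if (t_cur >= duration_s) break
        }
        # standing pause between units
        add_unit(list(list(kind = "static",
                           dur = stats::runif(1, 1, 3), in_fall = FALSE)),
                 theta_cur, 21L, FALSE)
      }
    }
    acc <- quantize_12bit(do.call(rbind, segs))
    n_want <- as.integer(round(duration_s * fs))
    acc <- acc[seq_len(min(nrow(acc), n_want)), , drop = FALSE]
    script <- do.call(rbind, script)
    script$end_s <- pmin(script$end_s, nrow(acc) / fs)
    script <- script[script$start_s < script$end_s, ]
    ann <- if (length(ann)) do.call(rbind, ann)
    else data.frame(start_s = numeric(0), end_s = numeric(0),
                    adl_id = integer(0), is_fall = logical(0))
  })
  trace <- accel_trace(acc[, 1], acc[, 2], acc[, 3], fs = fs,
                       meta = list(session = TRUE, seed = seed,
                                   embed_falls = embed_falls))
  list(trace = trace, annotation = ann, script = script)
}
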