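#' Physiological simulation parameters
#'
#' Parameter bundle for the synthetic cohort generator. The orthostatic
#' heart-rate rise after a transition to standing follows first-order
#' kinetics, `delta * (1 - exp(-t / ortho_tau))`, with the per-repetition
#' `delta` drawn from a hydration-state distribution: the defaults of
#' 26 +/- 12 bpm (dehydrated, >= 2% bodyweight loss) versus 14 +/- 8 bpm
#' (euhydrated) are literature-anchored supine-to-stand effect sizes. A
#' participant-level random effect (SD `participant_delta_sd`) is added on
#' top of the per-repetition draws. Post-exercise batteries start with the
#' baseline elevated by `post_exercise_hr_offset`, decaying exponentially
#' with `recovery_tau` over the ~35-min battery, so that baseline-relative
#' features must remove exercise-recovery drift to work.
#'
#' @param resting_hr Mean resting heart rate across participants (bpm).
#' @param resting_hr_sd Between-participant SD of resting heart rate (bpm).
#' @param post_exercise_hr_offset Baseline elevation at the start of a
#'   post-exercise battery (bpm).
#' @param recovery_tau Time constant of exercise-recovery baseline decay (s).
#' @param ortho_delta_hyd_mean,ortho_delta_hyd_sd Euhydrated orthostatic
#'   delta distribution (bpm).
#' @param ortho_delta_deh_mean,ortho_delta_deh_sd Dehydrated orthostatic
#'   delta distribution (bpm).
#' @param participant_delta_sd SD of the participant-level random effect on
#'   the orthostatic delta (bpm).
#' @param ortho_tau First-order rise time constant of the orthostatic
#'   response (s).
#' @param rest_recovery_tau Time constant of the heart-rate return toward
#'   baseline during seated rest (s).
#' @param hr_noise_sd Per-sample Gaussian heart-rate noise (bpm).
#' @param transition_duration Duration of a postural transition (s).
#' @param pitch_noise_sd Per-sample Gaussian pitch noise (degrees).
#' @param hr_rate Heart-rate sampling rate (Hz).
#' @param pitch_rate Pitch sampling rate (Hz).
#'
#' @return A list of class `physio_params`.
#' @examples
#' physio_params()
#' @export
physio_params <- function(resting_hr = 60, resting_hr_sd = 7,
                          post_exercise_hr_offset = 40, recovery_tau = 600,
                          ortho_delta_hyd_mean = 14, ortho_delta_hyd_sd = 8,
                          ortho_delta_deh_mean = 26, ortho_delta_deh_sd = 12,
                          participant_delta_sd = 4,
                          ortho_tau = 20, rest_recovery_tau = 30,
                          hr_noise_sd = 3, transition_duration = 2,
                          pitch_noise_sd = 1, hr_rate = 1, pitch_rate = 100) {
  p <- list(resting_hr = resting_hr, resting_hr_sd = resting_hr_sd,
            post_exercise_hr_offset = post_exercise_hr_offset,
            recovery_tau = recovery_tau,
            ortho_delta_hyd_mean = ortho_delta_hyd_mean,
            ortho_delta_hyd_sd = ortho_delta_hyd_sd,
            ortho_delta_deh_mean = ortho_delta_deh_mean,
            ortho_delta_deh_sd = ortho_delta_deh_sd,
            participant_delta_sd = participant_delta_sd,
            ortho_tau = ortho_tau, rest_recovery_tau = rest_recovery_tau,
            hr_noise_sd = hr_noise_sd, transition_duration = transition_duration,
            pitch_noise_sd = pitch_noise_sd,
            hr_rate = hr_rate, pitch_rate = pitch_rate)
  sds <- c(p$resting_hr_sd, p$ortho_delta_hyd_sd, p$ortho_delta_deh_sd,
           p$participant_delta_sd, p$hr_noise_sd, p$pitch_noise_sd)
  if (any(sds < 0)) stop("physio_params: SDs must be >= 0", call. = FALSE)
  taus <- c(p$recovery_tau, p$ortho_tau, p$rest_recovery_tau,
            p$transition_duration, p$hr_rate, p$pitch_rate)
  if (any(taus <= 0)) {
    stop("physio_params: time constants and rates must be > 0", call. = FALSE)
  }
  class(p) <- "physio_params"
  p
}

#' Simulate a single orthostatic heart-rate response
#'
#' The noiseless model is `HR(t) = baseline + delta * (1 - exp(-t / tau))`
#' with the transition at `t = 0`; iid Gaussian noise is added per sample.
#'
#' @param baseline Pre-transition heart rate (bpm).
#' @param delta Asymptotic orthostatic rise (bpm).
#' @param tau First-order rise time constant (s).
#' @param noise_sd Per-sample Gaussian noise SD (bpm).
#' @param duration Length of the simulated series (s); samples cover
#'   `[0, duration]` at spacing `1/rate`.
#' @param rate Sampling rate (Hz).
#'
#' @return A [sensor_series()] of heart rate.
#' @examples
#' s <- simulate_hr_response(70, 20, tau = 20, noise_sd = 0, duration = 60)
#' s$values[s$time == 20] # 70 + 20 * (1 - exp(-1))
#' @export
simulate_hr_response <- function(baseline, delta, tau, noise_sd = 0,
                                 duration, rate = 1) {
  if (tau <= 0 || rate <= 0) {
    stop("simulate_hr_response: 'tau' and 'rate' must be positive", call. = FALSE)
  }
  if (duration <= 0) stop("simulate_hr_response: 'duration' must be positive", call. = FALSE)
  t <- seq(0, duration, by = 1 / rate)
  v <- baseline + delta * (1 - exp(-t / tau))
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  sensor_series(t, v, nominal_rate = rate, units = "bpm")
}

# smooth posture-change kernel: logistic sigmoid centered at 0 whose
# effective width (1.8%..98.2%) spans 'duration' seconds
transition_sigmoid <- function(t_rel, duration) {
  stats::plogis(t_rel / (duration / 8))
}

#' Simulate a trunk-pitch trace for a movement battery
#'
#' Produces the piecewise-constant posture-angle profile implied by a
#' repetition schedule (convention: trunk-axis angle from vertical —
#' standing 0, supine 90, toe-touch 85, runner's pose 45, seated rest 10
#' degrees), joined by smooth sigmoidal transitions of the stated duration
#' and sampled at the IMU rate, with optional Gaussian noise. The scripted
#' transition time of each posture change is the sigmoid midpoint, where the
#' pitch velocity magnitude peaks.
#'
#' @param schedule Repetition table from [battery_schedule()].
#' @param transition_duration Transition duration (s).
#' @param pitch_noise_sd Per-sample Gaussian noise SD (degrees).
#' @param rate Sampling rate (Hz), 100 by default.
#'
#' @return A [sensor_series()] of pitch covering the half-open battery span
#'   `[start, rest_end)`.
#' @examples
#' tr <- simulate_pitch_trace(battery_schedule(), pitch_noise_sd = 0)
#' @export
simulate_pitch_trace <- function(schedule, transition_duration = 2,
                                 pitch_noise_sd = 0, rate = 100) {
  req <- c("movement_type", "phase1_start", "transition_time", "phase2_end", "rest_end")
  if (!is.data.frame(schedule) || !all(req %in% names(schedule)) || nrow(schedule) == 0L) {
    stop("simulate_pitch_trace: malformed schedule", call. = FALSE)
  }
  sch <- schedule[order(schedule$phase1_start), , drop = FALSE]
  ok_within <- all(sch$phase1_start < sch$transition_time &
                   sch$transition_time < sch$phase2_end &
                   sch$phase2_end <= sch$rest_end)
  ok_between <- nrow(sch) < 2L ||
    all(sch$rest_end[-nrow(sch)] <= sch$phase1_start[-1L])
  if (!ok_within || !ok_between) {
    stop("simulate_pitch_trace: overlapping or inverted schedule phases", call. = FALSE)
  }

  # breakpoints: (center time, level after the change)
  centers <- numeric(0); levels_after <- numeric(0)
  for (i in seq_len(nrow(sch))) {
    a1 <- movement_phase1_angle(sch$movement_type[i])
    if (is.na(a1)) {
      stop(sprintf("simulate_pitch_trace: unknown movement type '%s'",
                   sch$movement_type[i]), call. = FALSE)
    }
    if (i > 1L) { # seated rest -> initial posture
      centers <- c(centers, sch$phase1_start[i]); levels_after <- c(levels_after, a1)
    }
    centers <- c(centers, sch$transition_time[i]); levels_after <- c(levels_after, STAND_ANGLE)
    centers <- c(centers, sch$phase2_end[i]); levels_after <- c(levels_after, SEATED_ANGLE)
  }
  level0 <- movement_phase1_angle(sch$movement_type[1L])

  t0 <- sch$phase1_start[1L]
  t1 <- sch$rest_end[nrow(sch)]
  n <- round((t1 - t0) * rate)
  t <- t0 + (seq_len(n) - 1L) / rate

  # piecewise-constant base, then local sigmoid corrections near each change
  lev <- c(level0, levels_after)
  v <- lev[findInterval(t, centers) + 1L]
  half_support <- 10 * (transition_duration / 8) # plogis(<-80) ~ 0 well below 1e-9
  for (j in seq_along(centers)) {
    dl <- lev[j + 1L] - lev[j]
    if (dl == 0) next
    i0 <- max(1L, ceiling((centers[j] - half_support - t0) * rate) + 1L)
    i1 <- min(n, floor((centers[j] + half_support - t0) * rate) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    tr <- t[idx] - centers[j]
    v[idx] <- v[idx] + dl * (transition_sigmoid(tr, transition_duration) - (tr >= 0))
  }
  if (pitch_noise_sd > 0) v <- v + stats::rnorm(n, 0, pitch_noise_sd)
  sensor_series(t, v, nominal_rate = rate, units = "deg")
}

# orthostatic + recovery heart-rate profile for one battery (noiseless),
# given per-repetition deltas; baseline drift handled by the caller
battery_hr_profile <- function(t, schedule, deltas, ortho_tau, rest_recovery_tau) {
  v <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    tt <- schedule$transition_time[i]
    pe <- schedule$phase2_end[i]
    d <- deltas[i]
    rise <- t >= tt & t < pe
    v[rise] <- v[rise] + d * (1 - exp(-(t[rise] - tt) / ortho_tau))
    peak <- d * (1 - exp(-(pe - tt) / ortho_tau))
    after <- t >= pe & t < pe + 8 * rest_recovery_tau
    v[after] <- v[after] + peak * exp(-(t[after] - pe) / rest_recovery_tau)
  }
  v
}

#' Simulate a synthetic crossover cohort
#'
#' Generates a full two-session crossover study: each participant completes
#' the scripted five-movement battery four times ({no-fluid, fluid-replaced}
#' session x {pre-, post-exercise} timing), yielding 48 repetitions per
#' participant of which the 12 post-exercise no-fluid repetitions are truly
#' dehydrated. Heart-rate and pitch streams are generated per battery;
#' per-repetition orthostatic deltas and labels are recorded as ground truth.
#'
#' Each participant is simulated from an independent RNG substream derived
#' from `seed`, so the same seed reproduces the study bit-for-bit and adding
#' participants never changes earlier participants' data.
#'
#' @param n_participants Number of participants (>= 2).
#' @param params A [physio_params()] bundle.
#' @param seed Integer seed for the cohort.
#' @param signals If `FALSE`, skip generating the sensor streams and return
#'   only the ground-truth design (participant attributes and per-repetition
#'   deltas, identical to those underlying the full simulation); useful for
#'   checking the sampling distributions at large n.
#'
#' @return An object of class `synthetic_study`: a list with `participants`
#'   (data.frame of id, resting HR, random effect), `sessions` (list of
#'   [sensor_session()], one per battery; 4 per participant), and
#'   `ground_truth` (data.frame with one row per repetition: ids, session
#'   type, timing, movement, repetition, true orthostatic delta, label).
#' @examples
#' study <- simulate_cohort(2, seed = 1)
#' study
#' @export
simulate_cohort <- function(n_participants, params = physio_params(), seed = 1,
                            signals = TRUE) {
  if (!inherits(params, "physio_params")) {
    stop("simulate_cohort: 'params' must come from physio_params()", call. = FALSE)
  }
  if (n_participants < 2) {
    stop("simulate_cohort: need at least 2 participants", call. = FALSE)
  }
  sched <- battery_schedule()
  batteries <- expand.grid(session_type = c("NO_FLUID", "FLUID_REPLACED"),
                           timing = c("PRE_EXERCISE", "POST_EXERCISE"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  participants <- vector("list", n_participants)
  sessions <- list()
  truth <- vector("list", n_participants)

  for (p in seq_len(n_participants)) {
    set.seed((seed * 10007L + p) %% 2147483647L)
    resting <- stats::rnorm(1, params$resting_hr, params$resting_hr_sd)
    ranef <- stats::rnorm(1, 0, params$participant_delta_sd)
    participants[[p]] <- data.frame(id = p, resting_hr = resting,
                                    delta_ranef = ranef)

    # draw all per-repetition deltas first so the design is identical
    # whether or not signal noise is generated afterwards
    gt_p <- vector("list", nrow(batteries))
    for (b in seq_len(nrow(batteries))) {
      st <- batteries$session_type[b]; tm <- batteries$timing[b]
      lab <- hydration_label(st, tm)
      if (lab == "DEHYDRATED") {
        mu <- params$ortho_delta_deh_mean; sdv <- params$ortho_delta_deh_sd
      } else {
        mu <- params$ortho_delta_hyd_mean; sdv <- params$ortho_delta_hyd_sd
      }
      deltas <- stats::rnorm(nrow(sched), mu, sdv) + ranef
      gt_p[[b]] <- data.frame(
        participant_id = p, session_type = st, timing = tm,
        movement_type = sched$movement_type, repetition = sched$repetition,
        true_delta = deltas, label = lab, stringsAsFactors = FALSE
      )
    }
    truth[[p]] <- do.call(rbind, gt_p)

    if (signals) {
      for (b in seq_len(nrow(batteries))) {
        st <- batteries$session_type[b]; tm <- batteries$timing[b]
        deltas <- gt_p[[b]]$true_delta
        span <- c(sched$phase1_start[1L], sched$rest_end[nrow(sched)])
        t_hr <- seq(span[1L], span[2L] - 1 / params$hr_rate, by = 1 / params$hr_rate)
        base <- rep(resting, length(t_hr))
        if (tm == "POST_EXERCISE") {
          base <- base + params$post_exercise_hr_offset *
            exp(-(t_hr - span[1L]) / params$recovery_tau)
        }
        hr_v <- base + battery_hr_profile(t_hr, sched, deltas,
                                          params$ortho_tau, params$rest_recovery_tau)
        if (params$hr_noise_sd > 0) {
          hr_v <- hr_v + stats::rnorm(length(hr_v), 0, params$hr_noise_sd)
        }
        hr <- sensor_series(t_hr, hr_v, nominal_rate = params$hr_rate, units = "bpm")
        pitch <- simulate_pitch_trace(sched, params$transition_duration,
                                      params$pitch_noise_sd, params$pitch_rate)
        sessions[[length(sessions) + 1L]] <-
          sensor_session(p, st, tm, hr = hr, pitch = pitch, schedule = sched)
      }
    }
  }

  structure(
    list(participants = do.call(rbind, participants),
         sessions = sessions,
         ground_truth = do.call(rbind, truth),
         params = params, seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants, %d battery recordings, %d repetition windows (%d dehydrated), seed %d\n",
              nrow(x$participants), length(x$sessions), nrow(x$ground_truth),
              sum(x$ground_truth$label == "DEHYDRATED"), x$seed))
  invisible(x)
}
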