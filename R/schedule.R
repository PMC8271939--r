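#' The scripted postural-movement battery
#'
#' The protocol battery consists of five movements performed in a fixed order,
#' each repeated a set number of times. A repetition holds an initial posture
#' (phase 1), transitions to standing, stands (phase 2), and is followed by
#' 1 min of seated rest. Durations are in seconds.
#'
#' @return A data.frame with one row per movement: `movement_type`,
#'   `phase1_duration`, `phase2_duration`, `repetitions`, `inter_rep_rest`.
#' @examples
#' movement_specs()
#' @export
movement_specs <- function() {
  data.frame(
    movement_type = c("SUPINE_STAND_2MIN", "SUPINE_STAND_1MIN", "TOE_TOUCH_2MIN",
                      "TOE_TOUCH_30S", "RUNNER_POSE_30S"),
    phase1_duration = c(120, 60, 120, 30, 30),
    phase2_duration = c(60, 60, 60, 30, 30),
    repetitions = c(3L, 1L, 2L, 3L, 3L),
    inter_rep_rest = rep(60, 5L),
    stringsAsFactors = FALSE
  )
}

# initial posture angle (degrees of trunk axis from vertical) per movement;
# standing = 0, seated rest = 10 by convention
movement_phase1_angle <- function(movement_type) {
  angles <- c(SUPINE_STAND_2MIN = 90, SUPINE_STAND_1MIN = 90,
              TOE_TOUCH_2MIN = 85, TOE_TOUCH_30S = 85, RUNNER_POSE_30S = 45)
  unname(angles[movement_type])
}

STAND_ANGLE <- 0
SEATED_ANGLE <- 10

#' Enumerate the repetitions of one movement battery
#'
#' Lays out the five-movement battery on a time axis, one row per repetition.
#' The scripted transition to standing sits at the end of phase 1; each
#' repetition is followed by the seated rest, which is included in the
#' battery's span.
#'
#' @param start Battery start time in seconds (default 0).
#' @param specs Movement table as returned by [movement_specs()].
#'
#' @return A data.frame with one row per repetition (12 rows for the default
#'   battery): `movement_type`, `repetition`, `phase1_start`,
#'   `transition_time` (scripted), `phase2_end`, `rest_end`,
#'   `phase2_duration`.
#' @examples
#' sched <- battery_schedule()
#' nrow(sched)   # 12 repetitions
#' @export
battery_schedule <- function(start = 0, specs = movement_specs()) {
  required <- c("movement_type", "phase1_duration", "phase2_duration",
                "repetitions", "inter_rep_rest")
  if (!all(required %in% names(specs))) {
    stop("battery_schedule: malformed movement specs", call. = FALSE)
  }
  rows <- vector("list", sum(specs$repetitions))
  t <- start
  k <- 0L
  for (m in seq_len(nrow(specs))) {
    for (r in seq_len(specs$repetitions[m])) {
      k <- k + 1L
      transition <- t + specs$phase1_duration[m]
      phase2_end <- transition + specs$phase2_duration[m]
      rest_end <- phase2_end + specs$inter_rep_rest[m]
      rows[[k]] <- data.frame(
        movement_type = specs$movement_type[m],
        repetition = r,
        phase1_start = t,
        transition_time = transition,
        phase2_end = phase2_end,
        rest_end = rest_end,
        phase2_duration = specs$phase2_duration[m],
        stringsAsFactors = FALSE
      )
      t <- rest_end
    }
  }
  do.call(rbind, rows)
}

#' Construct a sensor session
#'
#' One continuous recording of a participant performing a full postural
#' battery: paired heart-rate and trunk-pitch streams plus the repetition
#' schedule. A participant contributes four sessions to a full crossover
#' study: {no-fluid, fluid-replaced} x {pre-exercise, post-exercise}.
#'
#' @param participant_id Integer participant identifier.
#' @param session_type `"NO_FLUID"` or `"FLUID_REPLACED"`.
#' @param timing `"PRE_EXERCISE"` or `"POST_EXERCISE"`.
#' @param hr Heart-rate [sensor_series()] (bpm).
#' @param pitch Trunk-pitch [sensor_series()] (degrees from vertical).
#' @param schedule Repetition table from [battery_schedule()].
#'
#' @return An object of class `sensor_session`.
#' @export
sensor_session <- function(participant_id, session_type, timing, hr, pitch, schedule) {
  session_type <- match.arg(session_type, c("NO_FLUID", "FLUID_REPLACED"))
  timing <- match.arg(timing, c("PRE_EXERCISE", "POST_EXERCISE"))
  stopifnot(inherits(hr, "sensor_series"), inherits(pitch, "sensor_series"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0L) {
    stop("sensor_session: empty schedule", call. = FALSE)
  }
  span_needed <- c(min(schedule$phase1_start), max(schedule$phase2_end))
  for (nm in c("hr", "pitch")) {
    s <- if (nm == "hr") hr else pitch
    sp <- series_span(s)
    if (sp[1L] > span_needed[1L] || sp[2L] < span_needed[2L] - 1 / s$nominal_rate) {
      stop(sprintf("sensor_session: %s stream does not cover the scheduled span", nm),
           call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.integer(participant_id),
         session_type = session_type, timing = timing,
         hr = hr, pitch = pitch, schedule = schedule),
    class = "sensor_session"
  )
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("<sensor_session> participant %d, %s / %s: %d repetitions, %d HR + %d pitch samples\n",
              x$participant_id, x$session_type, x$timing, nrow(x$schedule),
              length(x$hr), length(x$pitch)))
  invisible(x)
}

# hydration label implied by the crossover design: dehydrated iff the battery
# follows exercise in the no-fluid session
hydration_label <- function(session_type, timing) {
  ifelse(session_type == "NO_FLUID" & timing == "POST_EXERCISE",
         "DEHYDRATED", "EUHYDRATED")
}
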