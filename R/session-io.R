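#' Read and write sensor sessions as plain text
#'
#' A session on disk is a directory holding `hr.csv` (`time_s,hr_bpm`),
#' `pitch.csv` (`time_s,pitch_deg`) and `schedule.yaml` (session metadata and
#' the repetition table). Values round-trip to better than 1e-9 relative
#' error; timestamps are re-validated as strictly increasing on read, and the
#' streams must cover the scheduled span.
#'
#' @param session A `sensor_session`.
#' @param dir Directory to write to (created if needed).
#' @return `write_sensor_session` returns `dir` invisibly;
#'   `read_sensor_session` returns a `sensor_session`.
#' @examples
#' \donttest{
#' study <- simulate_cohort(2, seed = 1)
#' d <- file.path(tempdir(), "sess1")
#' write_sensor_session(study$sessions[[1]], d)
#' s2 <- read_sensor_session(d)
#' }
#' @export
write_sensor_session <- function(session, dir) {
  stopifnot(inherits(session, "sensor_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_channel <- function(s, path, value_name) {
    df <- data.frame(time_s = format(s$time, digits = 17, trim = TRUE, scientific = FALSE))
    df[[value_name]] <- format(s$values, digits = 17, trim = TRUE, scientific = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_channel(session$hr, file.path(dir, "hr.csv"), "hr_bpm")
  write_channel(session$pitch, file.path(dir, "pitch.csv"), "pitch_deg")
  meta <- list(
    participant_id = session$participant_id,
    session_type = session$session_type,
    timing = session$timing,
    hr_rate_hz = session$hr$nominal_rate,
    pitch_rate_hz = session$pitch$nominal_rate,
    schedule = lapply(seq_len(nrow(session$schedule)), function(i) {
      as.list(session$schedule[i, c("movement_type", "repetition", "phase1_start",
                                    "transition_time", "phase2_end", "rest_end",
                                    "phase2_duration")])
    })
  )
  yaml::write_yaml(meta, file.path(dir, "schedule.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_sensor_session
#' @export
read_sensor_session <- function(dir) {
  paths <- file.path(dir, c("hr.csv", "pitch.csv", "schedule.yaml"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop(sprintf("read_sensor_session: missing file(s): %s",
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  }
  meta <- yaml::read_yaml(paths[3L])
  sched <- do.call(rbind, lapply(meta$schedule, function(r) {
    data.frame(movement_type = r$movement_type, repetition = as.integer(r$repetition),
               phase1_start = as.numeric(r$phase1_start),
               transition_time = as.numeric(r$transition_time),
               phase2_end = as.numeric(r$phase2_end),
               rest_end = as.numeric(r$rest_end),
               phase2_duration = as.numeric(r$phase2_duration),
               stringsAsFactors = FALSE)
  }))
  read_channel <- function(path, value_name, rate, units) {
    df <- utils::read.csv(path)
    if (!all(c("time_s", value_name) %in% names(df))) {
      stop(sprintf("read_sensor_session: %s lacks columns time_s,%s",
                   basename(path), value_name), call. = FALSE)
    }
    sensor_series(df$time_s, df[[value_name]], nominal_rate = rate, units = units)
  }
  hr <- read_channel(paths[1L], "hr_bpm", meta$hr_rate_hz, "bpm")
  pitch <- read_channel(paths[2L], "pitch_deg", meta$pitch_rate_hz, "deg")
  sensor_session(meta$participant_id, meta$session_type, meta$timing,
                 hr = hr, pitch = pitch, schedule = sched)
}
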