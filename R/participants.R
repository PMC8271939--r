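#' Read a participant characteristics table
#'
#' Parses a comma-delimited participant table with columns ID, Age, Sex,
#' Height, InitialBW_DEH, PctBWLost, InitialBW_HYD, BMI, PFA1, PFA2, PARQ,
#' VO2max. Bodyweights are nude weights in kg; `InitialBW_DEH` is the weight
#' at the start of the dehydrated (no-fluid) session and `PctBWLost` the
#' percent of that weight lost to unreplenished sweat during exercise.
#'
#' Structural problems (missing columns, non-numeric masses, sex outside
#' M/F, percent loss outside (0, 10)) are errors naming the offending
#' row/column. A BMI that disagrees with `InitialBW_DEH / (Height/100)^2` by
#' more than 15% is a consistency warning only, since the printed BMI may be
#' self-reported.
#'
#' @param path Path to the delimited text file.
#' @return A data.frame of class `participant_table`, one row per
#'   participant, with lower-cased canonical column names (`id`, `age`,
#'   `sex`, `height`, `initial_bw_deh`, `pct_bw_lost`, `initial_bw_hyd`,
#'   `bmi`, `pfa1`, `pfa2`, `parq`, `vo2max`).
#' @examples
#' tab <- read_participant_table(
#'   system.file("extdata", "table1_participants.csv", package = "hydrostatus"))
#' nrow(tab)
#' table(tab$sex)
#' @export
read_participant_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_participant_table: file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop(sprintf("read_participant_table: parse error: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  expected <- c(ID = "id", Age = "age", Sex = "sex", Height = "height",
                InitialBW_DEH = "initial_bw_deh", PctBWLost = "pct_bw_lost",
                InitialBW_HYD = "initial_bw_hyd", BMI = "bmi",
                PFA1 = "pfa1", PFA2 = "pfa2", PARQ = "parq", VO2max = "vo2max")
  missing_cols <- setdiff(names(expected), names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("read_participant_table: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("read_participant_table: no data rows", call. = FALSE)
  }
  tab <- raw[, names(expected)]
  names(tab) <- unname(expected)

  numeric_cols <- setdiff(names(expected), "Sex")
  for (i in seq_along(expected)) {
    orig <- names(expected)[i]; canon <- expected[[i]]
    if (orig == "Sex") next
    v <- suppressWarnings(as.numeric(tab[[canon]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("read_participant_table: non-numeric value in column '%s', row %d",
                   orig, bad[1L]), call. = FALSE)
    }
    tab[[canon]] <- v
  }
  bad_sex <- which(!tab$sex %in% c("M", "F"))
  if (length(bad_sex) > 0L) {
    stop(sprintf("read_participant_table: sex outside {M, F} in row %d", bad_sex[1L]),
         call. = FALSE)
  }
  bad_mass <- which(tab$initial_bw_deh <= 0 | tab$initial_bw_hyd <= 0)
  if (length(bad_mass) > 0L) {
    stop(sprintf("read_participant_table: non-positive bodyweight in row %d",
                 bad_mass[1L]), call. = FALSE)
  }
  bad_pct <- which(tab$pct_bw_lost <= 0 | tab$pct_bw_lost >= 10)
  if (length(bad_pct) > 0L) {
    stop(sprintf("read_participant_table: percent bodyweight lost outside (0, 10) in row %d",
                 bad_pct[1L]), call. = FALSE)
  }
  implied_bmi <- tab$initial_bw_deh / (tab$height / 100)^2
  off <- which(abs(implied_bmi - tab$bmi) / implied_bmi > 0.15)
  for (i in off) {
    warning(sprintf(
      "participant %d: printed BMI %.1f differs from weight/height^2 (%.1f) by > 15%%",
      tab$id[i], tab$bmi[i], implied_bmi[i]), call. = FALSE)
  }
  tab$id <- as.integer(tab$id)
  class(tab) <- c("participant_table", "data.frame")
  tab
}
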