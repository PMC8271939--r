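#' Post-exercise bodyweight from percent loss
#'
#' Percent bodyweight lost is defined relative to the initial nude weight, so
#' the post-exercise weight is `initial_bw * (1 - pct_lost / 100)`.
#'
#' @param initial_bw Initial nude bodyweight in kg (vectorised).
#' @param pct_lost Percent of initial bodyweight lost, in `[0, 100)`.
#' @return Post-exercise bodyweight in kg.
#' @examples
#' post_exercise_weight(100, 2)      # 98
#' post_exercise_weight(85.60, 1.52) # 84.30 (2 d.p.)
#' @export
post_exercise_weight <- function(initial_bw, pct_lost) {
  if (any(initial_bw < 0) || any(pct_lost < 0)) {
    stop("post_exercise_weight: negative input", call. = FALSE)
  }
  if (any(pct_lost >= 100)) {
    stop("post_exercise_weight: percent lost must be < 100", call. = FALSE)
  }
  initial_bw * (1 - pct_lost / 100)
}

#' Summarize a participant cohort
#'
#' Computes the cohort summaries reported for a crossover dehydration study:
#' by-sex mean and SD of initial bodyweight at the dehydrated session, of the
#' derived post-exercise bodyweight, and of estimated VO2max, plus the overall
#' mean and SD of percent bodyweight lost. All SDs use the sample (n - 1)
#' convention; values are kept at full precision and rounded only when
#' printed.
#'
#' @param records A `participant_table` from [read_participant_table()] (or
#'   any data.frame with its canonical columns).
#' @return An object of class `cohort_summary`: a list with `by_sex` (a
#'   data.frame keyed by sex with `n` and the mean/SD columns),
#'   `pct_lost_mean`, `pct_lost_sd` and `n`. Groups with a single member get
#'   SD 0 and are flagged in `degenerate_sd`; empty groups are omitted with a
#'   warning.
#' @examples
#' tab <- read_participant_table(
#'   system.file("extdata", "table1_participants.csv", package = "hydrostatus"))
#' summarize_cohort(tab)
#' @export
summarize_cohort <- function(records) {
  needed <- c("sex", "initial_bw_deh", "pct_bw_lost", "vo2max")
  if (!all(needed %in% names(records))) {
    stop("summarize_cohort: records lack required columns", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("summarize_cohort: no records", call. = FALSE)
  }
  sd1 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  post_bw <- post_exercise_weight(records$initial_bw_deh, records$pct_bw_lost)

  sexes <- c("M", "F")
  present <- sexes[sexes %in% records$sex]
  for (s in setdiff(sexes, present)) {
    warning(sprintf("summarize_cohort: no records for sex %s; group omitted", s),
            call. = FALSE)
  }
  by_sex <- do.call(rbind, lapply(present, function(s) {
    idx <- records$sex == s
    data.frame(
      sex = s, n = sum(idx),
      initial_bw_mean = mean(records$initial_bw_deh[idx]),
      initial_bw_sd = sd1(records$initial_bw_deh[idx]),
      post_bw_mean = mean(post_bw[idx]),
      post_bw_sd = sd1(post_bw[idx]),
      vo2max_mean = mean(records$vo2max[idx]),
      vo2max_sd = sd1(records$vo2max[idx]),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(by_sex = by_sex,
         pct_lost_mean = mean(records$pct_bw_lost),
         pct_lost_sd = sd1(records$pct_bw_lost),
         n = nrow(records),
         degenerate_sd = by_sex$sex[by_sex$n < 2L]),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort of %d participants\n", x$n))
  cat(sprintf("  Percent bodyweight lost: %.1f%% +/- %.1f%%\n",
              x$pct_lost_mean, x$pct_lost_sd))
  for (i in seq_len(nrow(x$by_sex))) {
    r <- x$by_sex[i, ]
    cat(sprintf("  %s (n = %d): %.1f +/- %.1f kg pre, %.1f +/- %.1f kg post exercise; VO2max %.1f +/- %.2f\n",
                r$sex, r$n, r$initial_bw_mean, r$initial_bw_sd,
                r$post_bw_mean, r$post_bw_sd, r$vo2max_mean, r$vo2max_sd))
  }
  if (length(x$degenerate_sd) > 0L) {
    cat(sprintf("  (single-member group(s) %s: SD reported as 0)\n",
                paste(x$degenerate_sd, collapse = ", ")))
  }
  invisible(x)
}
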