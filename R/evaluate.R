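#' Area under the ROC curve (Mann-Whitney form)
#'
#' Over all positive-negative pairs, counts 1 when the positive scores
#' higher, 0.5 for a tie, and divides by `n_pos * n_neg` — the probability
#' of ranking a random positive above a random negative. Computed from
#' midranks, which is algebraically identical to the pairwise count.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Labels (logical, 0/1, or character/factor with `positive`).
#' @param positive Positive class for character/factor labels.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0)) # 0.75
#' @export
auroc <- function(scores, labels, positive = "DEHYDRATED") {
  y <- as_binary_labels(labels, positive)
  if (length(scores) != length(y)) {
    stop("auroc: 'scores' and 'labels' lengths differ", call. = FALSE)
  }
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop(errorCondition("auroc: undefined with a single class present",
                        class = c("hydrostatus_undefined_auroc", "error", "condition")))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' First and third quartiles
#'
#' Quartiles by linear interpolation of the order statistics (quantile
#' positions `p * (n - 1) + 1`, i.e. R's default type-7 rule).
#'
#' @param values Numeric vector (at least one value).
#' @return Numeric `c(q1, q3)`.
#' @examples
#' iqr_bounds(1:4) # 1.75 3.25
#' @export
iqr_bounds <- function(values) {
  if (length(values) == 0L) stop("iqr_bounds: empty input", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1L], q3 = q[2L])
}

MOVEMENT_TYPES <- c("SUPINE_STAND_2MIN", "SUPINE_STAND_1MIN", "TOE_TOUCH_2MIN",
                    "TOE_TOUCH_30S", "RUNNER_POSE_30S")

#' Leave-one-participant-out evaluation
#'
#' For each participant P: selects the regularization strength by inner
#' cross-validation on the other participants' data, fits on all of their
#' repetitions (pre- and post-exercise), and scores P's post-exercise
#' repetitions matching `movement_filter`. Evaluation is restricted to
#' post-exercise movements so the model is judged on the effect of
#' dehydration rather than of exercise. AUROC per participant treats
#' dehydrated rows as positives; the mean and interquartile range are taken
#' across participants. A participant whose filtered test set lacks one of
#' the classes is reported as skipped, never silently folded into the mean.
#'
#' @param dataset A `hyd_dataset` from [build_labeled_dataset()] (or any
#'   data.frame with `participant_id`, `session_type`, `timing`,
#'   `movement_type`, `label` and the feature columns).
#' @param movement_filter `"ALL"` or a subset of the five movement types.
#' @param reg_grid Candidate regularization strengths.
#' @param feature_cols Feature columns to use.
#' @return An object of class `lopo_eval`: list with `per_participant`
#'   (data.frame: participant, AUROC, n_pos, n_neg, selected C),
#'   `mean_auroc`, `iqr`, `movement_filter`, `skipped`.
#' @export
lopo_evaluate <- function(dataset, movement_filter = "ALL",
                          reg_grid = 10^(-3:3),
                          feature_cols = c("d1", "d2", "d3")) {
  parts <- unique(dataset$participant_id)
  if (length(parts) < 3L) {
    stop("lopo_evaluate: need at least 3 participants", call. = FALSE)
  }
  if (!identical(movement_filter, "ALL")) {
    bad <- setdiff(movement_filter, MOVEMENT_TYPES)
    if (length(bad) > 0L) {
      stop(sprintf("lopo_evaluate: unknown movement type(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  in_filter <- if (identical(movement_filter, "ALL")) {
    rep(TRUE, nrow(dataset))
  } else {
    dataset$movement_type %in% movement_filter
  }
  test_pool <- dataset$timing == "POST_EXERCISE" & in_filter
  if (!any(test_pool)) {
    stop("lopo_evaluate: movement filter matches no post-exercise rows", call. = FALSE)
  }

  res <- vector("list", length(parts))
  skipped <- integer(0)
  for (k in seq_along(parts)) {
    p <- parts[k]
    hold <- dataset$participant_id == p
    train <- dataset[!hold, , drop = FALSE]
    test <- dataset[hold & test_pool, , drop = FALSE]
    y_test <- as_binary_labels(test$label, "DEHYDRATED")
    if (nrow(test) == 0L || length(unique(y_test)) < 2L) {
      skipped <- c(skipped, p)
      next
    }
    C <- select_regularization(train, grid = reg_grid, feature_cols = feature_cols)
    fit <- fit_logistic(train[, feature_cols, drop = FALSE], train$label, C = C)
    sc <- predict(fit, test[, feature_cols, drop = FALSE])
    res[[k]] <- data.frame(participant_id = p,
                           auroc = auroc(sc, y_test),
                           n_pos = sum(y_test == 1L), n_neg = sum(y_test == 0L),
                           C = as.numeric(C))
  }
  per <- do.call(rbind, res)
  if (is.null(per) || nrow(per) == 0L) {
    stop("lopo_evaluate: no participant had both classes after filtering", call. = FALSE)
  }
  structure(
    list(per_participant = per,
         mean_auroc = mean(per$auroc),
         iqr = iqr_bounds(per$auroc),
         movement_filter = movement_filter,
         skipped = skipped,
         feature_cols = feature_cols),
    class = "lopo_eval"
  )
}

#' @export
print.lopo_eval <- function(x, ...) {
  filt <- paste(x$movement_filter, collapse = "+")
  cat(sprintf("Leave-one-participant-out evaluation (%s)\n", filt))
  cat(sprintf("  mean AUROC: %.2f (IQR: %.2f, %.2f) across %d participants\n",
              x$mean_auroc, x$iqr[["q1"]], x$iqr[["q3"]], nrow(x$per_participant)))
  if (length(x$skipped) > 0L) {
    cat(sprintf("  skipped (single-class test set): %s\n",
                paste(x$skipped, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.lopo_eval <- function(object, ...) {
  print(object)
  cat("  per participant:\n")
  print(object$per_participant, row.names = FALSE)
  invisible(object)
}

#' Per-movement evaluation table
#'
#' Runs [lopo_evaluate()] for the pooled post-exercise set (`ALL`) and for
#' each of the five scripted movements, returning one summary row per
#' filter.
#'
#' @inheritParams lopo_evaluate
#' @return A data.frame with columns `movement_filter`, `mean_auroc`, `q1`,
#'   `q3`, `n_participants`, `n_skipped`.
#' @export
lopo_by_movement <- function(dataset, reg_grid = 10^(-3:3),
                             feature_cols = c("d1", "d2", "d3")) {
  filters <- c("ALL", MOVEMENT_TYPES)
  do.call(rbind, lapply(filters, function(f) {
    ev <- lopo_evaluate(dataset, movement_filter = f, reg_grid = reg_grid,
                        feature_cols = feature_cols)
    data.frame(movement_filter = f, mean_auroc = ev$mean_auroc,
               q1 = ev$iqr[["q1"]], q3 = ev$iqr[["q3"]],
               n_participants = nrow(ev$per_participant),
               n_skipped = length(ev$skipped),
               stringsAsFactors = FALSE)
  }))
}
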