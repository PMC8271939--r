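#' Shapley feature importance with AUROC as the value function
#'
#' Quantifies each feature's contribution to held-out discriminative
#' performance. For every held-out participant (leave-one-participant-out,
#' with the regularization strength selected on that fold's training data)
#' and every feature coalition `S`, the value `v(S)` is the AUROC on the
#' participant's post-exercise repetitions of a model refit on the training
#' participants using only the features in `S`; the empty coalition is
#' assigned chance performance, `v(empty) = 0.5`. Shapley values are
#' computed by exact enumeration of all `2^p` coalitions, and their mean and
#' SD across held-out participants are reported. By construction the values
#' satisfy efficiency (they sum to `v(all) - 0.5` per participant) and
#' symmetry.
#'
#' @inheritParams lopo_evaluate
#' @return An object of class `shapley_report`: list with `per_participant`
#'   (matrix of Shapley values, participants x features), `v_full` (each
#'   participant's full-coalition AUROC, so efficiency
#'   `sum(phi) = v_full - 0.5` can be verified), `mean`, `sd`,
#'   `value_function` descriptor, `skipped`.
#' @export
shapley_importance <- function(dataset, reg_grid = 10^(-3:3),
                               feature_cols = c("d1", "d2", "d3")) {
  parts <- unique(dataset$participant_id)
  if (length(parts) < 3L) {
    stop("shapley_importance: need at least 3 participants", call. = FALSE)
  }
  p <- length(feature_cols)
  subsets <- subset_masks(p)
  weights <- shapley_weights(p)

  phi_rows <- list()
  v_full <- numeric(0)
  skipped <- integer(0)
  for (part in parts) {
    hold <- dataset$participant_id == part
    train <- dataset[!hold, , drop = FALSE]
    test <- dataset[hold & dataset$timing == "POST_EXERCISE", , drop = FALSE]
    y_test <- as_binary_labels(test$label, "DEHYDRATED")
    if (nrow(test) == 0L || length(unique(y_test)) < 2L) {
      skipped <- c(skipped, part)
      next
    }
    C <- select_regularization(train, grid = reg_grid, feature_cols = feature_cols)
    v <- vapply(subsets, function(S) {
      if (length(S) == 0L) return(0.5)
      cols <- feature_cols[S]
      fit <- fit_logistic(train[, cols, drop = FALSE], train$label, C = C)
      auroc(predict(fit, test[, cols, drop = FALSE]), y_test)
    }, numeric(1))
    phi <- vapply(seq_len(p), function(i) {
      total <- 0
      for (s in seq_along(subsets)) {
        S <- subsets[[s]]
        if (i %in% S) next
        with_i <- subset_index(subsets, sort(c(S, i)))
        total <- total + weights[length(S) + 1L] * (v[with_i] - v[s])
      }
      total
    }, numeric(1))
    phi_rows[[length(phi_rows) + 1L]] <- stats::setNames(phi, feature_cols)
    names(phi_rows)[length(phi_rows)] <- as.character(part)
    v_full <- c(v_full, v[length(v)])
  }
  if (length(phi_rows) == 0L) {
    stop("shapley_importance: no participant had both classes post-exercise",
         call. = FALSE)
  }
  mat <- do.call(rbind, phi_rows)
  structure(
    list(per_participant = mat,
         v_full = stats::setNames(v_full, rownames(mat)),
         mean = colMeans(mat),
         sd = apply(mat, 2L, stats::sd),
         value_function = "held-out AUROC; v(empty) = 0.5 (chance)",
         skipped = skipped,
         feature_cols = feature_cols),
    class = "shapley_report"
  )
}

# all subsets of 1..p as integer vectors, empty set first
subset_masks <- function(p) {
  out <- list(integer(0))
  for (size in seq_len(p)) {
    out <- c(out, utils::combn(p, size, simplify = FALSE))
  }
  out
}

subset_index <- function(subsets, S) {
  for (s in seq_along(subsets)) {
    if (length(subsets[[s]]) == length(S) && all(subsets[[s]] == S)) return(s)
  }
  stop("internal: subset not found")
}

# marginal-contribution weight |S|! (p - |S| - 1)! / p! indexed by |S| + 1
shapley_weights <- function(p) {
  s <- 0:(p - 1L)
  factorial(s) * factorial(p - s - 1L) / factorial(p)
}

#' @export
print.shapley_report <- function(x, ...) {
  cat("Shapley feature importance (value function:", x$value_function, ")\n")
  df <- data.frame(feature = names(x$mean),
                   mean = round(x$mean, 3), sd = round(x$sd, 3))
  print(df, row.names = FALSE)
  cat(sprintf("  across %d held-out participants\n", nrow(x$per_participant)))
  if (length(x$skipped) > 0L) {
    cat(sprintf("  skipped: %s\n", paste(x$skipped, collapse = ", ")))
  }
  invisible(x)
}
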