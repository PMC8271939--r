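#' L2-regularized logistic regression
#'
#' Fits the binary classifier used throughout the pipeline by minimizing
#' \deqn{\sum_i \log(1 + e^{-y_i (w \cdot x_i + b)}) + \frac{1}{2C} \|w\|^2,}
#' with `y in {-1, +1}`, the intercept unpenalized, and features
#' standardized by the training mean and SD (so a single regularization
#' strength `C` is meaningful across features of different magnitudes). The
#' objective is strictly convex in `w`, so the fit is deterministic: damped
#' Newton iterations from zero, stopping when the gradient norm is at most
#' `tol`.
#'
#' @param x Numeric matrix or data.frame of features (n x p).
#' @param y Labels: logical, 0/1 numeric, or character/factor, with
#'   `positive` naming the positive class for non-logical input.
#' @param C Regularization strength (larger = weaker penalty), positive.
#' @param positive Positive class label (default `"DEHYDRATED"`), used when
#'   `y` is character or factor.
#' @param standardize Standardize features by training mean/SD (default
#'   TRUE). A zero-variance feature gets SD 1 with a warning.
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#'
#' @return An object of class `hyd_logit` with elements `weights` (on the
#'   standardized scale), `intercept`, `C`, `center`, `scale`,
#'   `feature_names`, `fitted` (training scores), `y` (training labels as
#'   0/1), `objective`, `grad_norm`, `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), ncol = 3)
#' y <- rbinom(20, 1, plogis(x[, 3]))
#' fit <- fit_logistic(x, y, C = 1)
#' coef(fit)
#' @export
fit_logistic <- function(x, y, C = 1, positive = "DEHYDRATED",
                         standardize = TRUE, tol = 1e-8, max_iter = 200L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("fit_logistic: 'C' must be a single positive number", call. = FALSE)
  }
  y01 <- as_binary_labels(y, positive)
  n <- nrow(x)
  if (n != length(y01)) stop("fit_logistic: nrow(x) != length(y)", call. = FALSE)
  if (n < 2L) stop("fit_logistic: need at least 2 observations", call. = FALSE)
  if (length(unique(y01)) < 2L) {
    stop("fit_logistic: both classes must be present in the training labels",
         call. = FALSE)
  }
  p <- ncol(x)
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))

  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    zero_var <- scl == 0
    if (any(zero_var)) {
      warning(sprintf("fit_logistic: zero-variance feature(s) %s; SD set to 1",
                      paste(feature_names[zero_var], collapse = ", ")),
              call. = FALSE)
      scl[zero_var] <- 1
    }
  } else {
    center <- rep(0, p); scl <- rep(1, p)
  }
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scl, "/")
  ys <- ifelse(y01 == 1, 1, -1)

  # log(1 + exp(z)), overflow-safe
  log1pexp <- function(z) ifelse(z > 33, z, log1p(exp(z)))
  objective <- function(theta) {
    eta <- theta[1L] + drop(xs %*% theta[-1L])
    sum(log1pexp(-ys * eta)) + sum(theta[-1L]^2) / (2 * C)
  }
  gradient <- function(theta) {
    eta <- theta[1L] + drop(xs %*% theta[-1L])
    mu <- stats::plogis(-ys * eta)           # d/deta of loss = -y * mu
    g_eta <- -ys * mu
    c(sum(g_eta), drop(crossprod(xs, g_eta)) + theta[-1L] / C)
  }

  theta <- rep(0, p + 1L)
  obj <- objective(theta)
  iter <- 0L
  converged <- FALSE
  repeat {
    g <- gradient(theta)
    if (sqrt(sum(g^2)) <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    eta <- theta[1L] + drop(xs %*% theta[-1L])
    w_diag <- stats::plogis(eta) * stats::plogis(-eta)
    X1 <- cbind(1, xs)
    H <- crossprod(X1, X1 * w_diag)
    diag(H)[-1L] <- diag(H)[-1L] + 1 / C
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # halving line search: the objective never increases across iterations
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      obj_cand <- objective(cand)
      if (obj_cand <= obj + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { cand <- theta; obj_cand <- obj; break }
    }
    theta <- cand
    obj <- obj_cand
  }

  eta <- theta[1L] + drop(xs %*% theta[-1L])
  structure(
    list(weights = stats::setNames(theta[-1L], feature_names),
         intercept = theta[1L], C = C,
         center = stats::setNames(center, feature_names),
         scale = stats::setNames(scl, feature_names),
         feature_names = feature_names,
         fitted = stats::plogis(eta), y = y01, positive = positive,
         objective = obj, grad_norm = sqrt(sum(gradient(theta)^2)),
         iterations = iter, converged = converged),
    class = "hyd_logit"
  )
}

# coerce labels to 0/1 with a declared positive class
as_binary_labels <- function(y, positive) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    u <- unique(y)
    if (length(u) > 2L) stop("labels: more than two classes", call. = FALSE)
    if (!positive %in% u && length(u) == 2L) {
      stop(sprintf("labels: positive class '%s' not found", positive), call. = FALSE)
    }
    return(as.integer(y == positive))
  }
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(y))
  }
  stop("unsupported label type", call. = FALSE)
}

#' @export
print.hyd_logit <- function(x, ...) {
  cat("L2-regularized logistic regression (hyd_logit)\n")
  cat(sprintf("  C = %g, %d observations, converged: %s (|grad| = %.2e)\n",
              x$C, length(x$y), x$converged, x$grad_norm))
  cat("  standardized weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' @export
coef.hyd_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
summary.hyd_logit <- function(object, ...) {
  raw_w <- object$weights / object$scale
  raw_b <- object$intercept - sum(object$weights * object$center / object$scale)
  out <- list(fit = object,
              raw_weights = raw_w, raw_intercept = raw_b,
              train_auroc = tryCatch(auroc(object$fitted, object$y),
                                     error = function(e) NA_real_))
  class(out) <- "summary.hyd_logit"
  out
}

#' @export
print.summary.hyd_logit <- function(x, ...) {
  print(x$fit)
  cat("  raw-scale weights:\n")
  print(round(x$raw_weights, 4))
  cat(sprintf("  raw-scale intercept: %.4f\n", x$raw_intercept))
  cat(sprintf("  training AUROC: %.3f\n", x$train_auroc))
  invisible(x)
}

#' Predict dehydration scores
#'
#' @param object A fitted `hyd_logit`.
#' @param newdata Matrix or data.frame with the model's feature columns.
#' @param type `"response"` for probabilities in (0, 1), `"link"` for the
#'   linear predictor.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.hyd_logit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols) > 0L) {
      stop(sprintf("predict.hyd_logit: missing feature column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    stop("predict.hyd_logit: feature dimension mismatch", call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2L, object$center, "-"), 2L, object$scale, "/")
  eta <- object$intercept + drop(xs %*% object$weights)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.hyd_logit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted; y <- object$y
  if (type == "response") return(y - mu)
  sign(y - mu) * sqrt(-2 * (y * log(pmax(mu, 1e-300)) +
                            (1 - y) * log(pmax(1 - mu, 1e-300))))
}

#' @export
simulate.hyd_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, stats::rbinom(n, 1, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Select the regularization strength by inner cross-validation
#'
#' For each candidate `C`, performs leave-one-participant-out cross-
#' validation within the training set: fit on all but one training
#' participant, collect that participant's predicted scores, pool all
#' held-out scores, and compute a single AUROC. Returns the `C` maximizing
#' the pooled AUROC, with ties broken toward the smallest `C` (strongest
#' regularization). AUROC is rank-based, so pooling the inner folds gives a
#' single well-defined criterion even when per-fold class counts are tiny.
#'
#' @param train A `hyd_dataset` (or data.frame) with `participant_id`,
#'   `label` and the feature columns.
#' @param grid Candidate values of `C` (default `10^(-3:3)`).
#' @param feature_cols Feature columns to use.
#' @return The selected `C`, with the per-candidate pooled AUROCs attached
#'   as attribute `"cv"`.
#' @export
select_regularization <- function(train, grid = 10^(-3:3),
                                  feature_cols = c("d1", "d2", "d3")) {
  if (length(grid) == 0L) stop("select_regularization: empty grid", call. = FALSE)
  grid <- sort(grid)
  parts <- unique(train$participant_id)
  if (length(parts) < 2L) {
    stop("select_regularization: need at least 2 training participants", call. = FALSE)
  }
  x <- as.matrix(train[, feature_cols, drop = FALSE])
  y <- as_binary_labels(train$label, "DEHYDRATED")
  cv_auroc <- vapply(grid, function(C) {
    scores <- numeric(nrow(train))
    for (p in parts) {
      hold <- train$participant_id == p
      fit <- fit_logistic(x[!hold, , drop = FALSE], y[!hold], C = C)
      scores[hold] <- predict(fit, x[hold, , drop = FALSE])
    }
    auroc(scores, y)
  }, numeric(1))
  best <- grid[which(cv_auroc >= max(cv_auroc) - 1e-12)[1L]]
  attr(best, "cv") <- data.frame(C = grid, pooled_auroc = cv_auroc)
  best
}
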