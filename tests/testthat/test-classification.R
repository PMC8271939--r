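# independent implementation of the penalized objective on standardized
# features: sum log(1 + exp(-y * (b + Xw))) + ||w||^2 / (2C)
ref_objective <- function(theta, xs, ys, C) {
  eta <- theta[1] + drop(xs %*% theta[-1])
  z <- -ys * eta
  sum(ifelse(z > 33, z, log1p(exp(z)))) + sum(theta[-1]^2) / (2 * C)
}

standardize_ref <- function(x) scale(x, center = TRUE, scale = apply(x, 2, sd))

test_that("the optimum beats brute-force search and has zero gradient", {
  set.seed(101)
  x <- matrix(rnorm(36), ncol = 3)
  y <- rbinom(12, 1, plogis(1.5 * x[, 1] - x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  C <- 1
  fit <- fit_logistic(x, y, C = C)

  xs <- standardize_ref(x)
  ys <- ifelse(y == 1, 1, -1)
  theta_hat <- c(fit$intercept, fit$weights)
  obj_hat <- ref_objective(theta_hat, xs, ys, C)
  expect_equal(obj_hat, fit$objective, tolerance = 1e-8)

  # brute force: the returned optimum dominates 10000 random parameter draws
  draws <- matrix(rnorm(10000 * 4, 0, 2), ncol = 4)
  obj_draws <- apply(draws, 1, ref_objective, xs = xs, ys = ys, C = C)
  expect_true(all(obj_hat <= obj_draws + 1e-12))

  # central-difference gradient vanishes at the optimum
  h <- 1e-5
  num_grad <- vapply(1:4, function(j) {
    e <- rep(0, 4); e[j] <- h
    (ref_objective(theta_hat + e, xs, ys, C) -
       ref_objective(theta_hat - e, xs, ys, C)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_grad)), 1e-5)

  # agreement with a general-purpose optimizer on the same objective
  opt <- optim(rep(0, 4), ref_objective, xs = xs, ys = ys, C = C,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(obj_hat, opt$value, tolerance = 1e-7)
})

test_that("infinite penalty shrinks weights to zero and scores to the prior", {
  set.seed(102)
  x <- matrix(rnorm(90), ncol = 3)
  y <- rep(c(1, 0), c(12, 18))
  fit <- fit_logistic(x, y, C = 1e-8)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-3)
  sc <- predict(fit, x)
  expect_true(all(abs(sc - mean(y)) < 1e-3))
})

test_that("antisymmetric balanced data gives a zero intercept", {
  set.seed(103)
  xa <- matrix(rnorm(30), ncol = 3)
  x <- rbind(xa, -xa)
  y <- rep(c(1, 0), each = 10)
  fit <- fit_logistic(x, y, C = 1)
  expect_lt(abs(fit$intercept), 1e-6)
})

test_that("separable data under weak regularization scores near the labels", {
  x <- matrix(c(rep(2, 10), rep(-2, 10)) + rnorm(20, 0, 0.1), ncol = 1)
  y <- rep(c(1, 0), each = 10)
  fit <- fit_logistic(x, y, C = 1e6)
  sc <- predict(fit, x)
  expect_true(all(sc[y == 1] > 0.99))
  expect_true(all(sc[y == 0] < 0.01))
})

test_that("scores are invariant to constant shifts of a raw feature column", {
  set.seed(104)
  x <- matrix(rnorm(60), ncol = 3)
  y <- rbinom(20, 1, plogis(x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  xt <- matrix(rnorm(30), ncol = 3)
  base <- predict(fit_logistic(x, y, C = 1), xt)
  x2 <- x; x2[, 2] <- x2[, 2] + 57
  xt2 <- xt; xt2[, 2] <- xt2[, 2] + 57
  shifted <- predict(fit_logistic(x2, y, C = 1), xt2)
  expect_equal(shifted, base, tolerance = 1e-9)
})

test_that("the fit is invariant to row order", {
  set.seed(105)
  x <- matrix(rnorm(150), ncol = 3)
  y <- rbinom(50, 1, plogis(x[, 3]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  f1 <- fit_logistic(x, y, C = 1)
  perm <- sample(50)
  f2 <- fit_logistic(x[perm, ], y[perm], C = 1)
  expect_equal(f2$weights, f1$weights, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-6)
})

test_that("the weight norm is monotone along the regularization path", {
  set.seed(106)
  x <- matrix(rnorm(120), ncol = 3)
  y <- rbinom(40, 1, plogis(x[, 1] + 0.5 * x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  norms <- vapply(10^(-3:3), function(C) {
    sqrt(sum(fit_logistic(x, y, C = C)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-8))
})

test_that("degenerate fits are guarded", {
  x <- matrix(rnorm(30), ncol = 3)
  expect_error(fit_logistic(x, rep(1, 10), C = 1), "both classes")
  x0 <- x; x0[, 2] <- 5
  y <- rep(c(1, 0), 5)
  expect_warning(fit_logistic(x0, y, C = 1), "zero-variance")
  expect_error(fit_logistic(x, y, C = -1), "positive")
  fit <- fit_logistic(x, y, C = 1)
  expect_error(predict(fit, matrix(1, 2, 2)), "dimension mismatch")
})

test_that("model methods are coherent", {
  set.seed(107)
  x <- matrix(rnorm(90), ncol = 3, dimnames = list(NULL, c("d1", "d2", "d3")))
  y <- rbinom(30, 1, plogis(x[, 3]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_logistic(x, y, C = 1)
  expect_named(coef(fit), c("(Intercept)", "d1", "d2", "d3"))
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-8)
  # link and response predictions agree through the logistic link
  expect_equal(plogis(predict(fit, x, type = "link")), predict(fit, x))
  # deviance residuals have the sign of y - fitted
  expect_equal(sign(residuals(fit)), sign(y - fit$fitted))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
})

test_that("regularization selection honors the grid and tie rules", {
  # one-element grid is returned as-is
  ds <- design_dataset(4, signal_features(shift = 3), seed = 41)
  expect_equal(as.numeric(select_regularization(ds, grid = 0.5)), 0.5)

  # perfectly separable features: every C reaches pooled AUROC 1,
  # so the tie breaks to the smallest (strongest) C
  sep <- design_dataset(4, function(label, n) {
    f <- matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
    f[, 3] <- ifelse(label == "DEHYDRATED", 1, -1)
    f
  }, seed = 42)
  C <- select_regularization(sep, grid = 10^(-3:3))
  expect_equal(as.numeric(C), 1e-3)
  cv <- attr(C, "cv")
  expect_true(all(cv$pooled_auroc == 1))

  expect_error(select_regularization(ds, grid = numeric(0)), "empty grid")
})
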