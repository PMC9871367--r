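test_that("correlations match the textbook per-column formula", {
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30, 8)
  u <- rnorm(30)
  r <- compute_correlations(X, u)
  oracle <- vapply(1:8, function(j) {
    x <- X[, j]
    sum((x - mean(x)) * (u - mean(u))) /
      sqrt(sum((x - mean(x))^2) * sum((u - mean(u))^2))
  }, numeric(1))
  expect_equal(r, oracle, tolerance = 1e-12)

  # self-correlation and the zero-variance convention
  expect_equal(compute_correlations(X, X[, 3])[3], 1)
  Xz <- X; Xz[, 5] <- 2
  expect_equal(compute_correlations(Xz, u)[5], 0)
  expect_equal(compute_correlations(X, rep(1, 30)), rep(0, 8))
  expect_error(compute_correlations(X[1, , drop = FALSE], 1), "2 samples")
})

test_that("batch screening ranks by |correlation| and freezes the outer maximum", {
  # construct columns with known correlations to u
  set.seed(8)
  n <- 200
  u <- rnorm(n)
  mk <- function(rho) rho * u + sqrt(1 - rho^2) * rnorm(n)
  X <- cbind(mk(0.9), mk(0.1), mk(-0.5))
  r <- abs(compute_correlations(X, u))
  b <- screen_batch(X, u, 2)
  expect_equal(sort(b$indices), sort(order(-r)[1:2]))
  expect_equal(b$c_stop, r[order(-r)[3]])

  # whole-data batch: sentinel
  ball <- screen_batch(X, u, 3)
  expect_identical(ball$c_stop, -Inf)

  # exact ties break toward the lower index
  Xt <- cbind(u, u)
  bt <- screen_batch(Xt, u, 1)
  expect_equal(bt$indices, 1L)

  # all-zero correlations: warn, take the first p_batch
  Xz <- matrix(2, 10, 4)
  expect_warning(bz <- screen_batch(Xz, rnorm(10), 2), "zero")
  expect_equal(bz$indices, 1:2)
  expect_equal(bz$c_stop, 0)
})

test_that("base-learner fits reproduce ordinary least squares", {
  expect_equal(fit_base_learner(c(0, 1, 2), u = c(0, 1, 2))[c("intercept", "slope")],
               list(intercept = 0, slope = 1))
  expect_equal(fit_base_learner(c(0, 2), u = c(1, 3))[c("intercept", "slope")],
               list(intercept = 1, slope = 1))

  # with covariates: normal-equations oracle
  set.seed(11)
  n <- 40
  x <- rbinom(n, 2, 0.4); C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  u <- rnorm(n)
  bl <- fit_base_learner(x, C, u)
  D <- cbind(1, x, C)
  cf <- solve(crossprod(D), crossprod(D, u))
  expect_equal(c(bl$intercept, bl$slope, bl$covariates), as.vector(cf), tolerance = 1e-8)

  expect_error(fit_base_learner(rep(1, 5), u = rnorm(5)), "rank deficient")
  expect_error(fit_base_learner(x, cbind(x), u), "rank deficient")
})

test_that("repeated steps on one variant approach the OLS fit geometrically", {
  set.seed(12)
  n <- 100
  x <- rnorm(n)
  x <- (x - min(x)) / diff(range(x)) * 2
  y <- 2 * x + rnorm(n)
  b_ols <- fit_base_learner(x, u = y)$slope
  nu <- 0.1
  st <- init_boost_state(cbind(x), y)
  batch <- screen_batch(cbind(x), st$u, 1)
  for (m in 1:25) {
    st <- boosting_step(st, batch, cbind(x), nu = nu)
    expect_equal(st$beta[1], (1 - (1 - nu)^m) * b_ols, tolerance = 1e-9)
  }
})

test_that("a full step (nu = 1) on one variant lands on the exact regression", {
  set.seed(13)
  x <- runif(50, 0, 2); y <- 1 + 0.5 * x + rnorm(50)
  st <- init_boost_state(cbind(x), y)
  st <- boosting_step(st, screen_batch(cbind(x), st$u, 1), cbind(x), nu = 1)
  expect_equal(st$u %*% cbind(1, x), cbind(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  cf <- coef(lm(y ~ x))
  expect_equal(c(st$beta0, st$beta[1]), unname(cf), tolerance = 1e-10)
})

test_that("inner stopping fires on the stored threshold or the step budget", {
  # whole-data batch never fires before m_batch
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3)
  u <- rnorm(20)
  ball <- screen_batch(X, u, 3)
  expect_false(check_inner_stop(ball, X, u, steps_in_batch = 5, m_batch = 10))
  expect_true(check_inner_stop(ball, X, u, steps_in_batch = 10, m_batch = 10))

  # a dominant stored threshold fires at once
  b <- screen_batch(X, u, 2)
  b$c_stop <- 0.8; b$c_stop_cov <- 0.8 * b$sd_u
  un <- rnorm(20) * 1e-3  # fresh gradient nearly uncorrelated with the batch
  stat_in <- max(abs(vapply(b$indices, function(j) {
    x <- X[, j]
    sum((x - mean(x)) * (un - mean(un))) / (19 * sd(x))
  }, numeric(1))))
  expect_equal(check_inner_stop(b, X, un, 1, 100), b$c_stop_cov > stat_in)
  expect_true(check_inner_stop(b, X, un, 1, 100))
})

test_that("with orthogonal variants the batched fit reproduces the full-data selection order", {
  n <- 200; p <- 30
  Q <- orthogonal_columns(n, p, seed = 15)
  set.seed(16)
  y <- as.numeric(Q %*% rnorm(p) + 0.3 * rnorm(n))
  ref <- l2boost_reference(Q, y, m_stop = 120, nu = 0.1)
  for (pb in c(3, 10)) {
    fit <- prs_boost(Q, y, control = boost_control(p_batch = pb, m_batch = pb,
                                                   b_max = 10000),
                     m_max = 120)
    expect_equal(fit$path$iterations$variant, ref$path$iterations$variant)
    to_dense <- function(m) {
      b <- numeric(p)
      b[as.integer(sub("^v", "", m$coefficients$variant_id))] <- m$coefficients$beta
      b
    }
    expect_equal(to_dense(fit), to_dense(ref), tolerance = 1e-8)
  }
})

test_that("mandatory covariates are updated every step and never screened", {
  set.seed(17)
  n <- 300
  G <- toy_genotypes(n, 10, seed = 17)
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 0.8 * G$dosages[, 4] + 1.5 * C[, 1] - 0.7 * C[, 2] + rnorm(n)
  fit <- prs_boost(G, y, covariates = C, control = boost_control(p_batch = 5),
                   m_max = 300)
  expect_named(fit$covariate_coefficients, c("age", "sex"))
  # covariate effects recovered even though covariates are never in a batch
  expect_equal(unname(fit$covariate_coefficients), c(1.5, -0.7), tolerance = 0.15)
  expect_true(all(fit$path$iterations$variant <= 10))
})
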