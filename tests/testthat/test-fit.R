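test_that("the batched fit with one all-variant batch equals the classical algorithm", {
  cfg <- sim_config(n = 150, p = 40, h2 = 0.5, s = 0.1, seed = 21)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  m_stop <- 120
  ref <- l2boost_reference(G, y, m_stop = m_stop, nu = 0.1)
  fit <- prs_boost(G, y, control = boost_control(p_batch = 40, m_batch = m_stop,
                                                 b_max = 1),
                   m_max = m_stop)
  expect_equal(fit$path$iterations$variant, ref$path$iterations$variant)
  expect_equal(dense_beta(fit, G), dense_beta(ref, G), tolerance = 1e-10)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-10)
})

test_that("training loss never increases along the path", {
  cfg <- sim_config(n = 300, p = 60, h2 = 0.4, s = 0.05, seed = 22)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  fit <- prs_boost(G, y, control = boost_control(p_batch = 15), m_max = 200)
  expect_true(all(diff(fit$path$iterations$train_loss) <= 1e-12))

  yb <- as.integer(y > median(y))
  fitb <- prs_boost(G, yb, loss = "log",
                    control = boost_control(p_batch = 15), m_max = 200)
  expect_true(all(diff(fitb$path$iterations$train_loss) <= 1e-12))
})

test_that("predictions are reconstructable from the sparse coefficients", {
  cfg <- sim_config(n = 250, p = 50, h2 = 0.5, s = 0.1, seed = 23)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  idx <- split_samples(250, seed = 23)
  fit <- prs_boost(G[idx$train, ], y[idx$train],
                   G[idx$validation, ], y[idx$validation],
                   control = boost_control(p_batch = 10))
  sc <- predict(fit, G[idx$train, ])
  manual <- fit$intercept +
    as.vector(G$dosages[idx$train, , drop = FALSE] %*% dense_beta(fit, G))
  expect_equal(sc, manual, tolerance = 1e-8)
})

test_that("identical inputs give bit-identical fit paths", {
  cfg <- sim_config(n = 200, p = 30, h2 = 0.5, s = 0.1, seed = 24)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  idx <- split_samples(200, seed = 24)
  f1 <- prs_boost(G[idx$train, ], y[idx$train], G[idx$validation, ], y[idx$validation],
                  control = boost_control(p_batch = 8))
  f2 <- prs_boost(G[idx$train, ], y[idx$train], G[idx$validation, ], y[idx$validation],
                  control = boost_control(p_batch = 8))
  expect_identical(f1$path$iterations, f2$path$iterations)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("sparsity is bounded by the iteration count", {
  cfg <- sim_config(n = 200, p = 80, h2 = 0.5, s = 0.05, seed = 25)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  fit <- prs_boost(G, y, control = boost_control(p_batch = 20), m_max = 37)
  expect_lte(nrow(fit$coefficients), fit$n_iterations)
  expect_lte(fit$n_iterations, 37)
})

test_that("halving the learning rate and doubling iterations converges to the same fit", {
  set.seed(26)
  x <- runif(120, 0, 2); y <- 0.7 * x + rnorm(120, sd = 0.3)
  f1 <- l2boost_reference(cbind(x), y, m_stop = 60, nu = 0.1)
  f2 <- l2boost_reference(cbind(x), y, m_stop = 120, nu = 0.05)
  b1 <- f1$coefficients$beta; b2 <- f2$coefficients$beta
  # geometric-series argument: difference is o(nu)
  expect_lt(abs(b1 - b2), 0.05 * abs(b1))
})

test_that("a missing validation set demands a fixed iteration budget", {
  G <- toy_genotypes(30, 5)
  y <- rnorm(30)
  expect_error(prs_boost(G, y), "m_max")
  expect_s3_class(prs_boost(G, y, m_max = 5), "prs_model")
})

test_that("early stopping returns the best-validation snapshot, not the last state", {
  cfg <- sim_config(n = 400, p = 100, h2 = 0.3, s = 0.02, seed = 27)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  idx <- split_samples(400, seed = 27)
  fit <- prs_boost(G[idx$train, ], y[idx$train], G[idx$validation, ], y[idx$validation],
                   control = boost_control(p_batch = 10, b_stop = 2))
  path <- fit$path$batches
  expect_equal(fit$validation_loss, min(path$validation_loss))
  expect_equal(fit$n_batches, path$k[which.min(path$validation_loss)])
  # it kept going b_stop batches past the optimum before stopping
  expect_gte(max(path$k) - fit$n_batches, 1)
})

test_that("a pure-noise phenotype yields a near-zero test R-squared", {
  r2 <- vapply(1:5, function(s) {
    cfg <- sim_config(n = 500, p = 200, h2 = 0, s = 0.02, seed = 30 + s)
    G <- simulate_genotypes(cfg)
    y <- suppressWarnings(simulate_phenotype(G, cfg))$phenotype$pheno
    idx <- split_samples(500, seed = s)
    fit <- prs_boost(G[idx$train, ], y[idx$train], G[idx$validation, ], y[idx$validation],
                     control = boost_control(p_batch = 50))
    pr <- predict(fit, G[idx$test, ])
    suppressWarnings(prediction_metrics(y[idx$test], pr)$r2)
  }, numeric(1))
  expect_lt(median(r2), 0.05)
})
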