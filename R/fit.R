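#' Fit a polygenic risk score by batch-screened component-wise boosting
#'
#' The workhorse of the package. Starting from prediction 0, the algorithm
#' alternates two loops. The *outer* loop screens the `p_batch` variants
#' most correlated (in absolute value) with the current negative gradient
#' into a batch and freezes the best out-of-batch correlation as that
#' batch's stopping threshold. The *inner* loop runs component-wise
#' boosting on the batch: each step regresses the negative gradient on one
#' variant (plus intercept and any mandatory covariates), picks the variant
#' with the largest absolute correlation, and moves the coefficients a
#' fraction `nu` toward the fit. The inner loop ends when the frozen
#' out-of-batch threshold overtakes the best in-batch correlation (see
#' [check_inner_stop()]) or after `m_batch` steps. After each batch the
#' validation loss (MSEP for `"l2"`, mean log loss for `"log"`) is
#' recorded; fitting terminates when it has not improved for `b_stop`
#' consecutive batches, after `b_max` batches, or at `m_max` total
#' iterations. The returned model is the snapshot from the batch with the
#' smallest validation loss.
#'
#' @param genotypes Training genotypes: a [genotype_matrix()] or a plain
#'   numeric matrix (samples x variants) with no missing values.
#' @param phenotype Numeric response vector. For `loss = "log"` it must be
#'   coded `{0, 1}`; a PLINK-style `{1, 2}` coding is shifted with a
#'   warning.
#' @param genotypes_valid,phenotype_valid Validation data used to monitor
#'   predictive performance. May be omitted only with a finite `m_max`
#'   (fixed iteration budget), in which case the final state is returned.
#' @param covariates,covariates_valid Optional mandatory covariate matrices
#'   (same columns in both); covariates are part of every base-learner and
#'   are updated at each step without competing with the variants.
#' @param loss `"l2"` for continuous traits or `"log"` for binary traits.
#' @param control A [boost_control()] list of hyperparameters.
#' @param m_max Optional cap on the total number of boosting iterations
#'   (default unlimited).
#' @param trace If `TRUE`, print one tab-delimited progress record per
#'   batch.
#' @return A `prs_model`; see [tidy.prs_model()], [glance.prs_model()],
#'   [predict.prs_model()], [export_prs()]. The fitting history is in
#'   `$path` (tibbles `iterations` and `batches`).
#' @examples
#' cfg <- sim_config(n = 400, p = 100, h2 = 0.5, s = 0.05, seed = 7)
#' G <- simulate_genotypes(cfg)
#' sim <- simulate_phenotype(G, cfg)
#' idx <- split_samples(400, seed = 7)
#' fit <- prs_boost(G[idx$train, ], sim$phenotype$pheno[idx$train],
#'                  G[idx$validation, ], sim$phenotype$pheno[idx$validation],
#'                  control = boost_control(p_batch = 20))
#' glance(fit)
#' @export
prs_boost <- function(genotypes, phenotype,
                      genotypes_valid = NULL, phenotype_valid = NULL,
                      covariates = NULL, covariates_valid = NULL,
                      loss = c("l2", "log"), control = boost_control(),
                      m_max = Inf, trace = FALSE) {
  loss_name <- if (is.character(loss)) match.arg(loss) else loss$name
  lspec <- loss_spec(loss_name)
  X <- .dosage_matrix(genotypes)
  if (anyNA(X)) stop("training genotypes contain missing values; run impute_missing() first", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 training samples", call. = FALSE)
  y <- as.numeric(phenotype)
  if (length(y) != n) stop("phenotype must have length nrow(genotypes)", call. = FALSE)
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (loss_name == "log") y <- .check_binary(y)

  C <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  q <- if (is.null(C)) 0L else ncol(C)
  cov_names <- if (q > 0) colnames(C) %||% paste0("covariate_", seq_len(q)) else character(0)

  has_val <- !is.null(genotypes_valid)
  if (!has_val && !is.finite(m_max))
    stop("no validation set supplied: either provide one for early stopping, ",
         "or set a fixed iteration budget via `m_max`", call. = FALSE)
  if (has_val) {
    Xv <- .dosage_matrix(genotypes_valid)
    if (anyNA(Xv)) stop("validation genotypes contain missing values", call. = FALSE)
    if (ncol(Xv) != p) stop("training and validation genotypes must have the same variants", call. = FALSE)
    yv <- as.numeric(phenotype_valid)
    if (length(yv) != nrow(Xv)) stop("phenotype_valid must match genotypes_valid", call. = FALSE)
    if (loss_name == "log") yv <- .check_binary(yv)
    Cv <- if (q > 0) as.matrix(covariates_valid) else NULL
    if (q > 0 && (is.null(Cv) || ncol(Cv) != q))
      stop("covariates_valid must have the same columns as covariates", call. = FALSE)
  }

  p_batch <- min(control$p_batch, p)
  nu <- control$nu

  mom <- .col_moments(X)
  cm <- mom$mean; csd <- mom$sd

  beta0 <- 0; beta <- numeric(p); gamma <- numeric(q)
  pred <- numeric(n); predv <- if (has_val) numeric(nrow(Xv)) else NULL
  u <- lspec$negative_gradient(y, pred)

  cap <- 1024L                      # iteration records grow geometrically
  it_m <- integer(cap); it_k <- integer(cap); it_j <- integer(cap)
  it_inc <- numeric(cap); it_loss <- numeric(cap)
  bt_k <- integer(0); bt_size <- integer(0); bt_steps <- integer(0)
  bt_val <- numeric(0); bt_sel <- integer(0)

  best_val <- Inf; no_improve <- 0
  best <- NULL
  m <- 0L; k <- 0L
  warned_zero <- FALSE

  while (k < control$b_max && m < m_max) {
    k <- k + 1L
    # ---- outer: screen a batch against the current negative gradient ----
    cov_all <- .col_cov(X, u, cm)
    stat_all <- ifelse(csd > 0, abs(cov_all) / csd, 0)
    if (all(stat_all == 0) && !warned_zero) {
      warning("all variant correlations are zero; batch defaults to the first p_batch variants",
              call. = FALSE)
      warned_zero <- TRUE
    }
    ord <- order(-stat_all, seq_len(p))
    idx <- ord[seq_len(p_batch)]
    c_stop_cov <- if (p_batch < p) stat_all[ord[p_batch + 1L]] else -Inf
    Xb <- X[, idx, drop = FALSE]
    cmb <- cm[idx]; csdb <- csd[idx]

    # ---- inner: component-wise boosting on the batch ----
    steps <- 0L
    repeat {
      covb <- .col_cov(Xb, u, cmb)
      statb <- ifelse(csdb > 0, abs(covb) / csdb, 0)
      if (steps > 0L && c_stop_cov > max(statb)) break
      sel <- order(-statb, idx)[1]
      j <- idx[sel]
      x <- Xb[, sel]
      if (csdb[sel] > 0) {
        if (q == 0L) {
          slope <- covb[sel] / csdb[sel]^2
          a <- mean(u) - slope * cmb[sel]
          g <- numeric(0)
        } else {
          bl <- fit_base_learner(x, C, u)
          a <- bl$intercept; slope <- bl$slope; g <- bl$covariates
        }
      } else {                     # degenerate: constant column, intercept-only move
        a <- mean(u); slope <- 0; g <- numeric(q)
      }
      beta0 <- beta0 + nu * a
      beta[j] <- beta[j] + nu * slope
      delta <- nu * (a + slope * x)
      if (q > 0L && length(g)) {
        gamma <- gamma + nu * g
        delta <- delta + nu * as.vector(C %*% g)
      }
      pred <- pred + delta
      if (has_val) {
        dv <- nu * (a + slope * Xv[, j])
        if (q > 0L && length(g)) dv <- dv + nu * as.vector(Cv %*% g)
        predv <- predv + dv
      }
      u <- lspec$negative_gradient(y, pred)
      m <- m + 1L; steps <- steps + 1L
      if (m > cap) {
        cap <- cap * 2L
        length(it_m) <- cap; length(it_k) <- cap; length(it_j) <- cap
        length(it_inc) <- cap; length(it_loss) <- cap
      }
      it_m[m] <- m; it_k[m] <- k; it_j[m] <- j
      it_inc[m] <- nu * slope
      it_loss[m] <- lspec$evaluate(y, pred)
      if (steps >= control$m_batch || m >= m_max) break
    }

    val_loss <- if (has_val) lspec$evaluate(yv, predv) else NA_real_
    bt_k <- c(bt_k, k); bt_size <- c(bt_size, p_batch); bt_steps <- c(bt_steps, steps)
    bt_val <- c(bt_val, val_loss); bt_sel <- c(bt_sel, sum(beta != 0))
    if (trace)
      cat(sprintf("%d\t%d\t%s\t%d\n", k, m,
                  ifelse(is.na(val_loss), "NA", format(val_loss, digits = 8)),
                  sum(beta != 0)))

    if (has_val) {
      if (val_loss < best_val) {
        best_val <- val_loss
        best <- list(beta0 = beta0, beta = beta, gamma = gamma, m = m, k = k)
        no_improve <- 0
      } else {
        no_improve <- no_improve + 1
      }
      if (no_improve >= control$b_stop) break
    }
    if (steps == 0L) break
  }

  if (is.null(best)) best <- list(beta0 = beta0, beta = beta, gamma = gamma, m = m, k = k)

  new_prs_model(
    intercept = best$beta0, beta = best$beta, gamma = best$gamma,
    cov_names = cov_names, loss = loss_name, control = control,
    n_iterations = best$m, n_batches = best$k,
    variants = .variant_table(genotypes, p),
    path = list(
      iterations = {
        mm <- seq_len(m)
        tibble::tibble(m = it_m[mm], k = it_k[mm], variant = it_j[mm],
                       increment = it_inc[mm], train_loss = it_loss[mm])
      },
      batches = tibble::tibble(k = bt_k, batch_size = bt_size, n_steps = bt_steps,
                               validation_loss = bt_val, n_selected = bt_sel)
    ),
    validation_loss = if (has_val) best_val else NA_real_
  )
}

.check_binary <- function(y) {
  u <- sort(unique(y))
  if (all(u %in% c(0, 1))) return(y)
  if (all(u %in% c(1, 2))) {
    warning("binary phenotype coded {1,2}; recoding to {0,1}", call. = FALSE)
    return(y - 1)
  }
  stop("log loss requires a binary phenotype coded {0,1}", call. = FALSE)
}

.variant_table <- function(G, p) {
  if (inherits(G, "genotype_matrix")) G$variants
  else tibble::tibble(variant_id = sprintf("v%d", seq_len(p)), chromosome = "1",
                      position = seq_len(p), effect_allele = "A", other_allele = "B")
}

#' Classical component-wise L2-boosting (non-batched reference)
#'
#' Straightforward implementation of component-wise boosting with linear
#' base-learners in which *every* iteration scans all `p` variants for the
#' one most correlated with the residuals. It is deterministic given its
#' inputs, converges to the ordinary least squares solution for large
#' `m_stop` when `p < n`, and serves as the in-package oracle the batched
#' algorithm must reduce to when the batch contains all variants.
#'
#' @inheritParams prs_boost
#' @param m_stop Number of boosting iterations.
#' @param nu Learning rate.
#' @return A `prs_model` (squared-error loss) with the iteration path.
#' @export
l2boost_reference <- function(genotypes, phenotype, m_stop, nu = 0.1,
                              covariates = NULL) {
  X <- .dosage_matrix(genotypes)
  if (anyNA(X)) stop("genotypes contain missing values; impute first", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  y <- as.numeric(phenotype)
  stopifnot(length(y) == n, m_stop >= 0)
  C <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  q <- if (is.null(C)) 0L else ncol(C)

  beta0 <- 0; beta <- numeric(p); gamma <- numeric(q)
  pred <- numeric(n)
  it_j <- integer(m_stop); it_inc <- numeric(m_stop); it_loss <- numeric(m_stop)

  m <- 0L
  while (m < m_stop) {
    u <- y - pred
    r <- compute_correlations(X, u)
    a <- abs(r)
    sel <- order(-a, seq_len(p))[1]
    x <- X[, sel]
    if (a[sel] == 0 && .vec_sd(x) == 0) {
      bl <- list(intercept = mean(u), slope = 0, covariates = numeric(q))
    } else {
      bl <- fit_base_learner(x, C, u)
    }
    beta0 <- beta0 + nu * bl$intercept
    beta[sel] <- beta[sel] + nu * bl$slope
    pred <- pred + nu * (bl$intercept + bl$slope * x)
    if (q > 0L && length(bl$covariates)) {
      gamma <- gamma + nu * bl$covariates
      pred <- pred + nu * as.vector(C %*% bl$covariates)
    }
    m <- m + 1L
    it_j[m] <- sel; it_inc[m] <- nu * bl$slope
    it_loss[m] <- mean((y - pred)^2)
  }

  new_prs_model(
    intercept = beta0, beta = beta, gamma = gamma,
    cov_names = if (q > 0) colnames(C) %||% paste0("covariate_", seq_len(q)) else character(0),
    loss = "l2", control = boost_control(p_batch = max(p, 1), nu = nu,
                                         m_batch = max(m_stop, 1), b_max = 1),
    n_iterations = m, n_batches = 1L,
    variants = .variant_table(genotypes, p),
    path = list(
      iterations = tibble::tibble(m = seq_len(m), k = 1L, variant = it_j,
                                  increment = it_inc, train_loss = it_loss),
      batches = tibble::tibble(k = 1L, batch_size = p, n_steps = m,
                               validation_loss = NA_real_, n_selected = sum(beta != 0))
    ),
    validation_loss = NA_real_
  )
}
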