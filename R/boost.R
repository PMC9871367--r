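#' Boosting hyperparameters
#'
#' Defaults follow the recommended large-scale settings: learning rate
#' `nu = 0.1`, batch size `p_batch = 1000` with at most `m_batch = p_batch`
#' inner iterations per batch, a large ceiling of `b_max = 20000` batches,
#' and outer early stopping after `b_stop = 2` consecutive batches without
#' improvement of the validation loss.
#'
#' @param p_batch Number of variants screened into each batch.
#' @param nu Learning rate in `(0, 1]`.
#' @param m_batch Maximum boosting iterations per batch.
#' @param b_max Maximum number of batches.
#' @param b_stop Outer stopping lag: terminate after this many consecutive
#'   batches without strict improvement of the best validation loss.
#' @return A `boost_control` list.
#' @export
boost_control <- function(p_batch = 1000, nu = 0.1, m_batch = p_batch,
                          b_max = 20000, b_stop = 2) {
  stopifnot(p_batch >= 1, nu > 0, nu <= 1, m_batch >= 1, b_max >= 1, b_stop >= 1)
  structure(list(p_batch = as.integer(p_batch), nu = nu,
                 m_batch = as.integer(m_batch), b_max = as.integer(b_max),
                 b_stop = b_stop),
            class = "boost_control")
}

# column means and sds (denominator n - 1) of a dosage matrix
.col_moments <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  css <- colSums(X * X) - n * cm^2
  csd <- sqrt(pmax(css, 0) / max(n - 1, 1))
  list(mean = cm, sd = csd)
}

.vec_sd <- function(u) {
  n <- length(u)
  sqrt(max(sum(u * u) - n * mean(u)^2, 0) / max(n - 1, 1))
}

# covariance of each column of X with u, denominator n - 1
.col_cov <- function(X, u, col_means = NULL) {
  n <- nrow(X)
  if (is.null(col_means)) col_means <- colMeans(X)
  as.vector(crossprod(X, u) - n * col_means * mean(u)) / max(n - 1, 1)
}

#' Pearson correlation of variant columns with a vector
#'
#' Correlations drive both the batch screening and the base-learner
#' selection. Zero-variance columns (and a zero-variance `u`) map to
#' correlation 0 rather than `NaN`, so monomorphic variants can never be
#' selected.
#'
#' @param G A [genotype_matrix()] or plain numeric matrix (no missing
#'   values).
#' @param u Numeric vector, typically the current negative gradient.
#' @param subset Optional integer vector of column indices.
#' @return Numeric vector of correlations, one per (selected) column.
#' @export
compute_correlations <- function(G, u, subset = NULL) {
  X <- .dosage_matrix(G)
  if (nrow(X) < 2) stop("need at least 2 samples to compute correlations", call. = FALSE)
  if (length(u) != nrow(X)) stop("u must have length nrow(G)", call. = FALSE)
  if (anyNA(X)) stop("genotypes contain missing values; impute first", call. = FALSE)
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("subset must be nonempty", call. = FALSE)
    X <- X[, subset, drop = FALSE]
  }
  mom <- .col_moments(X)
  su <- .vec_sd(u)
  if (su == 0) return(rep(0, ncol(X)))
  r <- .col_cov(X, u, mom$mean) / (mom$sd * su)
  r[mom$sd == 0] <- 0
  r
}

#' Screen the variants most correlated with the negative gradient
#'
#' Builds a batch of the `p_batch` variants with largest absolute Pearson
#' correlation to `u` (ties broken toward the lowest variant index) and
#' stores the largest absolute correlation among the *excluded* variants as
#' the batch's stopping threshold `c_stop`. The residual standard deviation
#' at batch creation is stored alongside so the later in-batch comparison
#' (see [check_inner_stop()]) is made on a scale consistent with the frozen
#' threshold.
#'
#' @inheritParams compute_correlations
#' @param p_batch Batch size, between 1 and the number of variants. A batch
#'   of all variants gets the sentinel `c_stop = -Inf` (nothing lies
#'   outside it).
#' @return A `variant_batch`: list with `indices`, `c_stop`, `sd_u` and the
#'   covariance-scale threshold `c_stop_cov = c_stop * sd_u`.
#' @export
screen_batch <- function(G, u, p_batch) {
  X <- .dosage_matrix(G)
  p <- ncol(X)
  if (p_batch < 1 || p_batch > p) stop("p_batch must be in [1, p]", call. = FALSE)
  r <- compute_correlations(X, u)
  a <- abs(r)
  if (all(a == 0))
    warning("all variant correlations are zero; batch defaults to the first p_batch variants",
            call. = FALSE)
  ord <- order(-a, seq_len(p))
  idx <- ord[seq_len(p_batch)]
  su <- .vec_sd(u)
  c_stop <- if (p_batch < p) a[ord[p_batch + 1L]] else -Inf
  structure(
    list(indices = idx, c_stop = c_stop, sd_u = su,
         c_stop_cov = if (is.finite(c_stop)) c_stop * su else -Inf),
    class = "variant_batch"
  )
}

#' Fit a univariate base-learner by ordinary least squares
#'
#' Regresses the current negative gradient on an intercept, one variant
#' column and any mandatory covariates. Covariates are part of every
#' base-learner design ("mandatory", like the intercept): they are updated
#' at every boosting step and never compete with the variants.
#'
#' @param x Dosage column (length `n`).
#' @param C Covariate matrix (`n x q`), or `NULL` for none.
#' @param u Negative gradient vector.
#' @return List with `intercept`, `slope` and `covariates` (length-`q`
#'   numeric).
#' @export
fit_base_learner <- function(x, C = NULL, u) {
  n <- length(u)
  if (length(x) != n) stop("x and u must have equal length", call. = FALSE)
  if (is.null(C) || NCOL(C) == 0) {
    mx <- mean(x)
    vx <- sum((x - mx)^2)
    if (vx == 0) stop("base-learner design is rank deficient: variant column is constant", call. = FALSE)
    slope <- sum((x - mx) * (u - mean(u))) / vx
    list(intercept = mean(u) - slope * mx, slope = slope, covariates = numeric(0))
  } else {
    C <- as.matrix(C)
    D <- cbind(1, x, C)
    fit <- stats::lm.fit(D, u)
    if (fit$rank < ncol(D)) {
      bad <- which(is.na(fit$coefficients))[1]
      nm <- c("(intercept)", "variant", colnames(C) %||% paste0("covariate_", seq_len(ncol(C))))[bad]
      stop("base-learner design is rank deficient at column: ", nm, call. = FALSE)
    }
    cf <- fit$coefficients
    list(intercept = unname(cf[1]), slope = unname(cf[2]), covariates = unname(cf[-(1:2)]))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a boosting state
#'
#' The fit starts from prediction identically 0 (for the log loss this is
#' the linear predictor, i.e. probability 0.5 everywhere); the first
#' negative gradient is evaluated there.
#'
#' @param G Genotypes (matrix or [genotype_matrix()]), no missing values.
#' @param y Response vector.
#' @param covariates Optional `n x q` covariate matrix.
#' @param loss `"l2"` or `"log"` (or a `loss_spec`).
#' @return A `boost_state` list: coefficients, prediction, negative
#'   gradient `u`, iteration counter `m` and batch counter `k`.
#' @export
init_boost_state <- function(G, y, covariates = NULL, loss = "l2") {
  X <- .dosage_matrix(G)
  if (is.character(loss)) loss <- loss_spec(loss)
  n <- nrow(X)
  if (length(y) != n) stop("y must have length nrow(G)", call. = FALSE)
  q <- if (is.null(covariates)) 0L else NCOL(covariates)
  pred <- numeric(n)
  structure(
    list(y = y, loss = loss,
         beta0 = 0, beta = numeric(ncol(X)), gamma = numeric(q),
         prediction = pred, u = loss$negative_gradient(y, pred),
         m = 0L, k = 0L),
    class = "boost_state"
  )
}

#' Perform one component-wise boosting step on a batch
#'
#' Selects the in-batch variant with the largest absolute correlation to
#' the current negative gradient (ties toward the lowest variant index),
#' fits the base-learner, and moves all coefficients a fraction `nu` of the
#' way toward that fit: the intercept, the selected variant's coefficient
#' and every mandatory covariate coefficient are updated, the prediction
#' and negative gradient are refreshed, and the iteration counter advances.
#'
#' @param state A `boost_state` from [init_boost_state()].
#' @param batch A `variant_batch` from [screen_batch()].
#' @param G Genotypes used to create `state`.
#' @param covariates Covariate matrix used to create `state` (or `NULL`).
#' @param nu Learning rate.
#' @return The updated `boost_state`, with `state$selected` holding the
#'   chosen variant index.
#' @export
boosting_step <- function(state, batch, G, covariates = NULL, nu = 0.1) {
  X <- .dosage_matrix(G)
  idx <- batch$indices
  stat <- abs(compute_correlations(X, state$u, subset = idx))
  sel <- order(-stat, idx)[1]
  j <- idx[sel]
  x <- X[, j]
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (stat[sel] == 0 && .vec_sd(x) == 0) {
    # degenerate batch: nothing correlates; move only the mandatory terms
    bl <- if (is.null(C)) list(intercept = mean(state$u), slope = 0, covariates = numeric(0))
          else { f <- fit_base_learner(rep(c(0, 1), length.out = length(x)), C, state$u)
                 list(intercept = mean(state$u), slope = 0, covariates = f$covariates) }
    bl$slope <- 0
  } else {
    bl <- fit_base_learner(x, C, state$u)
  }
  state$beta0 <- state$beta0 + nu * bl$intercept
  state$beta[j] <- state$beta[j] + nu * bl$slope
  delta <- nu * (bl$intercept + bl$slope * x)
  if (length(bl$covariates)) {
    state$gamma <- state$gamma + nu * bl$covariates
    delta <- delta + nu * as.vector(C %*% bl$covariates)
  }
  state$prediction <- state$prediction + delta
  state$u <- state$loss$negative_gradient(state$y, state$prediction)
  state$m <- state$m + 1L
  state$selected <- j
  state
}

#' Inner stopping rule for a batch
#'
#' After each boosting step the largest absolute in-batch correlation to
#' the current negative gradient is compared against the batch's frozen
#' out-of-batch threshold: when the threshold wins (strictly), a variant
#' outside the batch may fit better and a new batch should be built. To
#' keep the comparison coherent while the residual scale shrinks over the
#' inner iterations, the in-batch side is evaluated with the residual
#' standard deviation frozen at batch creation (equivalently, both sides
#' are compared on the covariance scale); under mutually independent
#' variants this makes the batched algorithm reproduce the full-data
#' selection order exactly. The inner loop also stops unconditionally after
#' `m_batch` steps.
#'
#' @param batch A `variant_batch`.
#' @param G Genotypes.
#' @param u Current negative gradient.
#' @param steps_in_batch Number of boosting steps already taken on this
#'   batch.
#' @param m_batch Maximum steps per batch.
#' @return `TRUE` if the inner loop should stop.
#' @export
check_inner_stop <- function(batch, G, u, steps_in_batch, m_batch) {
  if (steps_in_batch >= m_batch) return(TRUE)
  if (!is.finite(batch$c_stop_cov %||% batch$c_stop)) return(FALSE)
  X <- .dosage_matrix(G)
  mom <- .col_moments(X[, batch$indices, drop = FALSE])
  covs <- .col_cov(X[, batch$indices, drop = FALSE], u, mom$mean)
  stat <- ifelse(mom$sd > 0, abs(covs) / mom$sd, 0)
  batch$c_stop_cov > max(stat)
}
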