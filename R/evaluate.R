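#' Predictive-performance metrics
#'
#' For continuous phenotypes: MSEP (mean squared error of prediction on the
#' supplied samples), its square root RMSEP, and the R-squared defined as
#' the *squared Pearson correlation* between predicted and observed
#' phenotype — the conventional PRS headline metric, which is invariant to
#' affine recalibration of the score. (The alternative `1 - SSE/SST`
#' definition is also returned as `r2_sse` for reference.) For binary
#' phenotypes: the AUC in its Mann-Whitney formulation (ties counted 1/2)
#' and the mean log loss.
#'
#' @param y Observed phenotype.
#' @param yhat Predicted phenotype (probabilities when `binary = TRUE`).
#' @param binary Treat the phenotype as binary.
#' @param bootstrap Number of percentile-bootstrap resamples for a 95 percent
#'   confidence interval on the headline metric (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @return A one-row tibble of metrics (with `*_lo` / `*_hi` CI columns
#'   when `bootstrap > 0`).
#' @export
prediction_metrics <- function(y, yhat, binary = FALSE, bootstrap = 0, seed = 1) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length", call. = FALSE)
  if (binary) {
    out <- tibble::tibble(auc = auc_mann_whitney(y, yhat),
                          log_loss = log_loss(y, yhat))
    if (bootstrap > 0) {
      set.seed(seed)
      bs <- replicate(bootstrap, {
        i <- sample.int(length(y), replace = TRUE)
        auc_mann_whitney(y[i], yhat[i])
      })
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
      out$auc_lo <- unname(ci[1]); out$auc_hi <- unname(ci[2])
    }
  } else {
    msep <- mean((yhat - y)^2)
    if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
      warning("constant predictions or phenotype: R-squared reported as 0", call. = FALSE)
      r2 <- 0
    } else {
      r2 <- stats::cor(y, yhat)^2
    }
    sst <- sum((y - mean(y))^2)
    out <- tibble::tibble(msep = msep, rmsep = sqrt(msep), r2 = r2,
                          r2_sse = if (sst > 0) 1 - sum((y - yhat)^2) / sst else NA_real_)
    if (bootstrap > 0) {
      set.seed(seed)
      bs <- replicate(bootstrap, {
        i <- sample.int(length(y), replace = TRUE)
        if (stats::sd(yhat[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
        else stats::cor(y[i], yhat[i])^2
      })
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
      out$r2_lo <- unname(ci[1]); out$r2_hi <- unname(ci[2])
    }
  }
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly drawn case scores higher than a randomly
#' drawn control, with ties contributing 1/2; computed from midranks, so it
#' equals exhaustive concordant-pair counting.
#'
#' @param y Binary labels `{0, 1}`.
#' @param score Numeric scores or probabilities.
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(y, score) {
  if (!all(y %in% c(0, 1))) stop("y must be coded {0, 1}", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Variant-selection metrics against simulation truth
#'
#' True positive rate (share of causal variants selected), precision (share
#' of selected variants that are causal) and the mean squared error of the
#' coefficient estimates, averaged over *all* `p` variants with
#' non-selected and non-causal coefficients treated as 0 (set
#' `causal_only = TRUE` to average over the causal variants instead).
#'
#' @param model A `prs_model` fitted on simulated data.
#' @param truth The `sim_truth` from the simulator.
#' @param variant_ids Character vector giving the variant id of each
#'   simulated column, used to map selected ids back to indices; defaults
#'   to the ids stored in the model's coefficient table matched against
#'   positional `sim` ids. Supply `G$variants$variant_id`
#'   when in doubt.
#' @param causal_only Average the coefficient MSE over causal variants
#'   only.
#' @return A one-row tibble: `n_selected`, `tp_rate`, `precision`,
#'   `coef_mse`.
#' @export
selection_metrics <- function(model, truth, variant_ids = NULL,
                              causal_only = FALSE) {
  stopifnot(inherits(model, "prs_model"), inherits(truth, "sim_truth"))
  p <- length(truth$true_beta)
  beta_hat <- numeric(p)
  if (nrow(model$coefficients) > 0) {
    if (is.null(variant_ids))
      variant_ids <- sprintf("sim%0*d", nchar(p), seq_len(p))
    sel <- match(model$coefficients$variant_id, variant_ids)
    if (anyNA(sel)) stop("model variants not found among simulated variant ids", call. = FALSE)
    beta_hat[sel] <- model$coefficients$beta
  } else sel <- integer(0)
  causal <- truth$causal_indices
  n_sel <- length(sel)
  tp <- length(intersect(sel, causal))
  if (n_sel == 0) warning("no variants selected; precision reported as 0", call. = FALSE)
  idx <- if (causal_only) causal else seq_len(p)
  tibble::tibble(
    n_selected = n_sel,
    tp_rate = if (length(causal)) tp / length(causal) else NA_real_,
    precision = if (n_sel > 0) tp / n_sel else 0,
    coef_mse = if (length(idx)) mean((beta_hat[idx] - truth$true_beta[idx])^2) else NA_real_
  )
}
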