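#' Loss functions for boosting
#'
#' The boosting engine is loss-agnostic: a loss is a small contract holding
#' the mean loss, its negative gradient with respect to the model's
#' prediction, and the name of the validation metric it monitors.
#'
#' * `"l2"`: squared-error loss for continuous traits. Predictions are on
#'   the phenotype scale; the negative gradient is the residual `y - yhat`,
#'   and the monitored validation metric is the mean squared error of
#'   prediction (MSEP).
#' * `"log"`: log loss (binomial deviance) for binary traits. Predictions
#'   are *linear predictors* `eta`; the negative gradient is
#'   `y - plogis(eta)` and the monitored metric is the mean log loss.
#'
#' @param name `"l2"` or `"log"`.
#' @return A `loss_spec` list with elements `name`, `evaluate(y, prediction)`,
#'   `negative_gradient(y, prediction)` and `validation_metric`.
#' @examples
#' ls <- loss_spec("l2")
#' ls$negative_gradient(c(1, 2), c(0, 0))
#' @export
loss_spec <- function(name = c("l2", "log")) {
  name <- match.arg(name)
  if (name == "l2") {
    list(
      name = "l2",
      evaluate = function(y, prediction) l2_loss(y, prediction),
      negative_gradient = function(y, prediction) y - prediction,
      validation_metric = "msep"
    )
  } else {
    list(
      name = "log",
      evaluate = function(y, prediction) log_loss(y, logistic_link(prediction)),
      negative_gradient = function(y, prediction) y - logistic_link(prediction),
      validation_metric = "log_loss"
    )
  }
}

#' Mean squared-error loss
#'
#' `(1/n) * sum((yhat - y)^2)`. The mean convention makes the value
#' directly comparable across sample sizes and identical to the MSEP when
#' evaluated on a held-out set.
#'
#' @param y,yhat Numeric vectors of equal length.
#' @return Scalar mean squared error.
#' @export
l2_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 1) stop("need at least one observation", call. = FALSE)
  mean((yhat - y)^2)
}

#' Mean log loss (binomial deviance)
#'
#' `-(1/n) * sum(y*log(p) + (1-y)*log(1-p))`, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` so saturated predictors yield a finite loss.
#'
#' @param y Binary vector in `{0, 1}`.
#' @param p_hat Probability vector.
#' @return Scalar mean log loss.
#' @export
log_loss <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("y and p_hat must have equal length", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be coded {0, 1}", call. = FALSE)
  p <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Logistic (inverse-logit) link
#'
#' Maps a linear predictor to a probability, `exp(eta) / (1 + exp(eta))`,
#' computed overflow-safely via [stats::plogis()].
#'
#' @param eta Numeric vector of linear predictors.
#' @return Probabilities in `(0, 1)`.
#' @export
logistic_link <- function(eta) stats::plogis(eta)

#' Negative gradient of a loss at the current prediction
#'
#' For the squared-error loss this is the residual vector `y - yhat`; for
#' the log loss it is `y - plogis(eta)`, where the prediction is the linear
#' predictor.
#'
#' @param loss A `loss_spec` (or its name).
#' @param y Response vector.
#' @param prediction Current model prediction (phenotype scale for `"l2"`,
#'   linear predictor for `"log"`).
#' @return Length-`n` numeric vector.
#' @export
negative_gradient <- function(loss, y, prediction) {
  if (is.character(loss)) loss <- loss_spec(loss)
  if (length(y) != length(prediction)) stop("y and prediction must have equal length", call. = FALSE)
  loss$negative_gradient(y, prediction)
}
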