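#' Downstream models relating a fitted PRS to the phenotype
#'
#' After the PRS itself is fitted, its added value is typically quantified
#' by small regression models on the combined training and validation
#' samples, evaluated on the independent test set:
#'
#' * `kind = "prs"`: phenotype on the PRS alone
#'   (`y = gamma_0 + gamma_PRS * PRS`).
#' * `kind = "full"`: phenotype on the PRS plus covariates such as sex, age
#'   and genetic principal components.
#' * `kind = "covariates"`: covariates only — the baseline against which
#'   the PRS's contribution is measured.
#'
#' A fourth variant — including the covariates directly in the boosting fit
#' as mandatory terms — is not a downstream model: pass `covariates` to
#' [prs_boost()] instead.
#'
#' Continuous phenotypes are fitted by ordinary least squares, binary ones
#' by maximum-likelihood logistic regression.
#'
#' @param prs_values Numeric vector of PRS values (ignored for
#'   `kind = "covariates"`).
#' @param covariates Covariate matrix or data frame (ignored for
#'   `kind = "prs"`; may be `NULL` for an intercept-only baseline).
#' @param y Phenotype vector (binary `{0,1}` when `binary = TRUE`).
#' @param kind Which design to fit.
#' @param binary Logistic instead of linear regression.
#' @return A `downstream_model`: list with `kind`, `binary`, the fitted
#'   coefficients (`gamma0`, `gamma_prs`, `gamma_covariates`) and the
#'   underlying `stats::lm`/`stats::glm` fit.
#' @export
fit_downstream <- function(prs_values, covariates = NULL, y,
                           kind = c("prs", "full", "covariates"),
                           binary = FALSE) {
  kind <- match.arg(kind)
  n <- length(y)
  use_prs <- kind %in% c("prs", "full")
  use_cov <- kind %in% c("full", "covariates")
  dat <- data.frame(y = y)
  if (use_prs) {
    if (length(prs_values) != n) stop("prs_values must have length(y)", call. = FALSE)
    if (stats::var(prs_values) == 0) stop("PRS is constant; cannot fit a PRS model", call. = FALSE)
    dat$prs <- prs_values
  }
  cov_names <- character(0)
  if (use_cov && !is.null(covariates) && NCOL(covariates) > 0) {
    Cm <- as.matrix(covariates)
    cov_names <- colnames(Cm) %||% paste0("covariate_", seq_len(ncol(Cm)))
    colnames(Cm) <- cov_names
    dat <- cbind(dat, as.data.frame(Cm))
  }
  fml <- stats::as.formula(paste("y ~", paste(c(if (use_prs) "prs", cov_names, "1"),
                                              collapse = " + ")))
  fit <- if (binary) stats::glm(fml, data = dat, family = stats::binomial())
         else stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  structure(
    list(kind = kind, binary = binary,
         gamma0 = unname(cf["(Intercept)"]),
         gamma_prs = if (use_prs) unname(cf["prs"]) else NULL,
         gamma_covariates = if (length(cov_names)) cf[cov_names] else NULL,
         fit = fit),
    class = "downstream_model"
  )
}

#' @export
print.downstream_model <- function(x, ...) {
  cat(sprintf("<downstream_model> kind=%s (%s)\n", x$kind,
              if (x$binary) "logistic" else "linear"))
  print(tidy.downstream_model(x))
  invisible(x)
}

#' @method tidy downstream_model
#' @export
tidy.downstream_model <- function(x, ...) broom::tidy(x$fit, ...)

#' @method glance downstream_model
#' @export
glance.downstream_model <- function(x, ...) broom::glance(x$fit, ...)

#' Predict from a downstream model
#'
#' @param object A `downstream_model`.
#' @param prs_values,covariates New data matching the model's design.
#' @param type `"response"` (default; probabilities for logistic models) or
#'   `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.downstream_model <- function(object, prs_values = NULL, covariates = NULL,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  nd <- data.frame(row.names = seq_len(max(length(prs_values), NROW(covariates), 1)))
  if (!is.null(object$gamma_prs)) nd$prs <- prs_values
  if (!is.null(object$gamma_covariates)) {
    Cm <- as.matrix(covariates)
    colnames(Cm) <- names(object$gamma_covariates)
    nd <- cbind(nd, as.data.frame(Cm))
  }
  stats::predict(object$fit, newdata = nd,
                 type = if (object$binary) type else "response")
}

#' Adjust measured LDL cholesterol for statin use
#'
#' Multiplies the measured LDL value by 0.684 for individuals on statin
#' therapy, leaving others untouched. Note the direction is the literal
#' multiplicative adjustment; if instead one wants to reconstruct the
#' untreated value from an on-treatment measurement, the measured value
#' would be *divided* by the factor. The literal multiplication is what is
#' implemented here.
#'
#' @param y_measured Measured LDL values.
#' @param on_statin Logical vector of the same length.
#' @param factor Adjustment factor (default 0.684).
#' @return Adjusted LDL vector.
#' @export
adjust_ldl_statin <- function(y_measured, on_statin, factor = 0.684) {
  if (length(y_measured) != length(on_statin))
    stop("y_measured and on_statin must have equal length", call. = FALSE)
  out <- y_measured
  out[on_statin] <- out[on_statin] * factor
  out
}
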