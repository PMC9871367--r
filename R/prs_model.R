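# The fitted PRS as a portable object: a sparse coefficient vector keyed by
# variant id and alleles, shareable exactly like summary statistics.

new_prs_model <- function(intercept, beta, gamma, cov_names, loss, control,
                          n_iterations, n_batches, variants, path,
                          validation_loss) {
  nz <- which(beta != 0)
  coefficients <- variants[nz, , drop = FALSE]
  coefficients$beta <- beta[nz]
  gamma <- stats::setNames(as.numeric(gamma), cov_names)
  structure(
    list(intercept = intercept,
         coefficients = tibble::as_tibble(coefficients),
         covariate_coefficients = gamma,
         loss = loss, control = control,
         n_iterations = as.integer(n_iterations),
         n_batches = as.integer(n_batches),
         path = path,
         validation_loss = validation_loss),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %s loss: %d variants, %d covariates; %d iterations in %d batch(es)\n",
              x$loss, nrow(x$coefficients), length(x$covariate_coefficients),
              x$n_iterations, x$n_batches))
  if (!is.na(x$validation_loss))
    cat(sprintf("  best validation %s: %.6g\n",
                if (x$loss == "l2") "MSEP" else "log loss", x$validation_loss))
  invisible(x)
}

#' Score samples with a fitted PRS
#'
#' Computes the linear score `intercept + sum_j beta_j * dosage_j` (plus
#' covariate terms when the model carries them and `covariates` is given).
#' Every model variant must be present in the target genotypes. If a target
#' variant lists the model's alleles swapped (its effect allele is the
#' model's other allele and vice versa), the dosage is flipped to
#' `2 - dosage` before scoring; any other allele combination is an error —
#' no strand-flip inference is attempted.
#'
#' @param object A `prs_model`.
#' @param genotypes A [genotype_matrix()] containing the model's variants
#'   (no missing values among them).
#' @param covariates Covariate matrix matching the model's covariate
#'   coefficients (optional when the model has none).
#' @param type `"link"` returns the linear score; `"response"` additionally
#'   applies the logistic link for log-loss models (probabilities).
#' @param ... Unused.
#' @return Numeric vector of scores, one per sample.
#' @export
predict.prs_model <- function(object, genotypes, covariates = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  cf <- object$coefficients
  score <- rep(object$intercept, n_samples(genotypes))
  if (nrow(cf) > 0) {
    pos <- match(cf$variant_id, genotypes$variants$variant_id)
    if (anyNA(pos))
      stop("variants absent from target genotypes: ",
           paste(utils::head(cf$variant_id[is.na(pos)], 5), collapse = ", "),
           call. = FALSE)
    tv <- genotypes$variants[pos, ]
    same <- tv$effect_allele == cf$effect_allele & tv$other_allele == cf$other_allele
    swapped <- tv$effect_allele == cf$other_allele & tv$other_allele == cf$effect_allele
    if (any(!same & !swapped))
      stop("allele mismatch not resolvable by swap for: ",
           paste(utils::head(cf$variant_id[!same & !swapped], 5), collapse = ", "),
           call. = FALSE)
    D <- genotypes$dosages[, pos, drop = FALSE]
    if (anyNA(D)) stop("missing dosages among model variants; impute first", call. = FALSE)
    if (any(swapped)) D[, swapped] <- 2 - D[, swapped]
    score <- score + as.vector(D %*% cf$beta)
  }
  q <- length(object$covariate_coefficients)
  if (q > 0) {
    if (is.null(covariates))
      stop("model includes covariate coefficients; supply `covariates`", call. = FALSE)
    Cm <- as.matrix(covariates)
    if (ncol(Cm) != q) stop("covariates must have ", q, " columns", call. = FALSE)
    score <- score + as.vector(Cm %*% object$covariate_coefficients)
  }
  if (type == "response" && object$loss == "log") logistic_link(score) else score
}

#' Export / import a PRS as a summary-statistics-style score file
#'
#' The score file is tab-delimited with columns `variant_id`, `chromosome`,
#' `position`, `effect_allele`, `other_allele`, `beta`, preceded by `#`
#' comment lines carrying the intercept, the loss and any covariate
#' coefficients. Exporting and re-importing a model reproduces its
#' predictions bit-identically (coefficients are written in full binary
#' precision).
#'
#' @param model A `prs_model`.
#' @param path Output (input) file path.
#' @return `export_prs` returns `path` invisibly; `import_prs` returns a
#'   `prs_model` (without the fitting path).
#' @export
export_prs <- function(model, path) {
  stopifnot(inherits(model, "prs_model"))
  hdr <- c(
    sprintf("# intercept\t%s", .fmt_full(model$intercept)),
    sprintf("# loss\t%s", model$loss)
  )
  if (length(model$covariate_coefficients) > 0)
    hdr <- c(hdr, sprintf("# covariate\t%s\t%s",
                          names(model$covariate_coefficients),
                          .fmt_full(model$covariate_coefficients)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "beta", sep = "\t"), con)
  if (nrow(model$coefficients) > 0) {
    cf <- model$coefficients
    writeLines(paste(cf$variant_id, cf$chromosome, cf$position,
                     cf$effect_allele, cf$other_allele, .fmt_full(cf$beta),
                     sep = "\t"), con)
  }
  invisible(path)
}

.fmt_full <- function(x) sprintf("%.17g", x)

#' @rdname export_prs
#' @export
import_prs <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  intercept <- 0; loss <- "l2"; gamma <- numeric(0)
  for (h in lines[is_hdr]) {
    f <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    if (f[1] == "intercept") intercept <- as.numeric(f[2])
    else if (f[1] == "loss") loss <- f[2]
    else if (f[1] == "covariate") gamma <- c(gamma, stats::setNames(as.numeric(f[3]), f[2]))
  }
  body <- lines[!is_hdr]
  if (length(body) == 0 || !identical(strsplit(body[1], "\t")[[1]][1], "variant_id"))
    stop("malformed PRS file: missing column header", call. = FALSE)
  rows <- body[-1]
  if (length(rows) > 0) {
    parts <- strsplit(rows, "\t")
    bad <- which(lengths(parts) != 6)
    if (length(bad))
      stop("malformed PRS file row at line ", which(!is_hdr)[bad[1] + 1L], call. = FALSE)
    mat <- do.call(rbind, parts)
    variants <- tibble::tibble(
      variant_id = mat[, 1], chromosome = mat[, 2],
      position = as.integer(mat[, 3]),
      effect_allele = mat[, 4], other_allele = mat[, 5]
    )
    beta <- as.numeric(mat[, 6])
    if (anyNA(beta)) stop("malformed PRS file: non-numeric beta", call. = FALSE)
  } else {
    variants <- tibble::tibble(variant_id = character(0), chromosome = character(0),
                               position = integer(0), effect_allele = character(0),
                               other_allele = character(0))
    beta <- numeric(0)
  }
  new_prs_model(
    intercept = intercept, beta = beta, gamma = gamma, cov_names = names(gamma),
    loss = loss, control = boost_control(), n_iterations = NA_integer_,
    n_batches = NA_integer_, variants = variants,
    path = list(iterations = tibble::tibble(), batches = tibble::tibble()),
    validation_loss = NA_real_
  )
}

#' Tidy the coefficients of a fitted PRS
#'
#' @param x A `prs_model`.
#' @param ... Unused.
#' @return A tibble with one row per selected variant (`variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `beta`),
#'   followed by covariate rows if the model has them.
#' @method tidy prs_model
#' @export
tidy.prs_model <- function(x, ...) {
  out <- x$coefficients
  if (length(x$covariate_coefficients) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(variant_id = names(x$covariate_coefficients),
                     chromosome = NA_character_, position = NA_integer_,
                     effect_allele = NA_character_, other_allele = NA_character_,
                     beta = unname(x$covariate_coefficients))
    )
  }
  out
}

#' One-row summary of a fitted PRS
#'
#' @param x A `prs_model`.
#' @param ... Unused.
#' @return A one-row tibble: loss, number of selected variants, iterations,
#'   batches, and the best validation loss.
#' @method glance prs_model
#' @export
glance.prs_model <- function(x, ...) {
  tibble::tibble(
    loss = x$loss,
    n_variants = nrow(x$coefficients),
    n_covariates = length(x$covariate_coefficients),
    n_iterations = x$n_iterations,
    n_batches = x$n_batches,
    validation_loss = x$validation_loss
  )
}

#' Plot a fitted PRS
#'
#' `what = "path"` shows the validation loss over batches (the early
#' stopping trajectory); `what = "coefficients"` shows the absolute
#' coefficient of each selected variant against genomic position.
#'
#' @param object A `prs_model`.
#' @param what `"path"` or `"coefficients"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prs_model
#' @export
autoplot.prs_model <- function(object, what = c("path", "coefficients"), ...) {
  what <- match.arg(what)
  if (what == "path") {
    d <- object$path$batches
    if (nrow(d) == 0 || all(is.na(d$validation_loss)))
      stop("model carries no validation path to plot", call. = FALSE)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$validation_loss)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = object$n_batches, linetype = 2) +
      ggplot2::labs(x = "batch", y = if (object$loss == "l2") "validation MSEP" else "validation log loss")
  } else {
    d <- object$coefficients
    ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = abs(.data$beta))) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
      ggplot2::labs(x = "position", y = "|coefficient|")
  }
}
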