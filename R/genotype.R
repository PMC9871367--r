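#' Genotype dosage matrix with variant metadata
#'
#' Container for an `n x p` matrix of effect-allele dosages in `[0, 2]`,
#' with `NA` marking missing genotypes, a variant annotation table and
#' sample identifiers. This is the object every fitting, filtering and
#' scoring function in the package consumes.
#'
#' @param dosages Numeric matrix (samples in rows, variants in columns).
#'   Non-missing entries must lie in `[0, 2]`; missing genotypes are `NA`.
#' @param variants A data frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele` (one row per column of
#'   `dosages`). If `NULL`, placeholder annotation is generated.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to rownames of `dosages` or `sample_1 ... sample_n`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (tibble) and `sample_ids`.
#'
#' @details Dosages count copies of the *effect allele* (PLINK A1). Minor
#'   allele frequencies are folded to `<= 0.5` for filtering, but dosages are
#'   never flipped: fitted coefficients are always signed relative to the
#'   stored effect allele.
#'
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2, 1), nrow = 2))
#' n_samples(G); n_variants(G)
#' @export
genotype_matrix <- function(dosages, variants = NULL, sample_ids = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
    else stop("`dosages` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(max(n, 0L)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("length(sample_ids) must equal nrow(dosages)", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (is.null(variants)) {
    variants <- tibble::tibble(
      variant_id = sprintf("v%d", seq_len(p)),
      chromosome = "1",
      position = seq_len(p),
      effect_allele = "A",
      other_allele = "B"
    )
  }
  variants <- tibble::as_tibble(variants)
  req <- c("variant_id", "chromosome", "position", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(variants) != p) stop("nrow(variants) must equal ncol(dosages)", call. = FALSE)
  if (anyDuplicated(variants$variant_id)) {
    dup <- variants$variant_id[duplicated(variants$variant_id)][1]
    stop("duplicate variant_id: ", dup, call. = FALSE)
  }
  if (p > 0) {
    if (any(variants$effect_allele == variants$other_allele))
      stop("effect_allele must differ from other_allele", call. = FALSE)
    if (any(variants$position < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  }
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (n > 0 && p > 0 && any(!is.na(dosages)) && (rng[1] < 0 || rng[2] > 2))
    stop("non-missing dosages must lie in [0, 2]", call. = FALSE)
  dimnames(dosages) <- NULL
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @rdname genotype_matrix
#' @param G A `genotype_matrix`.
#' @export
n_samples <- function(G) nrow(G$dosages)

#' @rdname genotype_matrix
#' @export
n_variants <- function(G) ncol(G$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
    n_samples(x), n_variants(x), 100 * miss
  ))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  genotype_matrix(
    x$dosages[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    sample_ids = x$sample_ids[i]
  )
}

.dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$dosages
  else if (is.matrix(G) && is.numeric(G)) G
  else stop("expected a genotype_matrix or a numeric matrix", call. = FALSE)
}

#' Per-variant allele frequency and call-rate summaries
#'
#' @param G A `genotype_matrix`.
#' @return A tibble with one row per variant: `variant_id`, `call_rate`,
#'   effect-allele frequency `eaf`, and folded minor allele frequency `maf`.
#' @export
variant_stats <- function(G) {
  X <- .dosage_matrix(G)
  n <- nrow(X)
  n_obs <- n - colSums(is.na(X))
  eaf <- ifelse(n_obs > 0, colMeans(X, na.rm = TRUE) / 2, NA_real_)
  tibble::tibble(
    variant_id = if (inherits(G, "genotype_matrix")) G$variants$variant_id else sprintf("v%d", seq_len(ncol(X))),
    call_rate = if (n > 0) n_obs / n else rep(0, ncol(X)),
    eaf = eaf,
    maf = pmin(eaf, 1 - eaf)
  )
}

#' Filter variants on minor allele frequency and call rate
#'
#' Keeps exactly the variants whose observed call rate is at least
#' `call_rate_min` and whose folded minor allele frequency (computed on the
#' non-missing dosages) is at least `maf_min`; variant order is preserved.
#' A variant with no observed genotypes has call rate 0 and is dropped
#' whenever `call_rate_min > 0` (and has no defined MAF, so it is also
#' dropped for any `maf_min > 0`).
#'
#' @param G A `genotype_matrix`.
#' @param maf_min Minimum folded minor allele frequency, in `[0, 0.5]`.
#' @param call_rate_min Minimum per-variant call rate, in `[0, 1]`.
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(G, maf_min = 0.001, call_rate_min = 0.9) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]", call. = FALSE)
  if (call_rate_min < 0 || call_rate_min > 1) stop("call_rate_min must be in [0, 1]", call. = FALSE)
  st <- variant_stats(G)
  # an all-missing variant has undefined MAF: count it as 0, so it only
  # survives when both thresholds are vacuous
  keep <- st$call_rate >= call_rate_min &
    ifelse(is.na(st$maf), 0, st$maf) >= maf_min
  G[, which(keep)]
}

#' Impute missing genotype dosages
#'
#' @param G A `genotype_matrix`.
#' @param strategy `"mean"` replaces each missing cell with the per-variant
#'   mean of the complete observations; `"reference"` replaces it with 0
#'   (zero copies of the effect allele, i.e. homozygous for the other
#'   allele).
#' @return A `genotype_matrix` with no missing entries; non-missing cells
#'   are untouched.
#' @export
impute_missing <- function(G, strategy = c("mean", "reference")) {
  stopifnot(inherits(G, "genotype_matrix"))
  strategy <- match.arg(strategy)
  X <- G$dosages
  na_idx <- which(is.na(X))
  if (length(na_idx) == 0) return(G)
  if (strategy == "reference") {
    X[na_idx] <- 0
  } else {
    n_obs <- nrow(X) - colSums(is.na(X))
    if (any(n_obs == 0)) {
      bad <- G$variants$variant_id[which(n_obs == 0)[1]]
      stop("cannot mean-impute variant with no observed genotypes: ", bad, call. = FALSE)
    }
    mu <- colMeans(X, na.rm = TRUE)
    X[na_idx] <- mu[((na_idx - 1) %/% nrow(X)) + 1]
  }
  genotype_matrix(X, variants = G$variants, sample_ids = G$sample_ids)
}

#' Align a genotype matrix and a phenotype table on shared samples
#'
#' Restricts both inputs to the intersection of their sample identifiers,
#' in the genotype matrix's order, and reports how many samples were
#' dropped from each side.
#'
#' @param G A `genotype_matrix`.
#' @param phenotype A data frame keyed by an `IID` column (plus anything
#'   else: phenotype values, covariates, `FID`).
#' @param id_col Name of the identifier column in `phenotype`.
#' @return A list with elements `genotypes`, `phenotype` (tibble) and
#'   `dropped` (named counts for each side).
#' @export
align_samples <- function(G, phenotype, id_col = "IID") {
  stopifnot(inherits(G, "genotype_matrix"))
  phenotype <- tibble::as_tibble(phenotype)
  if (!id_col %in% names(phenotype)) stop("phenotype table has no column `", id_col, "`", call. = FALSE)
  ids_p <- as.character(phenotype[[id_col]])
  shared <- G$sample_ids[G$sample_ids %in% ids_p]
  if (length(shared) == 0) stop("no shared samples between genotypes and phenotype table", call. = FALSE)
  g_idx <- match(shared, G$sample_ids)
  p_idx <- match(shared, ids_p)
  list(
    genotypes = G[g_idx, ],
    phenotype = phenotype[p_idx, , drop = FALSE],
    dropped = c(
      genotypes = n_samples(G) - length(shared),
      phenotype = nrow(phenotype) - length(shared)
    )
  )
}

#' Read a whitespace-delimited phenotype/covariate table
#'
#' Expects a header line containing `FID` and `IID` key columns, as used by
#' PLINK-style phenotype files. A binary phenotype coded `{1, 2}`
#' (PLINK case/control) is shifted to `{0, 1}` with a warning when
#' `binary = TRUE`.
#'
#' @param path File path.
#' @param phenotype_col Name of the phenotype column (default: first
#'   non-key column).
#' @param binary If `TRUE`, validate/recode the phenotype as `{0, 1}`.
#' @return A tibble.
#' @export
read_phenotype <- function(path, phenotype_col = NULL, binary = FALSE) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  tab <- tibble::as_tibble(tab)
  for (key in c("FID", "IID")) {
    if (!key %in% names(tab)) stop("phenotype file lacks required column ", key, call. = FALSE)
    tab[[key]] <- as.character(tab[[key]])
  }
  if (is.null(phenotype_col)) phenotype_col <- setdiff(names(tab), c("FID", "IID"))[1]
  if (is.na(phenotype_col) || !phenotype_col %in% names(tab))
    stop("phenotype column not found", call. = FALSE)
  y <- tab[[phenotype_col]]
  if (anyNA(y)) stop("missing values in phenotype column `", phenotype_col, "`", call. = FALSE)
  if (binary) {
    u <- sort(unique(y))
    if (all(u %in% c(1, 2)) && length(u) > 0) {
      warning("binary phenotype coded {1,2}; recoding to {0,1}", call. = FALSE)
      tab[[phenotype_col]] <- y - 1
    } else if (!all(u %in% c(0, 1))) {
      stop("binary phenotype must be coded {0,1} (or PLINK {1,2})", call. = FALSE)
    }
  }
  tab
}
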