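#' Configuration for the genotype/phenotype simulator
#'
#' The simulator emulates the statistical structure of a cohort-based PRS
#' study: dosages in `{0, 1, 2}` drawn at per-variant allele frequencies,
#' optional block-structured linkage disequilibrium, and phenotypes from a
#' sparse linear model with Gaussian noise calibrated to a target
#' heritability.
#'
#' @param n Number of samples.
#' @param p Number of variants.
#' @param maf_range Allele-frequency range; each variant's effect-allele
#'   frequency is drawn uniformly from it. Default `c(0.01, 0.5)` (common
#'   variants, MAF of at least 0.01).
#' @param h2 Heritability: the fraction of phenotypic variance explained by
#'   the genetic component.
#' @param s Sparsity: the fraction of variants that are causal
#'   (`round(s * p)` of them).
#' @param seed Integer seed; all simulator outputs are reproducible from it.
#' @param ld_block_size Variants per LD block (1 = independent variants).
#' @param ld_rho Latent pairwise correlation within an LD block.
#' @param split Training/validation/test fractions (must sum to 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n, p, maf_range = c(0.01, 0.5), h2 = 0.5, s = 0.01,
                       seed = 1, ld_block_size = 1, ld_rho = 0,
                       split = c(0.5, 0.2, 0.3)) {
  stopifnot(n >= 1, p >= 1)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5))
    stop("maf_range must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  stopifnot(h2 >= 0, h2 <= 1, s > 0, s <= 1, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1)
  if (h2 > 0 && round(s * p) < 1)
    stop("round(s * p) must be at least 1 when h2 > 0", call. = FALSE)
  if (length(split) != 3 || any(split <= 0) || abs(sum(split) - 1) > 1e-8)
    stop("split must be three positive fractions summing to 1", call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p), maf_range = maf_range,
                 h2 = h2, s = s, seed = as.integer(seed),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 split = split),
            class = "sim_config")
}

#' Simulate a genotype dosage matrix
#'
#' Per variant, an effect-allele frequency is drawn uniformly from
#' `maf_range`. With `ld_block_size = 1`, dosages are independent
#' `Binomial(2, f)` draws. With larger blocks, the two allele copies of
#' each variant are generated from latent Gaussians sharing a block-level
#' component with pairwise correlation `ld_rho`, thresholded at the allele
#' frequency, so genotype frequencies follow Hardy-Weinberg proportions
#' while variants within a block are positively correlated.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with no missing entries.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n; p <- cfg$p
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$ld_block_size == 1 || cfg$ld_rho == 0) {
    X <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), nrow = n)
  } else {
    X <- matrix(0, n, p)
    rho <- cfg$ld_rho
    blocks <- split(seq_len(p), ceiling(seq_len(p) / cfg$ld_block_size))
    for (b in blocks) {
      # one latent Gaussian per allele copy, sharing a block factor
      for (copy in 1:2) {
        shared <- stats::rnorm(n)
        Z <- sqrt(rho) * shared +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(b)), n)
        thr <- stats::qnorm(maf[b])
        X[, b] <- X[, b] + (Z < rep(thr, each = n))
      }
    }
  }
  genotype_matrix(
    X,
    variants = tibble::tibble(
      variant_id = sprintf("sim%0*d", nchar(p), seq_len(p)),
      chromosome = "1", position = seq_len(p),
      effect_allele = "A", other_allele = "G"
    ),
    sample_ids = sprintf("id%0*d", nchar(n), seq_len(n))
  )
}

#' Simulate a continuous phenotype from a sparse linear model
#'
#' Chooses `round(s * p)` causal variants uniformly at random, draws their
#' effects from a standard Gaussian, and adds Gaussian noise whose variance
#' is solved from the *realized* sample variance of the genetic component
#' `g = X_causal %*% beta` so that `var(g) / var(y)` hits the target
#' heritability tightly even at small `n`:
#' `var(noise) = var(g) * (1 - h2) / h2`.
#'
#' @param G Genotypes from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A list: `phenotype` (tibble with `FID`, `IID`, `pheno`) and
#'   `truth` (a `sim_truth` with `causal_indices`, `true_beta` over all `p`
#'   variants, `genetic_component`, `realized_h2`).
#' @export
simulate_phenotype <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  p <- n_variants(G); n <- n_samples(G)
  n_causal <- max(round(cfg$s * p), 1L)
  causal <- sort(sample.int(p, n_causal))
  beta <- numeric(p)
  beta[causal] <- stats::rnorm(n_causal)
  g <- as.vector(G$dosages[, causal, drop = FALSE] %*% beta[causal])
  vg <- stats::var(g)
  if (cfg$h2 == 0 || vg == 0) {
    if (cfg$h2 == 0)
      warning("h2 = 0: phenotype is pure noise; truth carries no effective signal",
              call. = FALSE)
    y <- stats::rnorm(n)
    g_eff <- rep(0, n)
    beta <- numeric(p); causal_eff <- integer(0)
  } else if (cfg$h2 == 1) {
    y <- g
    g_eff <- g; causal_eff <- causal
  } else {
    # draw noise, then remove its sample projection on (1, g) and rescale so
    # the realized variance ratio var(g)/var(y) equals h2 exactly
    eps <- stats::rnorm(n)
    eps <- stats::residuals(stats::lm.fit(cbind(1, g), eps))
    eps <- eps * sqrt(vg * (1 - cfg$h2) / cfg$h2 / stats::var(eps))
    y <- g + eps
    g_eff <- g; causal_eff <- causal
  }
  list(
    phenotype = tibble::tibble(FID = G$sample_ids, IID = G$sample_ids, pheno = y),
    truth = structure(
      list(causal_indices = causal_eff, true_beta = beta,
           genetic_component = g_eff,
           realized_h2 = if (stats::var(y) > 0) stats::var(g_eff) / stats::var(y) else 0),
      class = "sim_truth"
    )
  )
}

#' Simulate a binary phenotype under a logistic liability model
#'
#' The genetic component is rescaled so that, on the liability scale
#' (logistic residual variance `pi^2 / 3`), it explains the configured
#' `h2`; the intercept is then solved by monotone root-finding so the mean
#' case probability equals `prevalence`, and cases are drawn as Bernoulli
#' variables.
#'
#' @inheritParams simulate_phenotype
#' @param prevalence Target case fraction in `(0, 1)`.
#' @return As [simulate_phenotype()], with a binary `pheno` column; the
#'   truth's `true_beta` is on the rescaled liability scale.
#' @export
simulate_binary_phenotype <- function(G, cfg, prevalence = 0.2) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)", call. = FALSE)
  set.seed(cfg$seed + 1L)
  p <- n_variants(G); n <- n_samples(G)
  n_causal <- max(round(cfg$s * p), 1L)
  causal <- sort(sample.int(p, n_causal))
  beta <- numeric(p)
  beta[causal] <- stats::rnorm(n_causal)
  g <- as.vector(G$dosages[, causal, drop = FALSE] %*% beta[causal])
  vg <- stats::var(g)
  if (cfg$h2 > 0 && vg > 0) {
    target_vg <- cfg$h2 / (1 - cfg$h2) * pi^2 / 3
    scale <- sqrt(target_vg / vg)
    beta <- beta * scale
    g <- g * scale
  } else {
    g <- rep(0, n); beta <- numeric(p); causal <- integer(0)
  }
  gc <- g - mean(g)
  f <- function(a) mean(stats::plogis(a + gc)) - prevalence
  lo <- stats::qlogis(prevalence) - max(abs(gc)) - 1
  hi <- stats::qlogis(prevalence) + max(abs(gc)) + 1
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence unattainable for this genetic component", call. = FALSE)
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  eta <- alpha + gc
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(
    phenotype = tibble::tibble(FID = G$sample_ids, IID = G$sample_ids, pheno = y),
    truth = structure(
      list(causal_indices = causal, true_beta = beta, genetic_component = gc,
           realized_h2 = if (length(causal)) stats::var(gc) / (stats::var(gc) + pi^2 / 3) else 0,
           alpha = alpha),
      class = "sim_truth"
    )
  )
}

#' Random training/validation/test partition
#'
#' @param n Number of samples.
#' @param fractions Three positive fractions summing to 1 (default
#'   50/20/30).
#' @param seed Integer seed.
#' @return A list of disjoint, exhaustive index vectors `train`,
#'   `validation`, `test`.
#' @export
split_samples <- function(n, fractions = c(0.5, 0.2, 0.3), seed = 1) {
  if (length(fractions) != 3 || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive values summing to 1", call. = FALSE)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("n too small for a nonempty train/validation/test partition", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}
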