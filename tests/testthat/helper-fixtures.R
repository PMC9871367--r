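# Shared fixture builders. Everything is generated in code; no binary files
# ship with the package.

# small genotype matrix with controllable missingness
toy_genotypes <- function(n = 20, p = 6, seed = 1, miss = NULL) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  if (!is.null(miss)) X[miss] <- NA
  genotype_matrix(X)
}

# centered, exactly orthogonal columns (each a combination of centered
# Gaussians, hence mean zero); not dosages, but prs_boost accepts plain
# matrices for engine-level tests
orthogonal_columns <- function(n, p, seed = 1) {
  set.seed(seed)
  Xc <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  qr.Q(qr(Xc))
}

# write a hand-crafted single-byte PLINK triple:
# codes [hom-A1, het, hom-A2, missing] for 4 samples x 1 variant
write_hand_plink <- function(dir) {
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78)), paste0(prefix, ".bed"))
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("f%d\ti%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(prefix, ".fam"))
  prefix
}

# dense coefficient vector of a prs_model aligned with a genotype_matrix
dense_beta <- function(model, G) {
  b <- numeric(n_variants(G))
  if (nrow(model$coefficients) > 0)
    b[match(model$coefficients$variant_id, G$variants$variant_id)] <-
      model$coefficients$beta
  b
}
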