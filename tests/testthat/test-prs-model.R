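test_that("scoring is the documented dot product, with allele-swap symmetry", {
  v <- tibble::tibble(variant_id = c("rs1", "rs2"), chromosome = "1",
                      position = c(10L, 20L), effect_allele = c("A", "C"),
                      other_allele = c("G", "T"))
  model <- prsboost:::new_prs_model(
    0.25, c(0.5, -1), numeric(0), character(0), "l2", boost_control(), 2, 1, v,
    list(iterations = tibble::tibble(), batches = tibble::tibble()), NA_real_)

  G <- genotype_matrix(matrix(c(2, 1), 1), variants = v, sample_ids = "s1")
  # hand dot product: 0.25 + 0.5*2 + (-1)*1
  expect_equal(predict(model, G), 0.25 + 0.5 * 2 - 1 * 1)

  # swapped alleles at rs2: dosage flips to 2 - x
  v2 <- v; v2$effect_allele[2] <- "T"; v2$other_allele[2] <- "C"
  G2 <- genotype_matrix(matrix(c(2, 1), 1), variants = v2, sample_ids = "s1")
  expect_equal(predict(model, G2), predict(model, G))

  # unresolvable mismatch errors
  v3 <- v; v3$effect_allele[2] <- "G"; v3$other_allele[2] <- "A"
  G3 <- genotype_matrix(matrix(c(2, 1), 1), variants = v3, sample_ids = "s1")
  expect_error(predict(model, G3), "allele mismatch")

  # missing variant errors with its id
  expect_error(predict(model, G[, 1]), "rs2")

  # empty model scores a constant
  null_model <- prsboost:::new_prs_model(
    0.7, numeric(2), numeric(0), character(0), "l2", boost_control(), 0, 0, v,
    list(iterations = tibble::tibble(), batches = tibble::tibble()), NA_real_)
  expect_equal(predict(null_model, G), 0.7)
})

test_that("scoring is additive over variants", {
  cfg <- sim_config(n = 30, p = 8, s = 0.25, seed = 71)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  fit <- prs_boost(G, y, control = boost_control(p_batch = 8), m_max = 40)
  full <- predict(fit, G) - fit$intercept
  parts <- sapply(seq_len(nrow(fit$coefficients)), function(i) {
    m1 <- fit
    m1$coefficients <- fit$coefficients[i, , drop = FALSE]
    predict(m1, G) - fit$intercept
  })
  expect_equal(full, rowSums(parts), tolerance = 1e-12)
})

test_that("export/import round-trips reproduce predictions exactly", {
  cfg <- sim_config(n = 100, p = 20, s = 0.1, seed = 72)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  fit <- prs_boost(G, y, control = boost_control(p_batch = 10), m_max = 60)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_prs(fit, f)
  back <- import_prs(f)
  expect_identical(predict(back, G), predict(fit, G))
  expect_identical(back$intercept, fit$intercept)
  # idempotent serialization
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_prs(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("an exported file is scored identically by an independent reader", {
  cfg <- sim_config(n = 5, p = 10, s = 0.2, seed = 73)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  fit <- prs_boost(G, y, control = boost_control(p_batch = 5), m_max = 25)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_prs(fit, f)
  # independent scorer: base read.table + explicit loop
  tab <- utils::read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  icept <- as.numeric(strsplit(grep("intercept", readLines(f), value = TRUE), "\t")[[1]][2])
  manual <- rep(icept, 5)
  for (r in seq_len(nrow(tab))) {
    j <- match(tab$variant_id[r], G$variants$variant_id)
    manual <- manual + tab$beta[r] * G$dosages[, j]
  }
  expect_equal(predict(fit, G), manual, tolerance = 1e-10)
})

test_that("a variant-free model exports and re-imports as a constant predictor", {
  v <- tibble::tibble(variant_id = character(0), chromosome = character(0),
                      position = integer(0), effect_allele = character(0),
                      other_allele = character(0))
  m <- prsboost:::new_prs_model(1.5, numeric(0), numeric(0), character(0), "l2",
                                boost_control(), 0, 0, v,
                                list(iterations = tibble::tibble(),
                                     batches = tibble::tibble()), NA_real_)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_prs(m, f)
  back <- import_prs(f)
  G <- toy_genotypes(4, 2)
  expect_equal(predict(back, G), rep(1.5, 4))
})

test_that("malformed score files are reported with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# intercept\t0", "# loss\tl2",
               "variant_id\tchromosome\tposition\teffect_allele\tother_allele\tbeta",
               "rs1\t1\t5\tA\tG"), f)   # truncated row
  expect_error(import_prs(f), "line 4")
})

test_that("tidy, glance and autoplot expose the fit", {
  cfg <- sim_config(n = 200, p = 30, s = 0.1, seed = 74)
  G <- simulate_genotypes(cfg)
  y <- simulate_phenotype(G, cfg)$phenotype$pheno
  idx <- split_samples(200, seed = 74)
  fit <- prs_boost(G[idx$train, ], y[idx$train], G[idx$validation, ], y[idx$validation],
                   control = boost_control(p_batch = 10))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("variant_id", "beta") %in% names(td)))
  expect_true(all(td$beta != 0))
  gl <- glance(fit)
  expect_equal(gl$n_variants, nrow(fit$coefficients))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, "coefficients"), "ggplot")
})
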