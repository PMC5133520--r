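test_that("simulated cohort has the configured dimensions and valid entries", {
  cfg <- tiny_config(seed = 7)
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$genotypes), 120)
  expect_equal(ncol(co$expression), 12)
  expect_equal(ncol(co$phenotype_replicates), 12)
  expect_true(all(co$genotypes %in% 0:2))
  expect_true(all(co$phenotype_replicates %in% 0:1))
  expect_length(co$causal_genes, 3)
  expect_true(all(co$causal_genes %in% co$variant_annotations$gene_id))
  expect_equal(length(unique(co$covariates$pedigree_id)), 6)
  # one gene per variant, all matrices share the individual axis
  expect_equal(colnames(co$genotypes), co$variant_annotations$variant_id)
  expect_identical(rownames(co$genotypes), rownames(co$expression))
  expect_identical(rownames(co$genotypes), co$covariates$individual_id)
  v <- table(co$variant_annotations$variant_id)
  expect_true(all(v == 1))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_cohort(tiny_config(seed = 42))
  b <- simulate_cohort(tiny_config(seed = 42))
  d <- simulate_cohort(tiny_config(seed = 43))
  expect_identical(a, b)
  expect_false(identical(a$genotypes, d$genotypes))
  expect_false(identical(a$phenotype_replicates, d$phenotype_replicates))
})

test_that("null disease model reproduces the intercept's prevalence", {
  cfg <- tiny_config(seed = 5, n_individuals = 400, n_pedigrees = 16,
                     n_replicates = 50,
                     covariate_effects = c(age = 0, sex = 0, smoke = 0, age_sex = 0),
                     burden_effect = 0, expression_effect = 0,
                     interaction_effect = 0, disease_intercept = qlogis(0.1))
  co <- simulate_cohort(cfg)
  phat <- mean(co$phenotype_replicates)
  tol <- 4 * sqrt(0.1 * 0.9 / (400 * 50))
  expect_lt(abs(phat - 0.1), tol)
})

test_that("expression is uncoupled from burden when the coupling is zero", {
  cors <- unlist(lapply(1:5, function(s) {
    co <- simulate_cohort(tiny_config(seed = s, expression_genotype_coupling = 0,
                                      n_individuals = 200, n_pedigrees = 8))
    sapply(unique(co$variant_annotations$gene_id), function(g) {
      s_g <- compute_burden(co, g)
      if (length(unique(s_g)) < 2) return(NA_real_)
      cor(co$expression[, g], s_g)
    })
  }))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.03)
})

test_that("empirical MAFs stay within the configured range to binomial tolerance", {
  cfg <- simulation_config(n_replicates = 200, seed = 31)
  co <- simulate_cohort(cfg)
  emp <- variant_maf(co$genotypes)
  # Gene-drop roughly doubles the variance of the 2n-allele count (founder
  # alleles are resampled into offspring), so the exact binomial oracle uses
  # the founder-allele count n = 637.
  n_eff <- cfg$n_individuals
  lo <- qbinom(1e-9, n_eff, cfg$maf_range[1]) / n_eff
  hi <- qbinom(1 - 1e-9, n_eff, cfg$maf_range[2]) / n_eff
  expect_true(all(emp >= lo))
  expect_true(all(emp <= hi))
})

test_that("degenerate disease models and invalid configurations are rejected", {
  expect_error(simulate_cohort(tiny_config(disease_intercept = -80,
                                           covariate_effects = c(age = 0, sex = 0, smoke = 0, age_sex = 0),
                                           burden_effect = 0, expression_effect = 0,
                                           interaction_effect = 0)),
               "degenerate")
  expect_error(simulation_config(n_pedigrees = 10, n_individuals = 5), "n_pedigrees")
  expect_error(simulation_config(n_causal_genes = 20, n_genes = 10), "n_causal_genes")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(n_replicates = 0), "n_replicates")
})

test_that("offspring genotypes are Mendel-consistent with their recorded parents", {
  co <- simulate_cohort(tiny_config(seed = 17))
  cov <- co$covariates
  kids <- which(!is.na(cov$father_id))
  expect_gt(length(kids), 0)
  for (i in kids) {
    fa <- co$genotypes[cov$father_id[i], ]
    mo <- co$genotypes[cov$mother_id[i], ]
    ch <- co$genotypes[i, ]
    expect_true(all(ch <= (fa > 0) + (mo > 0)))
    expect_true(all(ch >= (fa == 2) + (mo == 2)))
  }
})

test_that("replicate case counts show binomial dispersion (exchangeability)", {
  co <- simulate_cohort(tiny_config(seed = 9, n_individuals = 400,
                                    n_pedigrees = 16, n_replicates = 100))
  counts <- colSums(co$phenotype_replicates)
  phat <- rowMeans(co$phenotype_replicates)
  v_model <- sum(phat * (1 - phat))
  expect_gt(var(counts) / v_model, 0.6)
  expect_lt(var(counts) / v_model, 1.6)
})

test_that("cohorts round-trip through the plain-text formats", {
  co <- tiny_cohort(seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- load_cohort(paths["genotypes"], paths["expression"],
                      paths["covariates"], paths["replicates"],
                      paths["variant_map"])
  expect_identical(back$genotypes, co$genotypes)
  expect_equal(back$expression, co$expression)
  expect_identical(back$phenotype_replicates, co$phenotype_replicates)
  expect_equal(back$covariates$pedigree_id, co$covariates$pedigree_id)
  expect_identical(back$causal_genes, character(0))
  # in-sample MAF is recomputed on load
  expect_equal(back$variant_annotations$maf,
               unname(variant_maf(co$genotypes)))
})

test_that("loading aligns individuals by identifier, not row order", {
  co <- tiny_cohort(seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  # permute the expression rows on disk
  expr <- read.delim(paths["expression"], check.names = FALSE)
  expr <- expr[rev(seq_len(nrow(expr))), ]
  write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- load_cohort(paths["genotypes"], paths["expression"],
                      paths["covariates"], paths["replicates"],
                      paths["variant_map"])
  expect_equal(back$expression, co$expression)
})

test_that("malformed inputs are rejected with informative errors", {
  co <- tiny_cohort(seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)

  geno <- read.delim(paths["genotypes"], check.names = FALSE)
  bad <- geno
  bad[2, 3] <- 3
  bad_path <- file.path(dir, "bad_geno.tsv")
  write.table(bad, bad_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(bad_path, paths["expression"], paths["covariates"],
                           paths["replicates"], paths["variant_map"]),
               names(geno)[3])

  mism <- geno
  mism$individual_id[1] <- "NOBODY"
  mism_path <- file.path(dir, "mism_geno.tsv")
  write.table(mism, mism_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(mism_path, paths["expression"], paths["covariates"],
                           paths["replicates"], paths["variant_map"]),
               "identifier")
})
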