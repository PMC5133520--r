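# Compact menus and the single-point classifier grid keep these structural
# tests fast; the statistically heavy checks live in test-acceptance.R.

small_grid_spec <- function(cohort, ..., seed = 5) {
  rn <- colnames(cohort$phenotype_replicates)
  grid_spec(gene_lists = data.frame(kind = c("causal", "none"),
                                    size = c(1, 0)),
            noise_levels = 0,
            classification_replicate_ids = rn[length(rn)],
            selection_replicate_ids = rn[-length(rn)],
            collapse_depths = c(3, 5),
            cost = 1, gamma = 1, seed = seed, ...)
}

test_that("grid cardinality is the product of the menu sizes", {
  expect_equal(nrow(enumerate_grid(grid_spec())), 315)
  single <- grid_spec(gene_lists = data.frame(kind = "causal", size = 1),
                      noise_levels = 0, collapse_depths = 5,
                      classification_replicate_ids = "SIMPHEN.151")
  expect_equal(nrow(enumerate_grid(single)), 1)
  followup2 <- grid_spec(gene_lists = data.frame(kind = "causal", size = c(1, 5, 10)),
                         noise_levels = 0, collapse_depths = c(5, 25, 50, 100, 150),
                         classification_replicate_ids = "SIMPHEN.151",
                         phenotype_mode = "sensitive")
  expect_equal(nrow(enumerate_grid(followup2)), 15)
  withr::with_seed(61, {
    for (i in 1:20) {
      nl <- sample(1:4, 1); nm <- sample(1:4, 1); nr <- sample(1:3, 1)
      sp <- grid_spec(gene_lists = data.frame(kind = rep("causal", nl),
                                              size = seq_len(nl)),
                      noise_levels = seq(0, 0.1, length.out = sample(1:3, 1)),
                      collapse_depths = sample(1:50, nm),
                      classification_replicate_ids = sprintf("R%d", seq_len(nr)))
      expect_equal(nrow(enumerate_grid(sp)),
                   nl * length(sp$noise_levels) * nm * nr)
    }
  })
})

test_that("grid specifications are validated", {
  expect_error(grid_spec(noise_levels = numeric(0)), "noise_levels")
  expect_error(grid_spec(gene_lists = data.frame(kind = "magic", size = 1)),
               "kind")
  expect_error(grid_spec(classification_replicate_ids = "SIMPHEN.1",
                         selection_replicate_ids = paste0("SIMPHEN.", 1:5)),
               "disjoint")
  expect_error(grid_spec(collapse_depths = integer(0)), "collapse_depths")
})

test_that("a small grid runs end to end with complete bookkeeping", {
  co <- tiny_cohort(seed = 20)
  spec <- small_grid_spec(co)
  cells <- suppressWarnings(run_grid(co, spec))
  expect_s3_class(cells, "grid_result")
  expect_equal(nrow(cells), 4)  # 2 lists x 1 k x 1 replicate x 2 m
  expect_false(any(cells$failed))
  aucs <- as.matrix(cells[, c("auc_logistic", "auc_svm_linear", "auc_svm_radial")])
  expect_true(all(aucs >= 0 & aucs <= 1))
  expect_equal(cells$n_causal_genes, ifelse(cells$list_kind == "causal", 1, 0))
  expect_true(all(cells$n_noncausal_genes == 0))
  # best_method attains the row maximum
  for (i in seq_len(nrow(cells))) {
    best <- strsplit(cells$best_method[i], "+", fixed = TRUE)[[1]]
    expect_equal(max(aucs[i, ]),
                 min(aucs[i, paste0("auc_", best)]))
  }
  # win bookkeeping: per-method wins sum to cells plus tie multiplicities
  summ <- summarize_grid(cells)
  n_best <- sum(lengths(strsplit(cells$best_method, "+", fixed = TRUE)))
  expect_equal(sum(summ$win_fraction * summ$n_cells), n_best)
})

test_that("grid reruns at a fixed seed reproduce every AUC and checkpoints resume", {
  co <- tiny_cohort(seed = 21)
  spec <- small_grid_spec(co, seed = 77)
  ckpt <- withr::local_tempfile(fileext = ".jsonl")
  a <- suppressWarnings(run_grid(co, spec, checkpoint_path = ckpt))
  expect_equal(length(readLines(ckpt)), nrow(a))
  # resume path: completed cells are read back, not recomputed
  b <- suppressWarnings(run_grid(co, spec, checkpoint_path = ckpt))
  expect_equal(b$auc_logistic, a$auc_logistic)
  expect_equal(b$auc_svm_radial, a$auc_svm_radial)
  expect_equal(length(readLines(ckpt)), nrow(a))
  # fresh rerun without checkpoint is bit-identical
  c2 <- suppressWarnings(run_grid(co, spec))
  expect_identical(c2$auc_logistic, a$auc_logistic)
  expect_identical(c2$auc_svm_linear, a$auc_svm_linear)
  expect_identical(c2$auc_svm_radial, a$auc_svm_radial)
})

test_that("an unsatisfiable gene list marks its cells failed without aborting", {
  co <- tiny_cohort(seed = 22)  # only 3 causal genes
  spec <- grid_spec(gene_lists = data.frame(kind = c("causal", "none"),
                                            size = c(8, 0)),
                    noise_levels = 0, collapse_depths = 3,
                    classification_replicate_ids = "SIMPHEN.12",
                    selection_replicate_ids = paste0("SIMPHEN.", 1:11),
                    cost = 1, gamma = 1)
  cells <- suppressWarnings(run_grid(co, spec))
  expect_equal(nrow(cells), 2)
  bad <- cells[cells$list_kind == "causal", ]
  expect_true(bad$failed)
  expect_match(bad$error, "available")
  expect_false(cells$failed[cells$list_kind == "none"])
})

test_that("meta-regression recovers planted coefficients and exact fits", {
  withr::with_seed(62, {
    cells <- expand.grid(n_causal_genes = c(0, 1, 5, 10),
                         n_noncausal_genes = c(0, 5, 15, 50),
                         k = c(0, 0.01, 0.1), m = c(5, 25, 50))
    noise <- rnorm(nrow(cells), sd = 1e-4)
  })
  planted <- 0.8 - 0.001 * cells$n_noncausal_genes + noise
  cells$auc_logistic <- cells$auc_svm_linear <- cells$auc_svm_radial <- planted
  cells$failed <- FALSE
  fit <- meta_regress(cells)
  co_tab <- fit$methods$logistic$coefficients
  est <- co_tab$estimate[co_tab$term == "n_noncausal_genes"]
  se <- co_tab$std_error[co_tab$term == "n_noncausal_genes"]
  expect_lt(abs(est - (-0.001)), 3 * se)

  # noise-free planted table: R^2 = 1 to machine tolerance
  exact <- 0.8 - 0.001 * cells$n_noncausal_genes + 0.002 * cells$k - 1e-4 * cells$m
  cells$auc_logistic <- cells$auc_svm_linear <- cells$auc_svm_radial <- exact
  fit2 <- meta_regress(cells)
  expect_equal(fit2$methods$svm_radial$r_squared, 1, tolerance = 1e-9)

  # closed-form normal-equations oracle on a small table
  withr::with_seed(63, {
    small <- data.frame(n_causal_genes = sample(0:10, 10, replace = TRUE),
                        n_noncausal_genes = sample(c(0, 5, 15, 50), 10, replace = TRUE),
                        k = sample(c(0, 0.01, 0.1), 10, replace = TRUE),
                        m = sample(c(5, 25, 50), 10, replace = TRUE),
                        auc_logistic = runif(10, 0.6, 0.9),
                        failed = FALSE)
  })
  small$auc_svm_linear <- small$auc_svm_radial <- small$auc_logistic
  fit3 <- meta_regress(small)
  X <- as.matrix(cbind(1, small[, c("n_causal_genes", "n_noncausal_genes", "k", "m")]))
  beta <- solve(t(X) %*% X, t(X) %*% small$auc_logistic)
  expect_equal(fit3$methods$logistic$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-8)

  cells$k <- 0  # constant predictor is refused by name
  expect_error(meta_regress(cells), "'k' is constant")
})

test_that("meta-regression output carries significance stars", {
  withr::with_seed(64, {
    cells <- expand.grid(n_causal_genes = c(0, 1, 5), n_noncausal_genes = c(0, 5, 50),
                         k = c(0, 0.1), m = c(5, 50))
    cells$auc_logistic <- 0.8 - 0.002 * cells$n_noncausal_genes + rnorm(nrow(cells), sd = 5e-4)
    cells$auc_svm_linear <- cells$auc_svm_radial <- cells$auc_logistic
  })
  cells$failed <- FALSE
  path <- withr::local_tempfile(fileext = ".csv")
  write_meta_regression(meta_regress(cells), path)
  out <- read.csv(path)
  expect_setequal(unique(out$method), c("logistic", "svm_linear", "svm_radial"))
  row <- out[out$method == "logistic" & out$term == "n_noncausal_genes", ]
  expect_equal(row$signif, "***")
  expect_output(print(meta_regress(cells)), "R\\^2")
})

test_that("the expression follow-up pairs both model forms over the causal lists", {
  co <- tiny_cohort(seed = 23, n_genes = 15, n_causal_genes = 10)
  spec <- small_grid_spec(co)
  tab <- suppressWarnings(
    run_followup_no_expression(co, spec, sizes = c(1, 5, 10), m = 3))
  expect_equal(nrow(tab), 18)  # 3 sizes x 3 methods x 2 conditions
  expect_equal(sort(unique(tab$n_causal_genes)), c(1, 5, 10))
  expect_setequal(unique(tab$with_expression), c(TRUE, FALSE))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})

test_that("with/without-expression differences are centred at zero under the null", {
  diffs <- unlist(lapply(1:6, function(s) {
    co <- tiny_cohort(seed = 500 + s, n_genes = 15, n_causal_genes = 10,
                      expression_effect = 0, interaction_effect = 0,
                      expression_genotype_coupling = 0)
    spec <- small_grid_spec(co, seed = 600 + s)
    tab <- suppressWarnings(
      run_followup_no_expression(co, spec, sizes = c(1, 5), m = 3))
    with_e <- tab$auc[tab$with_expression]
    without <- tab$auc[!tab$with_expression]
    with_e - without
  }))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("the sensitive-phenotype follow-up degenerates to zero at m = 1", {
  co <- tiny_cohort(seed = 24, n_genes = 15, n_causal_genes = 10)
  rn <- colnames(co$phenotype_replicates)
  spec <- grid_spec(collapse_depths = 1, noise_levels = 0,
                    classification_replicate_ids = rn[length(rn)],
                    selection_replicate_ids = rn[-length(rn)],
                    cost = 1, gamma = 1, seed = 3)
  out <- suppressWarnings(
    run_followup_sensitive(co, spec, sizes = c(1, 5), n_boot = 100))
  expect_equal(nrow(out$cells), 6)  # 1 m x 2 sizes x 3 methods
  expect_true(all(out$cells$improvement == 0))
  expect_true(all(out$summary$mean_improvement == 0))
})

test_that("sensitive collapsing yields more cases than specific at m >= 5", {
  wins <- sapply(1:20, function(s) {
    co <- tiny_cohort(seed = 700 + s, n_individuals = 200, n_pedigrees = 8)
    y <- sum(collapse_phenotype(co, "specific", m = 5)$status)
    z <- sum(collapse_phenotype(co, "sensitive", m = 5)$status)
    z > y
  })
  expect_gte(mean(wins), 0.95)
})
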