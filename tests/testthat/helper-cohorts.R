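# Small cohort builders shared across the suite. Everything is generated in
# code at test time; no stored fixtures.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_individuals = 120, n_pedigrees = 6, n_genes = 12,
               n_causal_genes = 3, variants_per_gene = c(3L, 8L),
               n_replicates = 12, burden_effect = 1.2, expression_effect = 0.6,
               interaction_effect = 0.4, disease_intercept = -6.5, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

tiny_cohort <- function(seed = 1, ...) {
  simulate_cohort(tiny_config(seed, ...))
}

# Cohort with a fully hand-specified genotype block (one or more genes),
# deterministic expression/covariates, for burden and design oracles.
manual_cohort <- function(genotypes, gene_ids, causal_genes = character(0),
                          expression = NULL, n_replicates = 4, seed = 99) {
  n <- nrow(genotypes)
  ids <- sprintf("IND%04d", seq_len(n))
  variant_ids <- sprintf("VAR%05d", seq_len(ncol(genotypes)))
  dimnames(genotypes) <- list(ids, variant_ids)
  storage.mode(genotypes) <- "integer"
  genes <- unique(gene_ids)
  withr::with_seed(seed, {
    if (is.null(expression)) {
      expression <- matrix(rnorm(n * length(genes)), n, length(genes),
                           dimnames = list(ids, genes))
    } else {
      dimnames(expression) <- list(ids, genes)
    }
    reps <- matrix(rbinom(n * n_replicates, 1L, 0.3), n, n_replicates,
                   dimnames = list(ids, sprintf("SIMPHEN.%d", seq_len(n_replicates))))
    covariates <- data.frame(
      individual_id = ids,
      pedigree_id = rep(c("PED01", "PED02"), length.out = n),
      sex = rbinom(n, 1L, 0.5), age = round(runif(n, 20, 80), 1),
      smoke = rbinom(n, 1L, 0.25), stringsAsFactors = FALSE)
  })
  f <- colSums(genotypes) / (2 * n)
  rvpredict:::new_cohort(
    genotypes = genotypes,
    variant_annotations = data.frame(variant_id = variant_ids,
                                     gene_id = gene_ids,
                                     maf = pmin(f, 1 - f),
                                     stringsAsFactors = FALSE),
    expression = expression,
    covariates = covariates,
    phenotype_replicates = reps,
    causal_genes = causal_genes)
}

# Exhaustive per-individual / per-rare-variant burden oracle.
burden_oracle <- function(genotypes, maf_threshold = 0.05) {
  n <- nrow(genotypes)
  out <- integer(n)
  for (i in seq_len(n)) {
    carrier <- FALSE
    for (j in seq_len(ncol(genotypes))) {
      f <- sum(genotypes[, j]) / (2 * n)
      maf <- min(f, 1 - f)
      minor <- if (f > 0.5) 2 - genotypes[i, j] else genotypes[i, j]
      if (maf < maf_threshold && minor > 0) carrier <- TRUE
    }
    out[i] <- as.integer(carrier)
  }
  out
}

# All-pairs Wilcoxon-Mann-Whitney AUC oracle.
auc_oracle <- function(scores, truth) {
  cases <- scores[truth == 1]
  controls <- scores[truth == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# A cheap classifier protocol for structural tests (single grid point skips
# cross-validation entirely).
fast_spec <- function(method, seed = 1) {
  classifier_spec(method, cost = 1, gamma = 1, seed = seed)
}
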