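#' Configuration for a synthetic cohort simulation
#'
#' Builds a validated configuration describing a family-structured cohort
#' with fixed genotypes, gene expression optionally coupled to rare-variant
#' burden, baseline covariates, and many independent binary phenotype
#' replicates drawn from one logistic disease model with known causal genes.
#'
#' The defaults emulate the structure of a family-based sequencing study with
#' expression data: n = 637 individuals in 20 extended pedigrees, 150 + 3
#' usable phenotype replicates over one fixed genotype matrix, and a
#' collapsed-case prevalence near 10\%. The disease model is
#' \deqn{logit P(Y=1) = \alpha + \beta_{age} Age + \beta_{sex} Sex +
#'   \beta_{smoke} Smoke + \beta_{age \times sex} Age \cdot Sex +
#'   \sum_{g \in causal} (\beta_S S_g + \beta_G G_g + \beta_{GS} G_g S_g)}
#' where \eqn{S_g} is the rare-variant carrier (burden) indicator and
#' \eqn{G_g} the expression of causal gene \eqn{g}. Phenotype replicates are
#' independent Bernoulli draws from the per-individual probability; the
#' genotypes, expression and covariates are drawn once and shared by all
#' replicates.
#'
#' @param n_individuals Number of individuals.
#' @param n_pedigrees Number of pedigrees; individuals are split near-equally.
#' @param n_genes Number of genes.
#' @param n_causal_genes Number of causal genes (must be <= `n_genes`).
#' @param variants_per_gene Integer count, or length-2 range from which each
#'   gene's variant count is drawn uniformly.
#' @param maf_range Length-2 range in (0, 0.5) for population minor-allele
#'   frequencies, drawn uniformly per variant.
#' @param expression_mean,expression_sd Baseline Gaussian expression
#'   parameters (per gene, per individual).
#' @param expression_genotype_coupling Additive shift of a gene's expression
#'   mean for carriers of a rare allele in that gene (applies to all genes).
#' @param disease_intercept Intercept of the disease model, on the log-odds
#'   scale.
#' @param covariate_effects Named numeric vector with elements `age`, `sex`,
#'   `smoke`, `age_sex` (log-odds per unit).
#' @param burden_effect,expression_effect,interaction_effect Log-odds per
#'   unit of \eqn{S}, \eqn{G} and \eqn{G S} for each causal gene.
#' @param n_replicates Number of independent phenotype replicates (>= 1).
#' @param seed Integer seed; `simulate_cohort()` is bit-reproducible given
#'   the configuration.
#'
#' @return An object of class `simulation_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_individuals = 637,
                              n_pedigrees = 20,
                              n_genes = 100,
                              n_causal_genes = 10,
                              variants_per_gene = c(4L, 16L),
                              maf_range = c(0.005, 0.05),
                              expression_mean = 0,
                              expression_sd = 1,
                              expression_genotype_coupling = 0.3,
                              disease_intercept = -9.0,
                              covariate_effects = c(age = 0.02, sex = 0.3,
                                                    smoke = 0.4, age_sex = 0),
                              burden_effect = 0.8,
                              expression_effect = 0.4,
                              interaction_effect = 0.3,
                              n_replicates = 153,
                              seed = 1L) {
  for (nm in c("n_individuals", "n_pedigrees", "n_genes", "n_replicates")) {
    if (!is_count(get(nm))) stop(sprintf("`%s` must be a positive integer", nm))
  }
  if (!is.numeric(n_causal_genes) || n_causal_genes < 0 ||
      n_causal_genes != floor(n_causal_genes)) {
    stop("`n_causal_genes` must be a non-negative integer")
  }
  if (n_causal_genes > n_genes) stop("`n_causal_genes` must be <= `n_genes`")
  if (n_pedigrees > n_individuals) stop("`n_pedigrees` must be <= `n_individuals`")
  if (length(variants_per_gene) == 1L) {
    variants_per_gene <- rep(variants_per_gene, 2L)
  }
  if (length(variants_per_gene) != 2L || any(variants_per_gene < 1) ||
      variants_per_gene[1] > variants_per_gene[2]) {
    stop("`variants_per_gene` must be a positive count or increasing range")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5)")
  }
  needed <- c("age", "sex", "smoke", "age_sex")
  if (!all(needed %in% names(covariate_effects))) {
    stop("`covariate_effects` must name age, sex, smoke, age_sex")
  }
  if (expression_sd <= 0) stop("`expression_sd` must be positive")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_pedigrees = as.integer(n_pedigrees),
    n_genes = as.integer(n_genes),
    n_causal_genes = as.integer(n_causal_genes),
    variants_per_gene = as.integer(variants_per_gene),
    maf_range = as.numeric(maf_range),
    expression_mean = expression_mean,
    expression_sd = expression_sd,
    expression_genotype_coupling = expression_genotype_coupling,
    disease_intercept = disease_intercept,
    covariate_effects = covariate_effects[needed],
    burden_effect = burden_effect,
    expression_effect = expression_effect,
    interaction_effect = interaction_effect,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

new_cohort <- function(genotypes, variant_annotations, expression, covariates,
                       phenotype_replicates, causal_genes) {
  ids <- rownames(genotypes)
  stopifnot(!is.null(ids))
  if (!identical(ids, rownames(expression)) ||
      !identical(ids, covariates$individual_id) ||
      !identical(ids, rownames(phenotype_replicates))) {
    stop("all cohort tables must share the same individuals in the same order")
  }
  if (!all(genotypes %in% c(0L, 1L, 2L))) {
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  }
  assert_binary_matrix(phenotype_replicates, "phenotype replicate matrix")
  if (anyDuplicated(variant_annotations$variant_id)) {
    stop("duplicated variant IDs in annotation")
  }
  if (!identical(colnames(genotypes), variant_annotations$variant_id)) {
    stop("genotype columns must match the variant annotation, in order")
  }
  structure(list(
    genotypes = genotypes,
    variant_annotations = variant_annotations,
    expression = expression,
    covariates = covariates,
    phenotype_replicates = phenotype_replicates,
    causal_genes = causal_genes
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d individuals, %d variants in %d genes, %d replicates\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$variant_annotations$gene_id)),
    ncol(x$phenotype_replicates)))
  cat(sprintf("  pedigrees: %d; causal genes: %d\n",
              length(unique(x$covariates$pedigree_id)),
              length(x$causal_genes)))
  invisible(x)
}

# Split n individuals into k near-equal pedigrees, each built from founder
# couples (roughly half the members) whose remaining members are offspring
# assigned round-robin to the couples. Returns the pedigree label and the
# within-cohort indices of each individual's father and mother (NA for
# founders).
pedigree_layout <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ped <- rep(sprintf("PED%02d", seq_len(k)), times = sizes)
  father <- mother <- rep(NA_integer_, n)
  offset <- 0L
  for (i in seq_len(k)) {
    s <- sizes[i]
    n_couples <- max(1L, s %/% 4L)
    n_founders <- min(2L * n_couples, s)
    kids <- seq_len(s)[-seq_len(n_founders)]
    if (length(kids)) {
      couple <- rep_len(seq_len(n_founders %/% 2L), length(kids))
      father[offset + kids] <- offset + 2L * couple - 1L
      mother[offset + kids] <- offset + 2L * couple
    }
    offset <- offset + s
  }
  list(pedigree_id = ped, father = father, mother = mother)
}

#' Simulate a synthetic family-based cohort
#'
#' Draws one fixed genotype matrix (founders at each variant's population
#' MAF, offspring by Mendelian gene-drop within pedigree), covariates,
#' expression optionally shifted by rare-allele carriage, and `n_replicates`
#' independent binary phenotype replicates from the configured logistic
#' disease model. Genotypes, expression and covariates are identical across
#' replicates; only the phenotype draws differ.
#'
#' @param config A [simulation_config()].
#' @return A `cohort` object: genotype matrix (individuals x variants,
#'   minor-allele counts), variant annotation (variant, gene, population
#'   MAF), expression matrix (individuals x genes), covariate table
#'   (individual, pedigree, sex, age, smoke), phenotype replicate matrix
#'   (individuals x replicates, columns `SIMPHEN.r`), and the causal gene
#'   IDs.
#' @examples
#' cfg <- simulation_config(n_individuals = 60, n_pedigrees = 6,
#'                          n_genes = 10, n_causal_genes = 2,
#'                          n_replicates = 8, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' cohort
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be built by simulation_config()")
  }
  with_seed(config$seed, {
    n <- config$n_individuals
    ids <- sprintf("IND%04d", seq_len(n))
    layout <- pedigree_layout(n, config$n_pedigrees)
    ped <- layout$pedigree_id

    n_var_per_gene <- if (config$variants_per_gene[1] == config$variants_per_gene[2]) {
      rep(config$variants_per_gene[1], config$n_genes)
    } else {
      sample(config$variants_per_gene[1]:config$variants_per_gene[2],
             config$n_genes, replace = TRUE)
    }
    gene_ids <- sprintf("GENE%03d", seq_len(config$n_genes))
    variant_gene <- rep(gene_ids, times = n_var_per_gene)
    n_var <- length(variant_gene)
    variant_ids <- sprintf("VAR%05d", seq_len(n_var))
    maf <- runif(n_var, config$maf_range[1], config$maf_range[2])

    geno <- matrix(0L, n, n_var, dimnames = list(ids, variant_ids))
    founders <- which(is.na(layout$father))
    for (i in founders) geno[i, ] <- rbinom(n_var, 2L, maf)
    for (i in which(!is.na(layout$father))) {
      geno[i, ] <- rbinom(n_var, 1L, geno[layout$father[i], ] / 2) +
        rbinom(n_var, 1L, geno[layout$mother[i], ] / 2)
    }

    covariates <- data.frame(
      individual_id = ids,
      pedigree_id = ped,
      father_id = ifelse(is.na(layout$father), NA_character_, ids[layout$father]),
      mother_id = ifelse(is.na(layout$mother), NA_character_, ids[layout$mother]),
      sex = rbinom(n, 1L, 0.5),
      age = round(runif(n, 20, 80), 1),
      smoke = rbinom(n, 1L, 0.25),
      stringsAsFactors = FALSE
    )

    # Carrier indicator per gene from the generating (population) MAFs; used
    # for both the expression coupling and the disease model.
    rare <- maf < 0.05
    carrier <- matrix(0L, n, config$n_genes, dimnames = list(ids, gene_ids))
    for (g in seq_along(gene_ids)) {
      cols <- which(variant_gene == gene_ids[g] & rare)
      if (length(cols)) {
        carrier[, g] <- as.integer(rowSums(geno[, cols, drop = FALSE] > 0) > 0)
      }
    }

    expression <- matrix(
      rnorm(n * config$n_genes, config$expression_mean, config$expression_sd),
      n, config$n_genes, dimnames = list(ids, gene_ids))
    expression <- expression + config$expression_genotype_coupling * carrier

    causal <- sort(sample(gene_ids, config$n_causal_genes))
    eta <- config$disease_intercept +
      config$covariate_effects[["age"]] * covariates$age +
      config$covariate_effects[["sex"]] * covariates$sex +
      config$covariate_effects[["smoke"]] * covariates$smoke +
      config$covariate_effects[["age_sex"]] * covariates$age * covariates$sex
    for (g in causal) {
      eta <- eta + config$burden_effect * carrier[, g] +
        config$expression_effect * expression[, g] +
        config$interaction_effect * expression[, g] * carrier[, g]
    }
    p <- plogis(eta)
    if (all(p < 1e-12) || all(p > 1 - 1e-12)) {
      stop("degenerate disease model: expected case prevalence is 0 or 1")
    }

    reps <- matrix(rbinom(n * config$n_replicates, 1L, rep(p, config$n_replicates)),
                   n, config$n_replicates,
                   dimnames = list(ids, sprintf("SIMPHEN.%d", seq_len(config$n_replicates))))

    new_cohort(
      genotypes = geno,
      variant_annotations = data.frame(variant_id = variant_ids,
                                       gene_id = variant_gene,
                                       maf = maf, stringsAsFactors = FALSE),
      expression = expression,
      covariates = covariates,
      phenotype_replicates = reps,
      causal_genes = causal
    )
  })
}

#' Write a cohort to plain-text tables
#'
#' Writes the genotype, variant-map, expression, covariate and phenotype
#' replicate tables as tab-separated files that [load_cohort()] can read
#' back, so downstream stages are format-agnostic.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             variant_map = file.path(dir, "variant_map.tsv"),
             expression = file.path(dir, "expression.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             replicates = file.path(dir, "replicates.tsv"))
  write_mat <- function(m, path) {
    df <- data.frame(individual_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(cohort$genotypes, paths["genotypes"])
  write_mat(cohort$expression, paths["expression"])
  write_mat(cohort$phenotype_replicates, paths["replicates"])
  write.table(cohort$variant_annotations[, c("variant_id", "gene_id")],
              paths["variant_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$covariates, paths["covariates"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

read_id_matrix <- function(path, what, integer = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df)) {
    stop(sprintf("%s file must have an individual_id column", what))
  }
  if (anyDuplicated(df$individual_id)) {
    stop(sprintf("duplicated individual IDs in %s file", what))
  }
  m <- as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE])
  rownames(m) <- df$individual_id
  storage.mode(m) <- if (integer) "integer" else "double"
  m
}

#' Load a cohort from plain-text tables
#'
#' Reads the five tables written by [write_cohort()] (or equivalently
#' formatted real data) and aligns individuals across tables by identifier,
#' not row order. Missing genotype entries are treated as 0 with a warning;
#' `causal_genes` is empty, since the truth is unknown for ingested data.
#'
#' @param genotype_path TSV with `individual_id` then one column per variant
#'   (minor-allele counts 0/1/2).
#' @param expression_path TSV with `individual_id` then one column per gene.
#' @param covariate_path TSV with columns `individual_id`, `pedigree_id`,
#'   `sex`, `age`, `smoke`.
#' @param replicate_path TSV with `individual_id` then one binary column per
#'   phenotype replicate.
#' @param variant_map_path Two-column TSV mapping `variant_id` to `gene_id`.
#' @return A `cohort` with empty `causal_genes`.
#' @export
load_cohort <- function(genotype_path, expression_path, covariate_path,
                        replicate_path, variant_map_path) {
  geno_df <- read.delim(genotype_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(names(geno_df))) stop("duplicated variant IDs in genotype file")
  geno <- {
    m <- as.matrix(geno_df[, setdiff(names(geno_df), "individual_id"), drop = FALSE])
    rownames(m) <- geno_df$individual_id
    m
  }
  if (!"individual_id" %in% names(geno_df)) {
    stop("genotype file must have an individual_id column")
  }
  if (anyNA(geno)) {
    warning("missing genotype entries treated as 0 minor alleles")
    geno[is.na(geno)] <- 0
  }
  bad <- which(!(geno %in% c(0, 1, 2)))
  if (length(bad)) {
    col <- (bad[1] - 1) %/% nrow(geno) + 1
    stop(sprintf("genotype entry %s at variant %s is outside {0, 1, 2}",
                 geno[bad[1]], colnames(geno)[col]))
  }
  storage.mode(geno) <- "integer"

  expr <- read_id_matrix(expression_path, "expression")
  reps <- read_id_matrix(replicate_path, "replicate", integer = TRUE)
  cov <- read.delim(covariate_path, stringsAsFactors = FALSE)
  need <- c("individual_id", "pedigree_id", "sex", "age", "smoke")
  if (!all(need %in% names(cov))) {
    stop("covariate file must have columns: ", paste(need, collapse = ", "))
  }
  vmap <- read.delim(variant_map_path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "gene_id") %in% names(vmap))) {
    stop("variant map must have columns variant_id, gene_id")
  }
  if (anyDuplicated(vmap$variant_id)) stop("duplicated variant IDs in variant map")
  if (!setequal(vmap$variant_id, colnames(geno))) {
    stop("variant map and genotype columns do not name the same variants")
  }

  ids <- rownames(geno)
  for (other in list(rownames(expr), rownames(reps), cov$individual_id)) {
    if (!setequal(ids, other)) {
      stop("individual identifier sets differ across input files")
    }
  }
  ids <- sort(ids)
  geno <- geno[ids, , drop = FALSE]
  vmap <- vmap[match(colnames(geno), vmap$variant_id), , drop = FALSE]
  n2 <- 2 * length(ids)
  f <- colSums(geno) / n2
  new_cohort(
    genotypes = geno,
    variant_annotations = data.frame(variant_id = vmap$variant_id,
                                     gene_id = vmap$gene_id,
                                     maf = pmin(f, 1 - f),
                                     stringsAsFactors = FALSE),
    expression = expr[ids, , drop = FALSE],
    covariates = {
      keep <- c(need, intersect(c("father_id", "mother_id"), names(cov)))
      cov <- cov[match(ids, cov$individual_id), keep, drop = FALSE]
      rownames(cov) <- NULL
      cov
    },
    phenotype_replicates = reps[ids, , drop = FALSE],
    causal_genes = character(0)
  )
}
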