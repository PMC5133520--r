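#' In-sample minor-allele frequencies
#'
#' Computes each variant's minor-allele frequency from the loaded cohort
#' itself: the frequency of the less common allele among all `2n` observed
#' alleles. When the nominal minor allele is in fact the major one in-sample
#' (frequency above 0.5), the complementary allele is taken as minor.
#'
#' @param genotypes Individuals x variants matrix of allele counts in
#'   {0, 1, 2}, or a `cohort`.
#' @return Named numeric vector of in-sample MAFs in [0, 0.5].
#' @export
variant_maf <- function(genotypes) {
  if (inherits(genotypes, "cohort")) genotypes <- genotypes$genotypes
  f <- colSums(genotypes) / (2 * nrow(genotypes))
  pmin(f, 1 - f)
}

# Counts of the in-sample minor allele (flips coding where the recorded
# allele is the in-sample major one).
minor_allele_counts <- function(genotypes) {
  f <- colSums(genotypes) / (2 * nrow(genotypes))
  flip <- f > 0.5
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip, drop = FALSE]
  }
  genotypes
}

#' Rare-variant burden (collapsing) indicator for one gene
#'
#' CMC-style collapsing: an individual's burden `S` is 1 when they carry at
#' least one minor allele at any variant of the gene whose in-sample MAF is
#' strictly below `maf_threshold`; variants at or above the threshold are
#' ignored. A gene with no rare variants yields an all-zero burden.
#'
#' @param cohort A `cohort`.
#' @param gene_id Gene identifier present in the variant annotation.
#' @param maf_threshold Rare-variant frequency cutoff (default 0.05, strict
#'   inequality).
#' @return Named integer 0/1 vector over individuals.
#' @export
compute_burden <- function(cohort, gene_id, maf_threshold = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  vars <- cohort$variant_annotations$variant_id[
    cohort$variant_annotations$gene_id == gene_id]
  if (length(vars) == 0L) {
    stop(sprintf("gene '%s' absent from the variant annotation", gene_id))
  }
  g <- minor_allele_counts(cohort$genotypes[, vars, drop = FALSE])
  maf <- variant_maf(cohort$genotypes[, vars, drop = FALSE])
  rare <- g[, maf < maf_threshold, drop = FALSE]
  s <- as.integer(rowSums(rare > 0) > 0)
  names(s) <- rownames(cohort$genotypes)
  s
}

#' Perturb an expression matrix with uniform noise
#'
#' Adds an independent Uniform(-k, k) draw to every entry; `k = 0` returns
#' the input unchanged. By contract the perturbation is applied to the
#' *selection* data only; classification-set expression stays untouched.
#'
#' @param expression Numeric matrix (individuals x genes).
#' @param k Noise half-width, `k >= 0`.
#' @param seed Optional seed for a reproducible draw (caller RNG state is
#'   restored).
#' @return Matrix of the same shape.
#' @export
inject_expression_noise <- function(expression, k, seed = NULL) {
  stopifnot(is.matrix(expression))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("`k` must be a single non-negative number")
  }
  if (k == 0) return(expression)
  draw <- function() expression + runif(length(expression), -k, k)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

covariate_block <- function(cohort) {
  cov <- cohort$covariates
  n <- nrow(cov)
  # reference pedigree = pedigree of the first individual in ID-sorted order
  ref <- cov$pedigree_id[order(cov$individual_id)][1]
  peds <- setdiff(sort(unique(cov$pedigree_id)), ref)
  ped_ind <- sapply(peds, function(p) as.numeric(cov$pedigree_id == p))
  if (length(peds)) {
    ped_ind <- matrix(ped_ind, nrow = n,
                      dimnames = list(NULL, paste0("pedigree_", peds)))
  } else {
    ped_ind <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  x <- cbind(intercept = 1, age = cov$age, sex = cov$sex, smoke = cov$smoke,
             age_sex = cov$age * cov$sex, ped_ind)
  rownames(x) <- cov$individual_id
  roles <- c(intercept = "intercept", age = "covariate", sex = "covariate",
             smoke = "covariate", age_sex = "covariate",
             stats::setNames(rep("pedigree", length(peds)),
                             paste0("pedigree_", peds)))
  list(values = x, roles = roles)
}

#' Build the model design matrix
#'
#' Assembles the fixed covariate block (intercept, age, sex, smoke, age x
#' sex, one indicator per non-reference pedigree) followed, for each
#' requested gene in order, by its expression term `G`, burden indicator `S`
#' and interaction `G x S` — or by `S` alone when expression is excluded.
#' Gene-term columns that are constant in this cohort (e.g. a monomorphic
#' burden) are dropped with a warning so downstream fits stay full rank.
#'
#' @param cohort A `cohort`.
#' @param gene_ids Character vector of genes (possibly empty for the
#'   covariates-only baseline model).
#' @param include_expression Include `G` and `G x S` terms? When `FALSE`
#'   each gene contributes its burden indicator only.
#' @param maf_threshold Rare-variant cutoff passed to [compute_burden()].
#' @param expression Optional replacement expression matrix (same shape and
#'   dimnames as `cohort$expression`), e.g. a noise-perturbed selection copy.
#' @return A `design_matrix`: list with `values` (numeric matrix),
#'   `column_roles` (named vector: intercept/covariate/pedigree/gene_term),
#'   `dropped` (names of removed constant gene columns), and the settings
#'   used.
#' @export
build_design <- function(cohort, gene_ids = character(0),
                         include_expression = TRUE, maf_threshold = 0.05,
                         expression = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  stopifnot_flag(include_expression, "include_expression")
  if (anyDuplicated(gene_ids)) stop("duplicated gene IDs")
  known <- unique(cohort$variant_annotations$gene_id)
  unknown <- setdiff(gene_ids, known)
  if (length(unknown)) {
    stop("unknown gene ID(s): ", paste(unknown, collapse = ", "))
  }
  expr <- expression %||% cohort$expression
  base <- covariate_block(cohort)
  x <- base$values
  roles <- base$roles
  dropped <- character(0)
  for (g in gene_ids) {
    s <- compute_burden(cohort, g, maf_threshold)
    block <- if (include_expression) {
      e <- expr[, g]
      cbind(e, s, e * s)
    } else {
      cbind(s)
    }
    colnames(block) <- if (include_expression) {
      paste0(g, c(".G", ".S", ".GxS"))
    } else {
      paste0(g, ".S")
    }
    keep <- apply(block, 2, function(col) diff(range(col)) > 0)
    if (any(!keep)) {
      dropped <- c(dropped, colnames(block)[!keep])
      warning(sprintf("dropping constant gene-term column(s): %s",
                      paste(colnames(block)[!keep], collapse = ", ")),
              call. = FALSE)
    }
    block <- block[, keep, drop = FALSE]
    if (ncol(block)) {
      roles <- c(roles, stats::setNames(rep("gene_term", ncol(block)),
                                        colnames(block)))
      x <- cbind(x, block)
    }
  }
  structure(list(values = x, column_roles = roles, dropped = dropped,
                 gene_ids = gene_ids, include_expression = include_expression,
                 maf_threshold = maf_threshold),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d individuals x %d columns (%d gene-term)\n",
              nrow(x$values), ncol(x$values),
              sum(x$column_roles == "gene_term")))
  invisible(x)
}

#' Write a design matrix with a JSON sidecar
#'
#' The TSV holds the numeric matrix keyed by individual ID; the sidecar
#' (`<path>.json`) records column roles and the settings used to build it.
#'
#' @param design A `design_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- data.frame(individual_id = rownames(design$values), design$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(column_roles = as.list(design$column_roles),
         dropped = design$dropped,
         include_expression = design$include_expression,
         maf_threshold = design$maf_threshold),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
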