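# Logistic maximum-likelihood fit on a raw design matrix. Returns the
# deviance, coefficient vector (NA for aliased columns) and a convergence
# flag; never throws on separation.
fit_logistic_ml <- function(x, y, maxit = 100, epsilon = 1e-8) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(x, y, family = binomial(),
                             control = list(maxit = maxit, epsilon = epsilon))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(deviance = NA_real_, coefficients = rep(NA_real_, ncol(x)),
                converged = FALSE, rank = 0L))
  }
  list(deviance = fit$deviance,
       coefficients = fit$coefficients,
       converged = isTRUE(fit$converged) && !isTRUE(fit$boundary),
       rank = fit$rank)
}

#' Per-gene association p-value from the joint expression-by-burden model
#'
#' Fits the logistic model
#' \deqn{logit P(Y=1) = Age + Sex + Smoke + Age \times Sex + Pedigree +
#'   G_i + S_i + G_i S_i}
#' by maximum likelihood and tests the gene's term columns jointly against
#' the nested covariates-only model with a likelihood-ratio test; the
#' degrees of freedom equal the number of surviving (non-constant,
#' non-aliased) gene columns — 3 with expression terms, 1 without. Perfect
#' separation or non-convergence never raises: the result carries
#' `converged = FALSE` and a p-value of 1, which ranks the gene last.
#'
#' @param design A `design_matrix` containing the covariate block plus
#'   exactly one gene's term block (see [build_design()]).
#' @param phenotype A `collapsed_phenotype` or binary vector aligned with
#'   the design rows.
#' @param maxit,epsilon IRLS iteration cap and log-likelihood convergence
#'   tolerance.
#' @return One-row data.frame: `gene_id`, `p_value`, `df`, `converged`.
#' @export
gene_pvalue <- function(design, phenotype, maxit = 100, epsilon = 1e-8) {
  stopifnot(inherits(design, "design_matrix"))
  y <- phenotype_status(phenotype, rownames(design$values))
  gene_cols <- names(design$column_roles)[design$column_roles == "gene_term"]
  gene_id <- design$gene_ids
  if (length(gene_id) != 1L) {
    stop("`design` must contain exactly one gene's term block")
  }
  base_cols <- setdiff(colnames(design$values), gene_cols)
  reduced <- fit_logistic_ml(design$values[, base_cols, drop = FALSE], y,
                             maxit, epsilon)
  lrt_vs_reduced(design, y, reduced, gene_id, maxit, epsilon)
}

# Shared LRT core: full fit of the given design against a prefitted reduced
# (covariates-only) model.
lrt_vs_reduced <- function(design, y, reduced, gene_id, maxit, epsilon) {
  gene_cols <- names(design$column_roles)[design$column_roles == "gene_term"]
  if (length(gene_cols) == 0L) {
    return(data.frame(gene_id = gene_id, p_value = 1, df = 0L,
                      converged = TRUE, stringsAsFactors = FALSE))
  }
  full <- fit_logistic_ml(design$values, y, maxit, epsilon)
  gene_coef <- full$coefficients[gene_cols]
  df <- sum(!is.na(gene_coef))
  ok <- full$converged && reduced$converged && df > 0 &&
    all(abs(gene_coef[!is.na(gene_coef)]) < 30)
  if (!ok) {
    return(data.frame(gene_id = gene_id, p_value = 1, df = as.integer(df),
                      converged = FALSE, stringsAsFactors = FALSE))
  }
  stat <- max(reduced$deviance - full$deviance, 0)
  data.frame(gene_id = gene_id,
             p_value = pchisq(stat, df = df, lower.tail = FALSE),
             df = as.integer(df), converged = TRUE, stringsAsFactors = FALSE)
}

phenotype_status <- function(phenotype, ids = NULL) {
  y <- if (inherits(phenotype, "collapsed_phenotype")) phenotype$status else phenotype
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary")
  if (!is.null(ids) && !is.null(names(y))) {
    if (!setequal(names(y), ids)) {
      stop("phenotype and design name different individuals")
    }
    y <- y[ids]
  }
  as.numeric(y)
}

#' Test every candidate gene on the selection data
#'
#' Runs [gene_pvalue()] for each gene (all genes by default), fitting the
#' shared covariates-only reduced model once. Genes whose term columns are
#' all constant get `p_value = 1`, ranking them last.
#'
#' @param cohort A `cohort`.
#' @param phenotype A `collapsed_phenotype` (typically built from the
#'   selection replicate set) or binary vector.
#' @param gene_ids Genes to test; default all genes in the annotation.
#' @param include_expression Use the full `G + S + G x S` gene block
#'   (`TRUE`) or the burden-only block (`FALSE`).
#' @param maf_threshold Rare-variant cutoff.
#' @param expression Optional perturbed expression matrix for the selection
#'   data (see [inject_expression_noise()]).
#' @param maxit,epsilon Fitting controls, as in [gene_pvalue()].
#' @return data.frame with one row per gene: `gene_id`, `p_value`, `df`,
#'   `converged`, `is_causal` (NA when the cohort carries no truth labels).
#' @export
test_genes <- function(cohort, phenotype, gene_ids = NULL,
                       include_expression = TRUE, maf_threshold = 0.05,
                       expression = NULL, maxit = 100, epsilon = 1e-8) {
  stopifnot(inherits(cohort, "cohort"))
  gene_ids <- gene_ids %||% unique(cohort$variant_annotations$gene_id)
  y <- phenotype_status(phenotype, rownames(cohort$genotypes))
  base <- covariate_block(cohort)
  reduced <- fit_logistic_ml(base$values, y, maxit, epsilon)
  rows <- lapply(gene_ids, function(g) {
    design <- withCallingHandlers(
      build_design(cohort, g, include_expression, maf_threshold, expression),
      warning = function(w) invokeRestart("muffleWarning"))
    lrt_vs_reduced(design, y, reduced, g, maxit, epsilon)
  })
  out <- do.call(rbind, rows)
  out$is_causal <- if (length(cohort$causal_genes)) {
    out$gene_id %in% cohort$causal_genes
  } else {
    NA
  }
  out
}

#' Rank genes by p-value and take the top of a list kind
#'
#' Filters the test results to causal or non-causal genes (or keeps all),
#' sorts ascending by p-value with ties broken by gene ID, and returns the
#' first `size`.
#'
#' @param results data.frame from [test_genes()] (columns `gene_id`,
#'   `p_value`, and `is_causal` when filtering by causality).
#' @param list_kind `"causal"`, `"noncausal"`, or `"all"`.
#' @param size Number of genes to return; must not exceed the genes
#'   available of that kind.
#' @return A `gene_list`: list with `gene_ids` (ordered), `list_kind`,
#'   `size`.
#' @export
select_top_genes <- function(results, list_kind = c("causal", "noncausal", "all"),
                             size) {
  list_kind <- match.arg(list_kind)
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must be a non-empty data.frame of gene test results")
  }
  if (list_kind != "all") {
    if (all(is.na(results$is_causal))) {
      stop("causal labels unavailable; cannot filter by list kind")
    }
    keep <- if (list_kind == "causal") results$is_causal else !results$is_causal
    results <- results[keep, , drop = FALSE]
  }
  if (!is_count(size) || size > nrow(results)) {
    stop(sprintf("requested %s genes of kind '%s' but only %d available",
                 size, list_kind, nrow(results)))
  }
  ord <- order(results$p_value, results$gene_id)
  structure(list(gene_ids = results$gene_id[ord][seq_len(size)],
                 list_kind = list_kind, size = as.integer(size)),
            class = "gene_list")
}

#' Write ranked gene test results and a gene list
#'
#' `write_gene_results()` emits the ranked CSV consumed by reporting;
#' `write_gene_list()` the JSON gene list consumed by classification.
#'
#' @param results data.frame from [test_genes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_results <- function(results, path) {
  results <- results[order(results$p_value, results$gene_id), , drop = FALSE]
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_results
#' @param gene_list A `gene_list` from [select_top_genes()].
#' @export
write_gene_list <- function(gene_list, path) {
  stopifnot(inherits(gene_list, "gene_list"))
  jsonlite::write_json(unclass(gene_list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
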