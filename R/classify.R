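#' Specification of a probabilistic classifier
#'
#' Describes one of the three benchmarked classification methods and its
#' tuning protocol. Logistic regression is fit by maximum likelihood on the
#' full selection set. The SVMs grid-search their hyperparameters — cost
#' `C`, and kernel width `gamma` for the radial kernel — by seeded,
#' class-stratified 10-fold cross-validation on the selection set (criterion:
#' CV accuracy; ties resolved to the smallest `C`, then the smallest
#' `gamma`), then refit at the chosen values with Platt-style sigmoid
#' probability calibration so every method emits a probability of disease.
#'
#' @param method `"logistic"`, `"svm_linear"`, or `"svm_radial"`.
#' @param cost Candidate values for the SVM cost `C`.
#' @param gamma Candidate kernel widths (radial kernel only). With
#'   `gamma_dim_scaled = TRUE` (default) these are multiples of `1/d` for a
#'   `d`-column feature matrix — the libsvm convention — so the width menu
#'   adapts to designs whose dimensionality varies with the gene list.
#' @param gamma_dim_scaled Interpret `gamma` as multiples of `1/d`?
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param tuning_tolerance SMO termination tolerance used for the
#'   cross-validation fits only; the final refit uses libsvm's default
#'   (0.001). A coarser tolerance speeds tuning without materially changing
#'   the accuracy ranking of the candidates.
#' @param seed Seed for the fold assignment.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("logistic", "svm_linear", "svm_radial"),
                            cost = c(0.1, 1, 10),
                            gamma = c(0.1, 1, 10),
                            gamma_dim_scaled = TRUE,
                            cv_folds = 10, tuning_tolerance = 0.05,
                            seed = 1L) {
  stopifnot_flag(gamma_dim_scaled, "gamma_dim_scaled")
  method <- match.arg(method)
  if (!is_count(cv_folds) || cv_folds < 2) stop("`cv_folds` must be >= 2")
  if (method != "logistic" && (length(cost) == 0L ||
      (method == "svm_radial" && length(gamma) == 0L))) {
    stop("tuning grid must be non-empty for SVM methods")
  }
  structure(list(method = method, cost = sort(cost), gamma = sort(gamma),
                 gamma_dim_scaled = gamma_dim_scaled,
                 cv_folds = as.integer(cv_folds),
                 tuning_tolerance = tuning_tolerance, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Seeded, class-stratified fold labels.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Non-intercept feature matrix with train-set standardization parameters.
svm_features <- function(design) {
  x <- design$values[, design$column_roles != "intercept", drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

tune_svm_cv <- function(x, y, spec) {
  kernel <- if (spec$method == "svm_linear") "linear" else "radial"
  gammas <- if (isTRUE(spec$gamma_dim_scaled)) spec$gamma / ncol(x) else spec$gamma
  grid <- if (kernel == "linear") {
    data.frame(cost = spec$cost, gamma = NA_real_)
  } else {
    expand.grid(gamma = gammas, cost = spec$cost)[, c("cost", "gamma")]
  }
  # order so that which.max's first-winner rule = smallest C, then gamma
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  if (nrow(grid) == 1L) return(grid)  # nothing to tune
  fold <- stratified_folds(y, spec$cv_folds, spec$seed)
  yf <- factor(y, levels = c(0, 1))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = kernel,
                      cost = grid$cost[i],
                      gamma = if (kernel == "radial") grid$gamma[i] else 1 / ncol(x),
                      tolerance = spec$tuning_tolerance %||% 0.001,
                      scale = FALSE)
      pred <- predict(m, x[!tr, , drop = FALSE])
      hits <- hits + sum(pred == yf[!tr])
    }
    hits / length(y)
  }, numeric(1))
  grid[which.max(acc), , drop = FALSE]
}

#' Fit a classifier on the selection data
#'
#' @param design A `design_matrix` built from the selection data.
#' @param phenotype A `collapsed_phenotype` or binary vector aligned with
#'   the design rows (both classes must be present).
#' @param spec A [classifier_spec()].
#' @return An `rv_classifier` handle usable with [predict_scores()]; it
#'   records the method, the training column names, and for SVMs the chosen
#'   hyperparameters (`fitted_hyperparameters`) and standardization
#'   parameters.
#' @details For logistic regression with at least as many columns as rows,
#'   an L2-regularised (ridge) fit at a small fixed penalty replaces the
#'   unpenalised maximum-likelihood fit, with a warning.
#' @export
fit_classifier <- function(design, phenotype, spec) {
  stopifnot(inherits(design, "design_matrix"), inherits(spec, "classifier_spec"))
  y <- phenotype_status(phenotype, rownames(design$values))
  if (length(unique(y)) < 2L) stop("phenotype has a single class; cannot fit")
  if (spec$method == "logistic") {
    x <- design$values
    if (ncol(x) >= nrow(x)) {
      warning("design has >= as many columns as rows; using ridge-stabilized fit")
      if (!requireNamespace("glmnet", quietly = TRUE)) {
        stop("the ridge fallback requires the glmnet package")
      }
      fit <- glmnet::glmnet(x[, colnames(x) != "intercept", drop = FALSE], y,
                            family = "binomial", alpha = 0, lambda = 1e-3)
      return(structure(list(method = "logistic", ridge = fit,
                            columns = colnames(design$values)),
                       class = "rv_classifier"))
    }
    fit <- fit_logistic_ml(x, y)
    if (!fit$converged) {
      warning("logistic fit did not converge cleanly; scores may be unstable")
    }
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    return(structure(list(method = "logistic", coefficients = coefs,
                          columns = colnames(x)),
                     class = "rv_classifier"))
  }
  feats <- svm_features(design)
  best <- tune_svm_cv(feats$x, y, spec)
  kernel <- if (spec$method == "svm_linear") "linear" else "radial"
  model <- with_seed(derive_seed(spec$seed, 1L), {
    e1071::svm(feats$x, factor(y, levels = c(0, 1)), kernel = kernel,
               cost = best$cost,
               gamma = if (kernel == "radial") best$gamma else 1 / ncol(feats$x),
               probability = TRUE, scale = FALSE)
  })
  structure(list(method = spec$method, model = model,
                 fitted_hyperparameters = list(
                   cost = best$cost,
                   gamma = if (kernel == "radial") best$gamma else NULL),
                 center = feats$center, scale = feats$scale,
                 columns = colnames(design$values)),
            class = "rv_classifier")
}

#' @export
print.rv_classifier <- function(x, ...) {
  cat(sprintf("<rv_classifier> method=%s, %d training columns\n",
              x$method, length(x$columns)))
  if (!is.null(x$fitted_hyperparameters)) {
    hp <- x$fitted_hyperparameters
    cat(sprintf("  tuned: C=%g%s\n", hp$cost,
                if (is.null(hp$gamma)) "" else sprintf(", gamma=%g", hp$gamma)))
  }
  invisible(x)
}

#' Predict disease probabilities on a classification design
#'
#' The classification design must have exactly the training design's columns
#' in the same order; any mismatch raises an error listing the symmetric
#' difference.
#'
#' @param model An `rv_classifier` from [fit_classifier()].
#' @param design A `design_matrix` for the classification individuals.
#' @return Named numeric vector of probabilities in [0, 1].
#' @export
predict_scores <- function(model, design) {
  stopifnot(inherits(model, "rv_classifier"), inherits(design, "design_matrix"))
  cols <- colnames(design$values)
  if (!identical(cols, model$columns)) {
    extra <- setdiff(cols, model$columns)
    missing <- setdiff(model$columns, cols)
    stop(sprintf(
      "design columns do not match training columns (missing: %s; extra: %s%s)",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none",
      if (!length(extra) && !length(missing)) "; column order differs" else ""))
  }
  if (model$method == "logistic") {
    if (!is.null(model$ridge)) {
      x <- design$values[, cols != "intercept", drop = FALSE]
      p <- as.numeric(predict(model$ridge, x, type = "response"))
    } else {
      p <- as.numeric(plogis(design$values %*% model$coefficients))
    }
  } else {
    x <- design$values[, design$column_roles != "intercept", drop = FALSE]
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
    pred <- predict(model$model, x, probability = TRUE)
    p <- attr(pred, "probabilities")[, "1"]
  }
  stats::setNames(as.numeric(p), rownames(design$values))
}

#' Area under the ROC curve
#'
#' Computed as the Wilcoxon-Mann-Whitney probability: the mean over all
#' case-control pairs of 1 if the case outscores the control, 0.5 on ties,
#' 0 otherwise. Uses midranks, so ties are handled exactly.
#'
#' @param scores Numeric score (probability) vector.
#' @param truth Binary vector of true statuses (>= 1 case and >= 1 control).
#' @return AUC in [0, 1].
#' @examples
#' compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
compute_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires at least one case and one control")
  }
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score a fitted classifier on held-out truth
#'
#' Convenience wrapper producing the per-individual scores together with the
#' AUC against a held-out binary status.
#'
#' @inheritParams predict_scores
#' @param truth Named binary vector of true statuses for the classification
#'   individuals.
#' @return A `prediction_result`: list with `scores`, `truth`, `auc`,
#'   `method`, `fitted_hyperparameters`.
#' @export
score_classifier <- function(model, design, truth) {
  scores <- predict_scores(model, design)
  if (!is.null(names(truth))) truth <- truth[names(scores)]
  structure(list(scores = scores, truth = truth,
                 auc = compute_auc(scores, truth), method = model$method,
                 fitted_hyperparameters = model$fitted_hyperparameters),
            class = "prediction_result")
}

#' Write a prediction result as CSV plus JSON summary
#'
#' @param result A `prediction_result`.
#' @param path Output CSV path (`<path>.json` holds method, tuned
#'   hyperparameters and AUC).
#' @return Invisibly, `path`.
#' @export
write_prediction <- function(result, path) {
  stopifnot(inherits(result, "prediction_result"))
  utils::write.csv(data.frame(individual_id = names(result$scores),
                              score = result$scores, truth = result$truth),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(method = result$method,
         hyperparameters = result$fitted_hyperparameters,
         auc = result$auc),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
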