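# The GA objective: 5-fold cross-validated AUC of a logistic regression on
# the mask-induced design, with out-of-fold probabilities pooled across folds.

# Convert a dense 0/1 design into the index-coded representation the IRLS
# core consumes (one record per column; design column 1 is the intercept).
dense_to_idx <- function(values) {
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L))) {
    stop_evospec("design entries must be 0 or 1", "evospec_validation_error")
  }
  m <- max(rowSums(values), 0L) + 1L
  idx <- matrix(0L, nrow = m, ncol = nrow(values))
  idx[1L, ] <- 1L
  for (i in seq_len(nrow(values))) {
    active <- which(values[i, ] == 1L)
    if (length(active)) idx[1L + seq_along(active), i] <- active + 1L
  }
  idx
}

#' Fit a (ridge-penalized) binary logistic regression on an indicator design
#'
#' Maximum-likelihood fit by iteratively reweighted least squares, with an
#' optional ridge penalty on all coefficients except the intercept. The fit
#' is deterministic: identical inputs give identical coefficients to
#' numerical tolerance. The tiny default penalty used elsewhere in the
#' package (`ridge = 1e-6`) guards against complete separation from rare
#' complaints while leaving coefficients essentially unpenalized.
#'
#' @param design a `design_matrix` from [build_design()], or any list with
#'   binary `values` (matrix) and `outcome` elements.
#' @param ridge non-negative ridge penalty; `0` gives the plain MLE.
#' @param maxit iteration cap.
#' @param tol convergence tolerance on the max absolute coefficient step.
#' @return A `fitted_logistic` object with named `coefficients`
#'   (`"(Intercept)"` first), `converged`, `iterations`.
#' @export
fit_logistic <- function(design, ridge = 1e-6, maxit = 50L, tol = 1e-9) {
  values <- design$values
  y <- design$outcome
  if (is.null(values) || is.null(y)) {
    stop_evospec("design must have 'values' and 'outcome'",
                 "evospec_validation_error")
  }
  if (length(unique(y)) < 2L) {
    stop_evospec("design must contain at least one row of each outcome class",
                 "evospec_validation_error")
  }
  if (ridge < 0) {
    stop_evospec("ridge must be non-negative", "evospec_validation_error")
  }
  idx <- dense_to_idx(values)
  fit <- irls_fit_idx(idx, as.numeric(y), ncol(values) + 1L, ridge,
                      as.integer(maxit), tol)
  if (!fit$converged) {
    stop_evospec(sprintf(
      paste0("logistic fit did not converge in %d iterations ",
             "(last step %.3g, max |coef| %.3g)%s"),
      maxit, fit$last_step, fit$max_abs_coef,
      if (ridge == 0 && fit$max_abs_coef > 15) {
        "; coefficients diverging suggests complete separation - use ridge > 0"
      } else ""),
      "evospec_convergence_error")
  }
  coefs <- fit$coefficients
  names(coefs) <- c("(Intercept)", colnames(values))
  structure(list(coefficients = coefs, column_names = colnames(values),
                 converged = fit$converged, iterations = fit$iterations,
                 ridge = ridge),
            class = "fitted_logistic")
}

#' Predicted event probabilities from a fitted logistic model
#'
#' @param object a `fitted_logistic`.
#' @param design a design with the same columns the model was fitted on.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.fitted_logistic <- function(object, design, ...) {
  values <- design$values
  if (!identical(colnames(values), object$column_names)) {
    stop_evospec("design columns do not match the fitted model",
                 "evospec_validation_error")
  }
  predict_prob_idx(dense_to_idx(values), object$coefficients)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The fraction of (positive, negative) pairs in which the positive scores
#' higher, counting ties as 1/2; computed via mid-ranks.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_evospec("scores and labels must be the same length",
                 "evospec_validation_error")
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_evospec("AUC undefined: both outcome classes must be present",
                 "evospec_degenerate_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Outcome-stratified fold assignment, a pure function of (outcome, k,
# fold_seed). One fold_seed is shared by every candidate evaluation in a GA
# run (common random numbers), so fitness differences reflect masks only.
assign_folds <- function(outcome, k, fold_seed) {
  if (k < 2L) {
    stop_evospec("k must be at least 2", "evospec_validation_error")
  }
  counts <- table(factor(outcome, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stop_evospec(sprintf(
      "stratified %d-fold CV needs at least %d records of each class (have %s)",
      k, k, paste(counts, collapse = "/")),
      "evospec_stratification_error")
  }
  with_seed(fold_seed, {
    folds <- integer(length(outcome))
    for (cls in c(0L, 1L)) {
      ids <- which(outcome == cls)
      folds[sample(ids)] <- rep_len(seq_len(k), length(ids))
    }
    folds
  })
}

cached_folds <- function(cohort, k, fold_seed) {
  key <- paste0("folds_", k, "_", fold_seed)
  f <- cohort$cache[[key]]
  if (is.null(f)) {
    f <- assign_folds(cohort$records$outcome, k, fold_seed)
    cohort$cache[[key]] <- f
  }
  f
}

#' Cross-validated AUC of the logistic model induced by a specification mask
#'
#' Partitions the cohort into `k` outcome-stratified folds (a pure function
#' of `fold_seed`), fits the full-rank logistic design on each training
#' split, predicts held-out probabilities, and summarizes the pooled
#' out-of-fold probabilities as a single AUC. Deterministic: repeated calls
#' with identical arguments return identical results.
#'
#' @param cohort an `ed_cohort`.
#' @param mask specification mask (ignored for the baseline modes).
#' @param mode specification mode, as in [build_design()].
#' @param k number of folds (default 5).
#' @param fold_seed integer seed fixing the fold assignment.
#' @param ridge ridge penalty passed to the logistic fit.
#' @param summary `"pooled"` (default) computes one AUC on the pooled
#'   out-of-fold probabilities; `"averaged"` averages per-fold AUCs. Pooling
#'   is the package default because downstream subgroup evaluation and
#'   DeLong tests operate on aligned per-patient probability vectors.
#' @return A `cv_result`: list with `oof_probabilities` (one per record,
#'   each from the fold model that did not train on it), `fold_assignment`,
#'   `auc`, `auc_by_fold`, and the call's mask/mode/seeds.
#' @export
cv_fitness <- function(cohort, mask = NULL,
                       mode = c("flattened", "hierarchical",
                                "complaints_only", "categories_only"),
                       k = 5L, fold_seed = 1L, ridge = 1e-6,
                       summary = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  summary <- match.arg(summary)
  ctx <- design_context(cohort)
  n <- length(ctx$hierarchy$complaints)
  if (mode %in% c("flattened", "hierarchical")) {
    mask <- check_mask(mask, n)
  } else {
    mask <- NULL
  }
  folds <- cached_folds(cohort, k, fold_seed)
  di <- design_index(ctx, mask, mode)
  y <- as.numeric(ctx$outcome)
  res <- tryCatch(
    cv_oof_idx(di$idx, y, folds, k, di$p, ridge, 30L, 1e-7, 1e-7),
    error = function(e) {
      stop_evospec(conditionMessage(e), "evospec_convergence_error")
    })
  if (res$failed_fold > 0L) {
    stop_evospec(sprintf(
      "fold %d: logistic fit did not converge%s", res$failed_fold,
      if (ridge == 0) "; use ridge > 0 if separation is suspected" else ""),
      "evospec_convergence_error")
  }
  oof <- res$oof
  auc_by_fold <- vapply(seq_len(k), function(f) {
    auc(oof[folds == f], y[folds == f])
  }, numeric(1))
  auc_pooled <- auc(oof, y)
  structure(
    list(oof_probabilities = oof, fold_assignment = folds,
         auc = if (summary == "pooled") auc_pooled else mean(auc_by_fold),
         auc_pooled = auc_pooled, auc_by_fold = auc_by_fold,
         mask = mask, mode = mode, k = k, fold_seed = fold_seed,
         ridge = ridge, summary = summary),
    class = "cv_result"
  )
}

# Lean fitness path for the GA: pooled out-of-fold AUC only, no per-fold
# bookkeeping. Produces exactly the same value as cv_fitness()$auc (pooled).
cv_auc_fast <- function(cohort, mask, mode, k, fold_seed, ridge) {
  ctx <- design_context(cohort)
  folds <- cached_folds(cohort, k, fold_seed)
  di <- design_index(ctx, mask, mode)
  y <- as.numeric(ctx$outcome)
  res <- cv_oof_idx(di$idx, y, folds, k, di$p, ridge, 30L, 1e-7, 1e-7)
  if (res$failed_fold > 0L) {
    stop_evospec(sprintf("fold %d: logistic fit did not converge",
                         res$failed_fold), "evospec_convergence_error")
  }
  auc(res$oof, y)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): AUC = %.4f (%s)\n", x$k, x$mode, x$auc,
              x$summary))
  invisible(x)
}

#' Export per-record cross-validation results as a data frame
#'
#' @param cv a `cv_result`.
#' @param outcome optional outcome vector to include.
#' @return Data frame with record id, fold, out-of-fold probability and
#'   (if given) outcome.
#' @export
cv_as_df <- function(cv, outcome = NULL) {
  df <- data.frame(record = seq_along(cv$oof_probabilities),
                   fold = cv$fold_assignment,
                   oof_probability = cv$oof_probabilities)
  if (!is.null(outcome)) df$outcome <- outcome
  df
}
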