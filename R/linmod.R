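# Stepwise additive multivariate classifier ("linmod"): candidate assays are
# ranked by univariate association with the output, included stepwise with a
# +/-1 weight (the sign of the univariate direction), and a chemical is
# predicted active when
#   sum_{i <= Nmax} sign_i * score_i - Cutoff > 0.
# Nmax and Cutoff are tuned by stratified k-fold cross-validation: Nmax
# maximizes mean held-out ROC AUC, Cutoff the pooled held-out balanced
# accuracy (AUC is invariant to the additive Cutoff).

#' Rank candidate columns by univariate association
#'
#' Welch t-test of each column's log-potency scores grouped by the binary
#' output. Columns are ordered by ascending p, ties broken by descending
#' |t| and then column id; the weight is the sign of the association
#' (+1 when output-positive chemicals score higher). Untestable columns
#' (degenerate groups) are dropped.
#'
#' @param scores Numeric matrix of log-potency scores (chemicals x columns).
#' @param output Binary output vector (length `nrow(scores)`).
#' @return `data.frame` with `column`, `sign`, `t`, `p_value`, in inclusion
#'   order (zero rows if nothing is testable).
#' @export
rank_features <- function(scores, output) {
  if (ncol(scores) < 1) stop("need at least one candidate column", call. = FALSE)
  rows <- lapply(colnames(scores), function(cn) {
    r <- ttest_association(scores[, cn], output, input_col = cn)
    data.frame(column = cn, sign = r$direction, t = r$statistic,
               p_value = r$p_value, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  rk <- do.call(rbind, rows)
  rk <- rk[!rk$degenerate & is.finite(rk$p_value) & rk$sign != 0, , drop = FALSE]
  if (nrow(rk) == 0) return(rk[, c("column", "sign", "t", "p_value")])
  rk <- rk[order(rk$p_value, -abs(rk$t), rk$column), , drop = FALSE]
  rownames(rk) <- NULL
  rk[, c("column", "sign", "t", "p_value")]
}

#' Model score and prediction
#'
#' `score = sum_i sign_i * score_i - Cutoff`; a chemical is predicted active
#' iff its score is strictly greater than 0 (the boundary itself is
#' inactive).
#'
#' @param model A `linmod` model (see [fit_linmod()]), or a list with
#'   `included_cols`, `signs`, `Cutoff`.
#' @param scores Numeric matrix (or single named vector) of log-potency
#'   scores covering the model's included columns.
#' @return `data.frame` with `score` and `predicted` (0/1).
#' @export
model_score <- function(model, scores) {
  if (is.null(dim(scores))) scores <- t(as.matrix(scores))
  miss <- setdiff(model$included_cols, colnames(scores))
  if (length(miss) > 0) {
    stop("score matrix missing model columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  s <- as.vector(scores[, model$included_cols, drop = FALSE] %*%
                   model$signs) - model$Cutoff
  data.frame(score = s, predicted = as.integer(s > 0))
}

raw_sums <- function(scores, cols, signs) {
  as.vector(scores[, cols, drop = FALSE] %*% signs)
}

#' ROC curve, AUC and threshold metrics
#'
#' Threshold sweep over the unique scores (predicted positive = score above
#' threshold); AUC by the trapezoid rule, which equals the
#' positive-negative pairwise concordance statistic with ties counted 1/2.
#' Sensitivity/specificity/balanced accuracy are reported at `threshold`
#' under the model's strict `> threshold` decision rule.
#'
#' @param scores Numeric score vector.
#' @param labels Binary truth vector; both classes must be present.
#' @param threshold Decision threshold for the at-threshold metrics
#'   (default 0).
#' @return An object of class `roc_result`: `points` (fpr, tpr), `auc`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
roc_curve <- function(scores, labels, threshold = 0) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct score cut (predict positive >= cut)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(l == 1)[keep] / npos)
  fpr <- c(0, cumsum(l == 0)[keep] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred <- as.integer(scores > threshold)
  sens <- sum(pred == 1 & labels == 1) / npos
  spec <- sum(pred == 0 & labels == 0) / nneg
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 threshold = threshold),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.4f; at threshold %.3g: sens = %.3f, spec = %.3f, BA = %.3f\n",
    x$auc, x$threshold, x$sensitivity, x$specificity, x$balanced_accuracy))
  invisible(x)
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

cutoff_grid <- function(sums) {
  u <- sort(unique(sums))
  if (length(u) == 1) return(c(u - 1, u, u + 1))
  c(u[1] - 1, u[-length(u)] + diff(u) / 2, u[length(u)] + 1)
}

#' Fit the stepwise additive classifier by cross-validation
#'
#' Stratified k-fold cross-validation (k = 5 realizes the 80% training /
#' 20% test split): within each training fold the candidate columns are
#' ranked by univariate association; for each candidate Nmax the held-out
#' ROC AUC of the first-Nmax signed score sum is computed. Nmax maximizes
#' the mean held-out AUC (ties toward the smaller, more parsimonious Nmax).
#' Cutoff then maximizes pooled held-out balanced accuracy over a grid of
#' midpoints between consecutive distinct score sums plus flanking extremes
#' (ties toward the smaller Cutoff). The returned model re-ranks on the full
#' data and carries per-fold and aggregate metrics, including the Fisher
#' exact p of the pooled predicted-vs-true contingency table.
#'
#' @param scores Numeric matrix of log-potency scores (chemicals x columns).
#' @param output Binary output vector.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param nmax_cap Upper bound on Nmax (default `min(20, n columns)`).
#' @return An object of class `linmod`.
#' @export
fit_linmod <- function(scores, output, k_folds = 5, seed = 1,
                       nmax_cap = 20) {
  n <- nrow(scores)
  if (n < 2 * k_folds) stop("too few chemicals for k folds", call. = FALSE)
  for (cls in 0:1) {
    if (sum(output == cls) < k_folds) {
      stop("class ", cls, " has fewer members than folds", call. = FALSE)
    }
  }
  fold <- stratified_folds(output, k_folds, seed)
  fold_rank <- lapply(seq_len(k_folds), function(j) {
    rank_features(scores[fold != j, , drop = FALSE], output[fold != j])
  })
  max_n <- min(nmax_cap, min(vapply(fold_rank, nrow, 1L)))
  if (max_n < 1) stop("no testable columns in some training fold", call. = FALSE)

  auc_fold <- matrix(NA_real_, nrow = k_folds, ncol = max_n)
  for (j in seq_len(k_folds)) {
    rk <- fold_rank[[j]]
    test <- fold == j
    for (nm in seq_len(max_n)) {
      s <- raw_sums(scores[test, , drop = FALSE],
                    rk$column[seq_len(nm)], rk$sign[seq_len(nm)])
      auc_fold[j, nm] <- roc_curve(s, output[test])$auc
    }
  }
  mean_auc <- colMeans(auc_fold)
  best_n <- which.max(mean_auc)  # which.max takes the first (smallest) tie

  # pooled held-out sums at best_n drive the Cutoff grid and selection
  pooled <- numeric(n)
  for (j in seq_len(k_folds)) {
    rk <- fold_rank[[j]]
    test <- fold == j
    pooled[test] <- raw_sums(scores[test, , drop = FALSE],
                             rk$column[seq_len(best_n)],
                             rk$sign[seq_len(best_n)])
  }
  grid <- cutoff_grid(pooled)
  ba <- vapply(grid, function(ct) {
    pred <- as.integer(pooled > ct)
    sens <- sum(pred == 1 & output == 1) / sum(output == 1)
    spec <- sum(pred == 0 & output == 0) / sum(output == 0)
    (sens + spec) / 2
  }, numeric(1))
  cutoff <- grid[which.max(ba)]

  fold_metrics <- do.call(rbind, lapply(seq_len(k_folds), function(j) {
    test <- fold == j
    r <- roc_curve(pooled[test], output[test], threshold = cutoff)
    data.frame(fold = j, auc = auc_fold[j, best_n], sensitivity = r$sensitivity,
               specificity = r$specificity,
               balanced_accuracy = r$balanced_accuracy)
  }))
  pred <- as.integer(pooled > cutoff)
  fp <- fisher_association(pred, output, "predicted", "truth")

  final_rank <- rank_features(scores, output)
  inc <- final_rank[seq_len(min(best_n, nrow(final_rank))), , drop = FALSE]
  structure(list(
    output_col = attr(output, "column") %||% "output",
    included_cols = inc$column,
    signs = stats::setNames(inc$sign, inc$column),
    Nmax = best_n,
    Cutoff = cutoff,
    ranking = final_rank,
    k_folds = k_folds,
    seed = seed,
    cv_metrics = list(
      per_fold = fold_metrics,
      mean_auc_by_nmax = mean_auc,
      mean_auc = mean_auc[best_n],
      balanced_accuracy = mean(fold_metrics$balanced_accuracy),
      sensitivity = mean(fold_metrics$sensitivity),
      specificity = mean(fold_metrics$specificity),
      fisher_p = fp$p_value,
      heldout_scores = pooled - cutoff,
      fold = fold
    )
  ), class = "linmod")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linmod <- function(x, ...) {
  cat(sprintf("linmod: %d included columns (Nmax = %d), Cutoff = %.4g\n",
              length(x$included_cols), x$Nmax, x$Cutoff))
  cat("  included:", paste(sprintf("%s(%+d)", x$included_cols,
                                   x$signs), collapse = ", "), "\n")
  cat(sprintf("  CV: mean AUC = %.3f, BA = %.3f, sens = %.3f, spec = %.3f\n",
              x$cv_metrics$mean_auc, x$cv_metrics$balanced_accuracy,
              x$cv_metrics$sensitivity, x$cv_metrics$specificity))
  invisible(x)
}

#' @export
predict.linmod <- function(object, scores, ...) {
  ms <- model_score(object, scores)
  data.frame(chemical = rownames(scores), ms, stringsAsFactors = FALSE)
}

#' Serialize a linmod model to JSON
#'
#' @param model A `linmod` model.
#' @param path File path.
#' @return `read_linmod` returns a list mirroring the model fields.
#' @export
write_linmod <- function(model, path) {
  x <- list(output = model$output_col,
            included_cols = model$included_cols,
            signs = as.list(model$signs),
            Nmax = model$Nmax, Cutoff = model$Cutoff,
            k_folds = model$k_folds, seed = model$seed,
            cv = list(mean_auc = model$cv_metrics$mean_auc,
                      balanced_accuracy = model$cv_metrics$balanced_accuracy,
                      sensitivity = model$cv_metrics$sensitivity,
                      specificity = model$cv_metrics$specificity,
                      fisher_p = model$cv_metrics$fisher_p,
                      per_fold = model$cv_metrics$per_fold))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linmod
#' @export
read_linmod <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
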