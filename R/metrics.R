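# Evaluation metrics: accuracy, macro-F1, Cohen's kappa (unweighted and
# quadratic-weighted), one-vs-rest macro AUROC / AUPR, confusion matrices
# and precision-recall curves.

#' Confusion matrix (rows = true, columns = predicted)
#'
#' @param truth,pred Integer grades in `0..n_class-1`.
#' @param n_class Number of classes (default 5).
#' @return `n_class x n_class` integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, n_class = 5L) {
  stopifnot(length(truth) == length(pred))
  m <- table(factor(truth, levels = 0:(n_class - 1L)),
             factor(pred, levels = 0:(n_class - 1L)))
  unclass(matrix(as.integer(m), n_class, n_class,
                 dimnames = list(true = 0:(n_class - 1L),
                                 pred = 0:(n_class - 1L))))
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/n` and chance agreement `p_e = sum_c row_c * col_c / n^2`;
#' returns 0 when `p_e = 1` by convention.  The quadratic-weighted variant
#' penalises disagreements by squared grade distance (common in
#' retinopathy grading, but not the default here).
#'
#' @param confusion Square count matrix (rows = true, columns = predicted).
#' @param weights `"none"` (default) or `"quadratic"`.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(confusion, weights = c("none", "quadratic")) {
  weights <- match.arg(weights)
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n < 1) stopf("confusion matrix is empty")
  k <- nrow(confusion)
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  if (weights == "none") {
    p_o <- sum(diag(confusion)) / n
    p_e <- sum(rs * cs) / n^2
    if (abs(1 - p_e) < 1e-12) return(0)
    (p_o - p_e) / (1 - p_e)
  } else {
    w <- outer(seq_len(k) - 1L, seq_len(k) - 1L,
               function(i, j) (i - j)^2) / (k - 1L)^2
    expected <- outer(rs, cs) / n
    denom <- sum(w * expected)
    if (denom < 1e-12) return(0)
    1 - sum(w * confusion) / denom
  }
}

#' Macro-averaged F1 score from a confusion matrix
#'
#' Unweighted mean over classes of per-class F1; a class with zero support
#' and zero predictions contributes F1 = 0.
#'
#' @param confusion Square count matrix (rows = true, columns = predicted).
#' @return Macro F1 in \[0, 1\].
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (sum(confusion) < 1) stopf("confusion matrix is empty")
  tp <- diag(confusion)
  f1 <- 2 * tp / (rowSums(confusion) + colSums(confusion))
  f1[!is.finite(f1)] <- 0
  mean(f1)
}

accuracy_score <- function(confusion) sum(diag(confusion)) / sum(confusion)

# ROC points with tie-grouped thresholds; returns (fpr, tpr) including the
# (0,0) origin, plus the matching (recall, precision) step points.
binary_curves <- function(score, label) {
  o <- order(-score, seq_along(score))
  s <- score[o]
  l <- label[o]
  pos <- sum(l)
  neg <- length(l) - pos
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  list(tpr = c(0, tp / pos), fpr = c(0, fp / neg),
       recall = tp / pos, precision = tp / (tp + fp))
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' One-vs-rest ROC and precision-recall curves
#'
#' Per class: trapezoidal AUROC and step-interpolated average precision
#' (AUPR); macro values are unweighted means over the classes present in
#' `truth`.  A class absent from `truth` is excluded from the macro
#' averages with a warning.
#'
#' @param scores `n x K` matrix of class probabilities (or scores).
#' @param truth Integer grades in `0..K-1`.
#' @return List with `auroc_macro`, `aupr_macro` and `per_class` (one
#'   entry per class: `auroc`, `aupr`, and `roc` / `pr` point data frames;
#'   `NULL` for absent classes).
#' @export
roc_pr_curves <- function(scores, truth) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  per_class <- vector("list", K)
  names(per_class) <- as.character(0:(K - 1L))
  absent <- setdiff(0:(K - 1L), unique(truth))
  if (length(absent)) {
    warning(sprintf("class(es) %s absent from truth; excluded from macro averages",
                    paste(absent, collapse = ", ")))
  }
  for (c0 in 0:(K - 1L)) {
    if (c0 %in% absent) next
    lab <- as.integer(truth == c0)
    cv <- binary_curves(scores[, c0 + 1L], lab)
    auroc <- if (all(lab == 1)) NA_real_ else trapezoid(cv$fpr, cv$tpr)
    aupr <- sum(diff(c(0, cv$recall)) * cv$precision)
    per_class[[as.character(c0)]] <-
      list(auroc = auroc, aupr = aupr,
           roc = data.frame(fpr = cv$fpr, tpr = cv$tpr),
           pr = data.frame(recall = cv$recall, precision = cv$precision))
  }
  ok <- !vapply(per_class, is.null, logical(1))
  list(auroc_macro = mean(vapply(per_class[ok], `[[`, numeric(1), "auroc"),
                          na.rm = TRUE),
       aupr_macro = mean(vapply(per_class[ok], `[[`, numeric(1), "aupr")),
       per_class = per_class)
}

#' Full metrics report for a labelled prediction set
#'
#' @param truth Integer grades in 0..4.
#' @param probs `n x 5` matrix of predicted probabilities (class decided
#'   by arg-max, ties to the lower grade).
#' @return An object of class `metrics_report`: accuracy, macro F1,
#'   unweighted and quadratic-weighted kappa, macro AUROC/AUPR, the 5x5
#'   confusion matrix, per-class precision/recall/F1, and `n`.
#' @export
metrics_report <- function(truth, probs) {
  probs <- as.matrix(probs)
  pred <- argmax_row(probs) - 1L
  cm <- confusion_matrix(truth, pred)
  curves <- roc_pr_curves(probs, truth)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = accuracy_score(cm),
                 f1_macro = macro_f1(cm),
                 kappa = cohen_kappa(cm),
                 kappa_quadratic = cohen_kappa(cm, "quadratic"),
                 auroc_macro = curves$auroc_macro,
                 aupr_macro = curves$aupr_macro,
                 confusion = cm,
                 per_class = data.frame(grade = 0:4, precision = prec,
                                        recall = rec, f1 = f1,
                                        support = rowSums(cm)),
                 curves = curves$per_class,
                 n = length(truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Metrics over %d samples\n", x$n))
  cat(sprintf("  accuracy   : %.*f\n", digits, x$accuracy))
  cat(sprintf("  macro F1   : %.*f\n", digits, x$f1_macro))
  cat(sprintf("  kappa      : %.*f  (quadratic: %.*f)\n", digits, x$kappa,
              digits, x$kappa_quadratic))
  cat(sprintf("  macro AUROC: %.*f   macro AUPR: %.*f\n", digits,
              x$auroc_macro, digits, x$aupr_macro))
  cat("  confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on a labelled set
#'
#' Runs [mc_dropout_predict()] batch-wise and computes the metrics from
#' the Monte-Carlo mean probabilities.
#'
#' @param model A fitted [fundus_gcn()] model.
#' @param samples Labelled samples (e.g. the test partition).
#' @param T_passes MC dropout passes (default from the model config).
#' @param seed Optional seed for the dropout draws.
#' @return List with `metrics` (a [metrics_report()]) and `predictions`
#'   (the `prediction_bundle`).
#' @export
evaluate <- function(model, samples, T_passes = NULL, seed = NULL) {
  bundle <- mc_dropout_predict(model, samples, T_passes = T_passes,
                               seed = seed)
  truth <- vapply(samples, `[[`, integer(1), "grade")
  list(metrics = metrics_report(truth, attr(bundle, "ybar")),
       predictions = bundle)
}

#' Write a metrics report as flat-key JSON
#'
#' Keys: `accuracy, f1_macro, kappa, kappa_quadratic, auroc_macro,
#' aupr_macro, n, confusion` (row-major 5x5) and `per_class`.
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @export
write_metrics_json <- function(report, path) {
  x <- list(accuracy = report$accuracy, f1_macro = report$f1_macro,
            kappa = report$kappa, kappa_quadratic = report$kappa_quadratic,
            auroc_macro = report$auroc_macro, aupr_macro = report$aupr_macro,
            n = report$n,
            confusion = unname(report$confusion),
            per_class = report$per_class)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-class precision-recall curve points as CSV files
#'
#' One `pr_class<g>.csv` per class with columns `recall,precision`.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @export
write_pr_curves_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(report$curves)) {
    cl <- report$curves[[g]]
    if (is.null(cl)) next
    utils::write.csv(cl$pr, file.path(dir, sprintf("pr_class%s.csv", g)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
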