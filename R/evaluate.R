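# Classification metrics and nested (double) cross-validation.
#
# The external loop estimates generalization of the entire pipeline; every
# label-dependent step (filters, stability selection, refits) runs inside
# each external training fold only. Label-free preprocessing (LD reduction,
# gene assignment) is done once by the caller on all samples, which leaks no
# phenotype information.

#' Classification metrics for case/control predictions
#'
#' Positive class is `+1`. Precision and recall are 0 when their denominator
#' is empty, and F1 is 0 when precision + recall is 0.
#'
#' @param y_true,y_pred Aligned vectors of labels in `{-1, +1}`.
#' @return Named numeric vector: `precision`, `recall`, `f1`, `accuracy`.
#' @export
metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == -1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == -1L)
  tn <- sum(y_true == -1L & y_pred == -1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- (tp + tn) / length(y_true)
  c(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' Double (nested) cross-validation of the two-stage pipeline
#'
#' External loop: stratified 2-fold split or leave-one-out. The two-stage
#' discovery (including its internal 2-fold CV for lambda) runs on each
#' external training set only; held-out predictions are pooled into one
#' confusion matrix and scored once. Folds that would lose a class raise an
#' error. An external training fold whose final model is empty predicts its
#' majority class.
#'
#' @param gm A [genotype_matrix()] (after any LD reduction).
#' @param phen A [phenotype()].
#' @param gene_map Named list from [assign_snps()].
#' @param cfg A [run_config()].
#' @param external `"2fold"` or `"loo"`.
#' @return A list of class `cv_report`: `mode`, `precision`, `recall`, `f1`,
#'   `accuracy`, `predictions`.
#' @export
double_cv <- function(gm, phen, gene_map, cfg = run_config(),
                      external = c("2fold", "loo")) {
  external <- match.arg(external)
  y <- phen$labels
  n <- length(y)
  if (external == "2fold" && n < 4L) stop("2-fold CV needs n >= 4", call. = FALSE)
  if (external == "loo" && n < 2L) stop("LOO CV needs n >= 2", call. = FALSE)

  if (external == "2fold") {
    foldid <- with_seed(derive_seed(cfg$seed, 4242L), stratified_folds(y, 2L))
    folds <- lapply(1:2, function(f) which(foldid == f))
  } else {
    folds <- as.list(seq_len(n))
  }

  pred <- integer(n)
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    if (!any(y[tr] == 1L) || !any(y[tr] == -1L)) {
      stop("external training fold lost a phenotype class", call. = FALSE)
    }
    gm_tr <- subset_genotypes(gm, samples = tr)
    phen_tr <- phenotype(y[tr], phen$positive_label_name)
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, 5000L + f)
    fit <- run_two_stage(gm_tr, phen_tr, gene_map, cfg_f)
    gm_te <- subset_genotypes(gm, samples = te)
    majority <- if (sum(y[tr] == 1L) >= sum(y[tr] == -1L)) 1L else -1L
    pred[te] <- predict_two_stage(fit, gm_te, fallback = majority)
  }

  m <- metrics(y, pred)
  structure(
    list(mode = if (external == "2fold") "external_2fold" else "external_loo",
         precision = m[["precision"]], recall = m[["recall"]],
         f1 = m[["f1"]], accuracy = m[["accuracy"]], predictions = pred),
    class = "cv_report"
  )
}

#' Training (single-loop) performance of a fitted two-stage model
#'
#' In-sample scores of the final model on the data it was fitted to; upward
#' biased relative to [double_cv()] and reported for the same contrast.
#'
#' @param fit A `two_stage_fit`.
#' @param gm,phen The training data.
#' @return A `cv_report` with `mode = "training"`.
#' @export
training_report <- function(fit, gm, phen) {
  majority <- if (sum(phen$labels == 1L) >= sum(phen$labels == -1L)) 1L else -1L
  pred <- predict_two_stage(fit, gm, fallback = majority)
  m <- metrics(phen$labels, pred)
  structure(
    list(mode = "training", precision = m[["precision"]],
         recall = m[["recall"]], f1 = m[["f1"]], accuracy = m[["accuracy"]],
         predictions = pred),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s: precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$mode, x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Write one or more CV reports as a TSV table
#'
#' @param reports List of `cv_report` objects.
#' @param path Output file.
#' @export
write_cv_tsv <- function(reports, path) {
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(mode = r$mode, precision = r$precision, recall = r$recall,
               f1 = r$f1, accuracy = r$accuracy)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
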