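#' Multi-label evaluation metrics
#'
#' Evaluation of a documents x labels score matrix (and a thresholded
#' binary prediction) against true label sets: Hamming loss, one-error,
#' average precision and three areas under precision-recall curves
#' (pooled over all document-label pairs, macro-averaged per label and
#' frequency-weighted per label).  Ranking ties are always broken by
#' label order, so every metric is deterministic.
#'
#' @name pftp-metrics
NULL

as_truth_matrix <- function(truth, labels, doc_ids = NULL) {
  if (is.matrix(truth)) return(truth == 1L | truth == TRUE)
  if (is.null(doc_ids)) doc_ids <- names(truth)
  m <- matrix(FALSE, length(doc_ids), length(labels),
              dimnames = list(doc_ids, labels))
  for (i in seq_along(doc_ids)) {
    labs <- truth[[doc_ids[i]]]
    unknown <- setdiff(labs, labels)
    if (length(unknown))
      pftp_data_error(sprintf("unknown label(s) in truth: %s",
                              paste(unknown, collapse = ", ")))
    m[i, match(labs, labels)] <- TRUE
  }
  m
}

#' Hamming loss
#'
#' Mean size of the symmetric difference between true and predicted label
#' sets, normalized by `D * L`.
#'
#' @param truth logical documents x labels matrix of true labels.
#' @param predicted logical matrix of the same shape (thresholded scores).
#' @return value in `[0, 1]`.
#' @export
hamming_loss <- function(truth, predicted) {
  truth <- truth == TRUE; predicted <- predicted == TRUE
  if (!all(dim(truth) == dim(predicted)))
    pftp_config_error("truth and prediction dimensions differ")
  if (ncol(truth) == 0L) pftp_config_error("no labels to evaluate")
  mean(truth != predicted)
}

# Documents without any true label cannot be ranked against; they are
# excluded from the ranking metrics with a logged count.
drop_empty_docs <- function(truth, scores, metric) {
  keep <- rowSums(truth) > 0L
  if (!all(keep))
    message(sprintf("%s: excluded %d document(s) with empty true label set",
                    metric, sum(!keep)))
  list(truth = truth[keep, , drop = FALSE],
       scores = scores[keep, , drop = FALSE])
}

#' One-error
#'
#' Fraction of documents whose top-scored label (ties broken by label
#' order) is not a true label.
#'
#' @param truth logical documents x labels matrix.
#' @param scores numeric matrix of the same shape.
#' @return value in `[0, 1]`.
#' @export
one_error <- function(truth, scores) {
  x <- drop_empty_docs(truth == TRUE, scores, "one_error")
  if (nrow(x$truth) == 0L) pftp_config_error("no documents with true labels")
  top <- apply(x$scores, 1L, which.max)  # which.max is first-index on ties
  mean(!x$truth[cbind(seq_len(nrow(x$truth)), top)])
}

#' Average precision (label-ranking)
#'
#' For each document, labels are ranked by descending score (ties by
#' label order); the score of a true label y is the fraction of labels
#' ranked at or above y that are true, and these are averaged over the
#' document's true labels, then over documents.
#'
#' @inheritParams one_error
#' @return value in `[0, 1]`; 1 iff every true label outranks every
#'   false one.
#' @export
average_precision <- function(truth, scores) {
  x <- drop_empty_docs(truth == TRUE, scores, "average_precision")
  if (nrow(x$truth) == 0L) pftp_config_error("no documents with true labels")
  per_doc <- vapply(seq_len(nrow(x$truth)), function(d) {
    s <- x$scores[d, ]; y <- x$truth[d, ]
    ord <- order(-s, seq_along(s))          # descending, ties by label index
    rnk <- match(seq_along(s), ord)         # rank of each label
    ry <- rnk[y]
    mean(vapply(ry, function(r) sum(ry <= r) / r, numeric(1)))
  }, numeric(1))
  mean(per_doc)
}

# Precision-recall curve by a global threshold sweep over the distinct
# scores, area by trapezoid over recall after prepending a recall-0 point
# at the first curve point's precision.
pr_area <- function(pos, s) {
  P <- sum(pos)
  if (P == 0L) pftp_config_error("no positive pairs: PR area undefined")
  ord <- order(-s)
  s <- s[ord]; pos <- pos[ord]
  cum_tp <- cumsum(pos)
  n_pred <- seq_along(s)
  last <- which(c(s[-1L] != s[-length(s)], TRUE))  # last index of each score
  prec <- cum_tp[last] / n_pred[last]
  rec <- cum_tp[last] / P
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  sum(diff(rec) * (utils::head(prec, -1L) + utils::tail(prec, -1L)) / 2)
}

#' Pooled area under the precision-recall curve
#'
#' All document-label pairs are pooled, a global threshold is swept over
#' the distinct scores, and the area is computed by trapezoidal
#' integration over recall (prepending the recall-0 point at the first
#' point's precision).
#'
#' @inheritParams one_error
#' @return area in `[0, 1]`.
#' @export
pr_area_pooled <- function(truth, scores) {
  pr_area(as.vector(truth == TRUE), as.vector(scores))
}

#' Per-label precision-recall areas, macro and weighted means
#'
#' The pooled-curve construction restricted to each label's column.
#' Labels with no positive document have an undefined PR curve; they are
#' excluded from both means and their count is logged.  The weighted mean
#' uses weights `n_l / sum(n_l)` where `n_l` is the number of proteins
#' annotated with label l.
#'
#' @inheritParams one_error
#' @return list with `per_label` (named vector, `NA` for labels without
#'   positives), `macro` and `weighted`.
#' @export
pr_area_per_label <- function(truth, scores) {
  truth <- truth == TRUE
  n_l <- colSums(truth)
  has_pos <- n_l > 0L
  if (!any(has_pos)) pftp_config_error("no label has a positive document")
  if (any(!has_pos))
    message(sprintf("pr_area_per_label: excluded %d label(s) with no positives",
                    sum(!has_pos)))
  per <- rep(NA_real_, ncol(truth))
  names(per) <- colnames(truth)
  for (j in which(has_pos)) per[j] <- pr_area(truth[, j], scores[, j])
  w <- n_l[has_pos] / sum(n_l[has_pos])
  list(per_label = per, macro = mean(per[has_pos]),
       weighted = sum(w * per[has_pos]))
}

#' Full evaluation report
#'
#' Computes all six metrics from a score matrix, true label sets and a
#' binarization threshold (used only by the Hamming loss and recorded in
#' the report).
#'
#' @param truth logical documents x labels matrix, or a named list of
#'   label sets (then `labels` must be supplied).
#' @param scores numeric documents x labels matrix (e.g.
#'   `prediction$scores`), rows aligned with `truth`.
#' @param threshold binarization threshold for the Hamming loss;
#'   `NULL` for the uniform baseline `1/L`.
#' @param labels label ids when `truth` is a list.
#' @return object of class `pftp_eval` with the six metrics plus
#'   settings.
#' @export
evaluate_predictions <- function(truth, scores, threshold = NULL,
                                 labels = colnames(scores)) {
  if (inherits(scores, "pftp_prediction")) scores <- scores$scores
  truth <- as_truth_matrix(truth, labels, rownames(scores))
  if (is.null(threshold)) threshold <- 1 / ncol(scores)
  pred <- binarize_scores(scores, threshold)
  pl <- pr_area_per_label(truth, scores)
  structure(list(hamming_loss = hamming_loss(truth, pred),
                 one_error = one_error(truth, scores),
                 average_precision = average_precision(truth, scores),
                 au_prc_pooled = pr_area_pooled(truth, scores),
                 auprc_macro = pl$macro, auprc_weighted = pl$weighted,
                 threshold = threshold,
                 n_documents = nrow(scores), n_labels = ncol(scores)),
            class = "pftp_eval")
}

#' @export
print.pftp_eval <- function(x, ...) {
  cat("Multi-label evaluation\n")
  for (m in c("hamming_loss", "one_error", "average_precision",
              "au_prc_pooled", "auprc_macro", "auprc_weighted"))
    cat(sprintf("  %-18s %.4f\n", m, x[[m]]))
  cat(sprintf("  (threshold %.4g, %d documents, %d labels)\n",
              x$threshold, x$n_documents, x$n_labels))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report a `pftp_eval`.
#' @param path file path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "pftp_eval"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
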