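#' Predict function labels for new proteins (fold-in)
#'
#' Holds the trained global parameters `pi` and `theta` fixed and
#' resamples only the per-document label assignments: every extended
#' label (all L observed labels plus the background) is admissible for a
#' new protein, and the per-token conditional is proportional to
#' `(beta + N_dl) * pi[l, k] * theta[k, w]`.  The document-label mixture
#' `psi_d` is averaged over the retained samples.
#'
#' @param bow a `pftp_bow` built on the training vocabulary (its blocks
#'   must match the model's; out-of-vocabulary blocks are dropped when
#'   the bag of words is built).
#' @param model a `pftp_model` from [pftp_train()].
#' @param schedule a `pftp_schedule`; defaults to the standard prediction
#'   schedule (1000 sweeps, 500 burn-in, thin 50).
#' @return object of class `pftp_prediction`: `doc_ids`; `scores`, a
#'   documents x L matrix of label probabilities renormalized to exclude
#'   the background; `background`, the raw background mass per document;
#'   `raw`, the documents x (L+1) mixture summing to 1 per row; and
#'   `empty_docs`, ids of documents with no in-vocabulary token (their
#'   scores are the uniform prior and are flagged, not dropped).
#' @export
pftp_predict <- function(bow, model,
                         schedule = sampling_schedule(1000L, 500L, 50L)) {
  stopifnot(inherits(bow, "pftp_bow"), inherits(model, "pftp_model"),
            inherits(schedule, "pftp_schedule"))
  if (!identical(bow$vocabulary$blocks, model$vocabulary$blocks))
    pftp_data_error("corpus vocabulary does not match the model vocabulary")
  p <- model$partition
  L <- p$L
  tok <- bow_tokens(bow)
  D <- nrow(bow$counts)
  # uniform initialization over all admissible (l, k) pairs
  set.seed(schedule$seed)
  cand_l <- rep.int(seq_len(p$Lext), p$sizes)
  cand_k <- unlist(p$subsets)
  pick <- sample.int(length(cand_l), length(tok$doc), replace = TRUE)
  lay <- partition_layout(p)
  res <- pftp_gibbs_predict_cpp(tok$doc - 1L, tok$word - 1L, model$pi,
                                model$theta, lay$start, lay$size, D,
                                p$Lext, model$hyper$beta,
                                cand_l[pick] - 1L, cand_k[pick] - 1L,
                                schedule$iterations, schedule$burn_in,
                                schedule$thin)
  raw <- res$psi_mean
  rownames(raw) <- bow$doc_ids
  colnames(raw) <- c(model$labels[seq_len(L)],
                     if (p$B > 0L) "__background__")
  obs <- raw[, seq_len(L), drop = FALSE]
  scores <- obs / rowSums(obs)
  empty <- bow$doc_ids[bow$doc_totals == 0L]
  structure(list(doc_ids = bow$doc_ids, scores = scores,
                 background = if (p$B > 0L) raw[, L + 1L] else
                   setNames(rep(0, D), bow$doc_ids),
                 raw = raw, empty_docs = empty, schedule = schedule),
            class = "pftp_prediction")
}

#' @export
print.pftp_prediction <- function(x, ...) {
  cat(sprintf("Predictions for %d proteins over %d labels\n",
              length(x$doc_ids), ncol(x$scores)))
  if (length(x$empty_docs))
    cat(sprintf("  (%d empty documents scored with the uniform prior)\n",
                length(x$empty_docs)))
  invisible(x)
}

#' Threshold prediction scores into binary label sets
#'
#' A label is predicted when its renormalized score is greater than or
#' equal to `threshold`; ties at the threshold are included.  The default
#' threshold is the uniform baseline `1/L`.
#'
#' @param prediction a `pftp_prediction` or a numeric score matrix.
#' @param threshold value in `[0, 1]`, or `NULL` for `1/L`.
#' @return logical documents x labels matrix.
#' @export
binarize_scores <- function(prediction, threshold = NULL) {
  scores <- if (inherits(prediction, "pftp_prediction"))
    prediction$scores else as.matrix(prediction)
  if (is.null(threshold)) threshold <- 1 / ncol(scores)
  if (threshold < 0 || threshold > 1)
    pftp_config_error("threshold must lie in [0, 1]")
  scores >= threshold
}

#' Write / read a prediction score matrix as TSV
#'
#' One row per protein: `protein_id`, one column per label (renormalized
#' probabilities) and a final `__background__` column with the raw
#' background mass.
#'
#' @param prediction a `pftp_prediction`.
#' @param path file path.
#' @return `read_scores()` returns a list with `scores` (matrix) and
#'   `background` (vector).
#' @export
write_scores <- function(prediction, path) {
  stopifnot(inherits(prediction, "pftp_prediction"))
  df <- data.frame(protein_id = prediction$doc_ids,
                   prediction$scores, check.names = FALSE)
  df[["__background__"]] <- unname(prediction$background)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) pftp_data_error(paste("no such file:", path))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  ids <- df$protein_id
  num <- df[, setdiff(colnames(df), "protein_id"), drop = FALSE]
  m <- apply(num, 2L, as.numeric)
  m <- matrix(m, nrow = length(ids),
              dimnames = list(ids, colnames(num)))
  bg <- if ("__background__" %in% colnames(m)) m[, "__background__"] else
    setNames(rep(0, length(ids)), ids)
  list(scores = m[, setdiff(colnames(m), "__background__"), drop = FALSE],
       background = bg)
}
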