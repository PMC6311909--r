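#' Gibbs sampler state
#'
#' A `pftp_state` holds the per-token (label, topic) assignments of a
#' corpus together with the sufficient-count statistics the collapsed
#' sampler maintains incrementally: `N_dl` (document x label), `N_lk`
#' (label x topic), `N_kw` (topic x word) and the totals `N_d`, `N_l`,
#' `N_k`.  Tokens are stored document-major, words within a document in
#' vocabulary order (the bag-of-words is exchangeable, so this fixed
#' order is just a reproducibility convention).
#'
#' @name pftp_state
NULL

bow_tokens <- function(bow) {
  D <- nrow(bow$counts)
  per_doc <- lapply(seq_len(D), function(d) {
    row <- bow$counts[d, ]
    rep.int(seq_along(row), row)
  })
  list(doc = rep.int(seq_len(D), vapply(per_doc, length, integer(1))),
       word = unlist(per_doc, use.names = FALSE))
}

active_labels <- function(label_matrix) {
  lapply(seq_len(nrow(label_matrix)), function(d)
    which(label_matrix[d, ] == 1L))
}

new_state <- function(doc, word, l, z, D, bow, label_matrix, partition) {
  st <- list(doc = as.integer(doc), word = as.integer(word),
             l = as.integer(l), z = as.integer(z), D = as.integer(D),
             W = bow$vocabulary$size, K = partition$K,
             Lext = partition$Lext, bow = bow,
             label_matrix = label_matrix, partition = partition,
             active = active_labels(label_matrix))
  st <- c(st, recount_tokens(st))
  class(st) <- "pftp_state"
  st
}

recount_tokens <- function(st) {
  N_dl <- matrix(0L, st$D, st$Lext)
  N_lk <- matrix(0L, st$Lext, st$K)
  N_kw <- matrix(0L, st$K, st$W)
  if (length(st$doc)) {
    tab <- function(i, j, ni, nj) {
      m <- matrix(0L, ni, nj)
      t3 <- table(factor(i, levels = seq_len(ni)), factor(j, levels = seq_len(nj)))
      m[] <- as.integer(t3)
      m
    }
    N_dl <- tab(st$doc, st$l, st$D, st$Lext)
    N_lk <- tab(st$l, st$z, st$Lext, st$K)
    N_kw <- tab(st$z, st$word, st$K, st$W)
  }
  list(N_dl = N_dl, N_lk = N_lk, N_kw = N_kw,
       N_d = as.integer(rowSums(N_dl)), N_l = as.integer(rowSums(N_lk)),
       N_k = as.integer(rowSums(N_kw)))
}

#' Recount sufficient statistics from the token table
#'
#' Recomputes all count matrices from the raw (label, topic) assignments;
#' used to validate the incrementally maintained counts.
#'
#' @param state a `pftp_state`.
#' @return list with `N_dl`, `N_lk`, `N_kw`, `N_d`, `N_l`, `N_k`.
#' @export
recount <- function(state) {
  stopifnot(inherits(state, "pftp_state"))
  recount_tokens(state)
}

#' Check all state invariants
#'
#' Verifies assignment admissibility (every token label is active in its
#' document, every topic lies in its label's subset), count marginals and
#' agreement of the live counts with a fresh recount.
#'
#' @param state a `pftp_state`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "pftp_state"))
  for (n in seq_along(state$doc)) {
    d <- state$doc[n]
    if (!(state$l[n] %in% state$active[[d]]))
      pftp_internal_error(sprintf("token %d: label %d not active in doc %d",
                                  n, state$l[n], d))
    if (!(state$z[n] %in% state$partition$subsets[[state$l[n]]]))
      pftp_internal_error(sprintf("token %d: topic %d outside subset of label %d",
                                  n, state$z[n], state$l[n]))
  }
  rc <- recount_tokens(state)
  for (nm in names(rc))
    if (!identical(unname(rc[[nm]]), unname(state[[nm]])))
      pftp_internal_error(paste("count statistic out of sync:", nm))
  if (sum(state$N_d) != length(state$doc) ||
      sum(state$N_l) != length(state$doc) ||
      sum(state$N_k) != length(state$doc))
    pftp_internal_error("token totals inconsistent")
  invisible(TRUE)
}

#' Initialize a sampler state
#'
#' Each token receives a label drawn uniformly from its document's active
#' extended labels and a topic drawn uniformly from that label's subset.
#'
#' @param bow a `pftp_bow`.
#' @param label_matrix binary matrix from [build_label_matrix()].
#' @param partition a `pftp_partition`.
#' @param seed integer seed (the initialization is reproducible).
#' @return a `pftp_state`.
#' @export
init_state <- function(bow, label_matrix, partition, seed = 1L) {
  stopifnot(inherits(bow, "pftp_bow"), inherits(partition, "pftp_partition"))
  if (nrow(label_matrix) != nrow(bow$counts) ||
      ncol(label_matrix) != partition$Lext)
    pftp_config_error("label matrix dimensions do not match corpus/partition")
  act <- active_labels(label_matrix)
  if (any(vapply(act, length, integer(1)) == 0L))
    pftp_data_error("document with no active label")
  tok <- bow_tokens(bow)
  set.seed(seed)
  l <- integer(length(tok$doc)); z <- integer(length(tok$doc))
  for (n in seq_along(tok$doc)) {
    cand <- act[[tok$doc[n]]]
    l[n] <- cand[sample.int(length(cand), 1L)]
    sub <- partition$subsets[[l[n]]]
    z[n] <- sub[sample.int(length(sub), 1L)]
  }
  new_state(tok$doc, tok$word, l, z, nrow(bow$counts), bow, label_matrix,
            partition)
}

#' Build a state from explicit token assignments
#'
#' Useful for loading simulated ground-truth assignments, which must then
#' satisfy every state invariant.
#'
#' @inheritParams init_state
#' @param l,z integer vectors of 1-based (label, topic) assignments in the
#'   document-major token order of the corpus.
#' @return a `pftp_state`.
#' @export
state_from_assignments <- function(bow, label_matrix, partition, l, z) {
  tok <- bow_tokens(bow)
  if (length(l) != length(tok$doc) || length(z) != length(tok$doc))
    pftp_config_error("assignment length does not match token count")
  st <- new_state(tok$doc, tok$word, l, z, nrow(bow$counts), bow,
                  label_matrix, partition)
  validate_state(st)
  st
}

#' @export
print.pftp_state <- function(x, ...) {
  cat(sprintf("Gibbs state: %d tokens, %d docs, K = %d, W = %d\n",
              length(x$doc), x$D, x$K, x$W))
  invisible(x)
}
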