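#' The 20-letter amino-acid alphabet
#'
#' Residue letters considered valid by default when tokenizing protein
#' sequences into amino-acid blocks.
#' @export
AA_ALPHABET <- c("G", "A", "V", "L", "I", "F", "P", "Y", "S", "C",
                 "M", "N", "Q", "T", "D", "E", "K", "R", "H", "W")

#' Tokenize a protein sequence into amino-acid blocks
#'
#' Slides a window of length `k` (stride `step`) along the sequence and
#' returns the overlapping blocks (k-mers), the "words" of the topic model.
#' Sequences are upper-cased first; blocks containing letters outside
#' `alphabet` are dropped (set `alphabet = NULL` to keep any letter).
#' With `mixed_lengths = TRUE` all block lengths `1..k` are emitted
#' (shortest first), covering vocabularies that mix word lengths.
#'
#' @param sequence single character string of residue letters.
#' @param k block length (>= 1).
#' @param step window stride (>= 1).
#' @param alphabet allowed residue letters, or `NULL` to keep all letters.
#' @param mixed_lengths emit all lengths `1..k` instead of only `k`.
#' @return character vector of blocks, in sequence order; empty when the
#'   sequence is shorter than `k`.
#' @examples
#' tokenize_sequence("ACDEF", k = 2)          # "AC" "CD" "DE" "EF"
#' tokenize_sequence("MSMS", k = 2)           # "MS" "SM" "MS"
#' @export
tokenize_sequence <- function(sequence, k = 2L, step = 1L,
                              alphabet = AA_ALPHABET,
                              mixed_lengths = FALSE) {
  if (length(sequence) != 1L || !is.character(sequence))
    pftp_config_error("'sequence' must be a single character string")
  if (k < 1L) pftp_config_error("block length 'k' must be >= 1")
  if (step < 1L) pftp_config_error("'step' must be >= 1")
  bad <- regexpr("[^A-Za-z]", sequence)
  if (bad > 0L)
    pftp_data_error(sprintf(
      "non-letter character '%s' at position %d in sequence",
      substr(sequence, bad, bad), bad))
  s <- toupper(sequence)
  n <- nchar(s)
  lengths <- if (mixed_lengths) seq_len(k) else k
  out <- character(0)
  for (len in lengths) {
    if (n < len) next
    starts <- seq.int(1L, n - len + 1L, by = step)
    out <- c(out, substring(s, starts, starts + len - 1L))
  }
  if (!is.null(alphabet) && length(out)) {
    ok <- !grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), out)
    out <- out[ok]
  }
  out
}

#' Tokenize a set of protein sequences
#'
#' @param sequences named character vector (names are protein ids).
#' @inheritParams tokenize_sequence
#' @return named list of block vectors, one per protein.
#' @export
tokenize_proteins <- function(sequences, k = 2L, step = 1L,
                              alphabet = AA_ALPHABET,
                              mixed_lengths = FALSE) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    pftp_data_error("'sequences' must be a named character vector")
  lapply(setNames(as.list(sequences), names(sequences)), tokenize_sequence,
         k = k, step = step, alphabet = alphabet,
         mixed_lengths = mixed_lengths)
}

#' Build the block vocabulary
#'
#' Collects the distinct blocks of a tokenized corpus, drops blocks seen
#' fewer than `min_count` times in total, and fixes a deterministic
#' (lexicographic) ordering, i.e. the vocabulary space of the model.
#'
#' @param tokenized named list of block vectors (see [tokenize_proteins()]).
#' @param min_count minimum total corpus count for a block to be kept.
#' @return object of class `pftp_vocab` with elements `blocks` (ordered
#'   character vector) and `size`.
#' @export
build_vocabulary <- function(tokenized, min_count = 1L) {
  if (min_count < 1L) pftp_config_error("'min_count' must be >= 1")
  all_blocks <- unlist(tokenized, use.names = FALSE)
  if (!length(all_blocks))
    pftp_config_error("no tokens: cannot build a vocabulary")
  tab <- table(all_blocks)
  keep <- sort(names(tab)[tab >= min_count])
  if (!length(keep))
    pftp_config_error(sprintf(
      "no block reaches min_count = %d; vocabulary would be empty", min_count))
  structure(list(blocks = keep, size = length(keep)), class = "pftp_vocab")
}

#' @export
print.pftp_vocab <- function(x, ...) {
  cat(sprintf("Block vocabulary: W = %d (e.g. %s)\n", x$size,
              paste(utils::head(x$blocks, 5L), collapse = ", ")))
  invisible(x)
}

#' Build the bag-of-words corpus
#'
#' Counts block occurrences per protein over a fixed vocabulary; blocks
#' absent from the vocabulary are skipped.
#'
#' @param tokenized named list of block vectors.
#' @param vocab a `pftp_vocab`.
#' @return object of class `pftp_bow`: `vocabulary`, `doc_ids`, integer
#'   `counts` matrix (documents x blocks) and `doc_totals` (row sums).
#' @export
build_bow <- function(tokenized, vocab) {
  stopifnot(inherits(vocab, "pftp_vocab"))
  ids <- names(tokenized)
  if (anyDuplicated(ids))
    pftp_data_error(sprintf("duplicate protein id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  W <- vocab$size
  counts <- matrix(0L, nrow = length(ids), ncol = W,
                   dimnames = list(ids, vocab$blocks))
  for (i in seq_along(tokenized)) {
    idx <- match(tokenized[[i]], vocab$blocks)
    idx <- idx[!is.na(idx)]
    if (length(idx)) counts[i, ] <- tabulate(idx, nbins = W)
  }
  new_bow(vocab, ids, counts)
}

new_bow <- function(vocab, doc_ids, counts) {
  structure(list(vocabulary = vocab, doc_ids = doc_ids, counts = counts,
                 doc_totals = as.integer(rowSums(counts))),
            class = "pftp_bow")
}

#' @export
print.pftp_bow <- function(x, ...) {
  cat(sprintf("Bag-of-words corpus: %d proteins, W = %d, %d tokens\n",
              length(x$doc_ids), x$vocabulary$size, sum(x$doc_totals)))
  invisible(x)
}

#' Write / read a bag-of-words corpus as plain text
#'
#' The corpus is stored as a sparse triplet TSV (`doc_id`, `block`,
#' `count`; one row per non-zero cell, and a single `doc_id . 0` row for a
#' document with no in-vocabulary tokens) plus a vocabulary file with one
#' block per line, so tokenization and training are decoupled.
#'
#' @param bow a `pftp_bow`.
#' @param counts_path,vocab_path output/input file paths.
#' @return `read_bow()` returns a `pftp_bow`; `write_bow()` returns the
#'   paths invisibly.
#' @export
write_bow <- function(bow, counts_path, vocab_path) {
  stopifnot(inherits(bow, "pftp_bow"))
  nz <- which(bow$counts > 0L, arr.ind = TRUE)
  df <- data.frame(doc_id = rownames(bow$counts)[nz[, 1L]],
                   block = colnames(bow$counts)[nz[, 2L]],
                   count = bow$counts[nz], stringsAsFactors = FALSE)
  empty <- setdiff(bow$doc_ids, unique(df$doc_id))
  if (length(empty))
    df <- rbind(df, data.frame(doc_id = empty, block = ".", count = 0L))
  df <- df[order(match(df$doc_id, bow$doc_ids), df$block), , drop = FALSE]
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bow$vocabulary$blocks, vocab_path)
  invisible(c(counts_path, vocab_path))
}

#' @rdname write_bow
#' @export
read_bow <- function(counts_path, vocab_path) {
  if (!file.exists(counts_path)) pftp_data_error(paste("no such file:", counts_path))
  if (!file.exists(vocab_path)) pftp_data_error(paste("no such file:", vocab_path))
  blocks <- readLines(vocab_path)
  blocks <- blocks[nzchar(blocks)]
  if (anyDuplicated(blocks)) pftp_data_error("duplicate blocks in vocabulary file")
  vocab <- structure(list(blocks = blocks, size = length(blocks)),
                     class = "pftp_vocab")
  df <- read.table(counts_path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer"))
  ids <- unique(df$doc_id)
  real <- df[df$block != ".", , drop = FALSE]
  bad <- setdiff(unique(real$block), blocks)
  if (length(bad))
    pftp_data_error(sprintf("blocks not in vocabulary: %s",
                            paste(utils::head(bad, 5L), collapse = ", ")))
  counts <- matrix(0L, nrow = length(ids), ncol = length(blocks),
                   dimnames = list(ids, blocks))
  if (nrow(real))
    counts[cbind(match(real$doc_id, ids), match(real$block, blocks))] <-
      as.integer(real$count)
  new_bow(vocab, ids, counts)
}
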