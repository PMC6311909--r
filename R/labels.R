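#' Read protein sequences from a FASTA file
#'
#' The record id is the first whitespace-delimited token of the header;
#' wrapped sequence lines are concatenated and `*` stop characters are
#' stripped.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) pftp_data_error(paste("no such file:", path))
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) pftp_data_error(
                     paste("cannot parse FASTA:", conditionMessage(e))))
  if (length(seqs) == 0L) pftp_data_error(paste("empty FASTA file:", path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    pftp_data_error(sprintf("duplicate FASTA id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  out <- gsub("*", "", as.character(seqs), fixed = TRUE)
  names(out) <- ids
  out
}

#' Define the function-label space
#'
#' Fixes the ordered universe of the L observed function labels (GO terms)
#' and, optionally, the latent background label appended as label L+1.
#'
#' @param labels character vector of unique label identifiers.
#' @param background whether the latent background label is enabled.
#' @return object of class `pftp_label_space`.
#' @export
label_space <- function(labels, background = TRUE) {
  labels <- as.character(labels)
  if (!length(labels)) pftp_config_error("label space is empty")
  if (anyDuplicated(labels))
    pftp_data_error(sprintf("duplicate label(s): %s",
                            paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  structure(list(labels = labels, L = length(labels),
                 background = isTRUE(background)),
            class = "pftp_label_space")
}

#' Read a label universe file (one label per line; defines label order)
#' @param path file path.
#' @param background passed to [label_space()].
#' @return a `pftp_label_space`.
#' @export
read_label_universe <- function(path, background = TRUE) {
  if (!file.exists(path)) pftp_data_error(paste("no such file:", path))
  lab <- readLines(path)
  lab <- trimws(lab)
  label_space(lab[nzchar(lab)], background = background)
}

#' Read per-protein annotations from a two-column TSV
#'
#' Each line is `protein_id<TAB>label1,label2,...`; labels are
#' deduplicated per protein and must all belong to `space`.
#'
#' @param path TSV file path.
#' @param space a `pftp_label_space`.
#' @return named list mapping protein id to a character vector of labels.
#' @export
read_labels_tsv <- function(path, space) {
  stopifnot(inherits(space, "pftp_label_space"))
  if (!file.exists(path)) pftp_data_error(paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(trimws(parts[2L])))
      pftp_data_error(sprintf("malformed annotation line %d: %s", i, lines[i]))
    id <- parts[1L]
    if (!is.null(out[[id]]))
      pftp_data_error(sprintf("duplicate protein id at line %d: %s", i, id))
    labs <- unique(trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]]))
    labs <- labs[nzchar(labs)]
    if (!length(labs))
      pftp_data_error(sprintf("blank label field at line %d", i))
    unknown <- setdiff(labs, space$labels)
    if (length(unknown))
      pftp_data_error(sprintf("unknown label(s) at line %d: %s", i,
                              paste(unknown, collapse = ", ")))
    out[[id]] <- labs
  }
  out
}

#' Build the binary document-label matrix
#'
#' One row per protein over the extended label space: the L observed
#' labels plus (when the background is enabled) a final background column
#' that is identically 1, encoding that the latent background label is
#' active in every document.  In `mode = "predict"` every label is marked
#' admissible regardless of annotations (fold-in frees the constraint).
#'
#' @param annotations named list protein id -> label ids (may be `NULL`
#'   in predict mode, in which case `doc_ids` must be given).
#' @param space a `pftp_label_space`.
#' @param mode `"train"` (rows follow annotations) or `"predict"`
#'   (all-ones rows).
#' @param doc_ids document ids for predict mode without annotations.
#' @param allow_unlabeled in training, accept proteins with no observed
#'   label as background-only rows (with a warning) instead of erroring.
#' @return integer 0/1 matrix, rows = proteins, columns = labels
#'   (background column named `"__background__"`).
#' @export
build_label_matrix <- function(annotations, space,
                               mode = c("train", "predict"),
                               doc_ids = NULL, allow_unlabeled = FALSE) {
  stopifnot(inherits(space, "pftp_label_space"))
  mode <- match.arg(mode)
  if (is.null(doc_ids)) doc_ids <- names(annotations)
  if (!length(doc_ids)) pftp_config_error("no documents")
  Lext <- space$L + as.integer(space$background)
  cols <- c(space$labels, if (space$background) "__background__")
  m <- matrix(0L, nrow = length(doc_ids), ncol = Lext,
              dimnames = list(doc_ids, cols))
  if (mode == "predict") {
    m[] <- 1L
    return(m)
  }
  for (i in seq_along(doc_ids)) {
    labs <- annotations[[doc_ids[i]]]
    unknown <- setdiff(labs, space$labels)
    if (length(unknown))
      pftp_data_error(sprintf("unknown label(s) for %s: %s", doc_ids[i],
                              paste(unknown, collapse = ", ")))
    if (!length(labs)) {
      if (!allow_unlabeled)
        pftp_data_error(sprintf(
          "protein %s has no observed label (training is supervised; see allow_unlabeled)",
          doc_ids[i]))
      warning(sprintf("protein %s has no observed label; background-only row",
                      doc_ids[i]), call. = FALSE)
    } else {
      m[i, match(labs, space$labels)] <- 1L
    }
  }
  if (space$background) m[, Lext] <- 1L
  if (!space$background && any(rowSums(m) == 0L))
    pftp_data_error("document with no admissible label and no background")
  m
}
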