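#' Save / load a trained model bundle
#'
#' A model bundle is a directory holding `metadata.json` (hyperparameters,
#' schedule, partition, labels and an md5 of the vocabulary file),
#' `vocabulary.txt` (one block per line) and the `pi`/`theta` matrices as
#' tab-separated text written with 17 significant digits, so the
#' write-read round trip is lossless to full double precision.
#'
#' @param model a `pftp_model`.
#' @param dir bundle directory (created if needed).
#' @return `read_model()` returns a `pftp_model`; `write_model()` the
#'   directory, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "pftp_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vocab_path <- file.path(dir, "vocabulary.txt")
  writeLines(model$vocabulary$blocks, vocab_path)
  write_matrix_txt(model$pi, file.path(dir, "pi.tsv"))
  write_matrix_txt(model$theta, file.path(dir, "theta.tsv"))
  if (!is.null(model$psi_train))
    write_matrix_txt(model$psi_train, file.path(dir, "psi_train.tsv"))
  p <- model$partition
  meta <- list(hyperparameters = unclass(model$hyper),
               schedule = if (!is.null(model$schedule))
                 unclass(model$schedule),
               partition = list(L = p$L, topics_per_label = p$m,
                                background_topics = p$B, K = p$K),
               labels = model$labels,
               vocabulary_md5 = unname(tools::md5sum(vocab_path)),
               vocabulary_size = model$vocabulary$size)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_matrix_txt <- function(m, path) {
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
}

read_matrix_txt <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    pftp_data_error(paste("not a model bundle (no metadata.json):", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  vocab_path <- file.path(dir, "vocabulary.txt")
  md5 <- unname(tools::md5sum(vocab_path))
  if (!identical(md5, meta$vocabulary_md5))
    pftp_data_error("vocabulary file does not match the recorded md5")
  blocks <- readLines(vocab_path)
  vocab <- structure(list(blocks = blocks, size = length(blocks)),
                     class = "pftp_vocab")
  p <- make_partition(meta$partition$L, meta$partition$topics_per_label,
                      meta$partition$background_topics)
  hyper <- pftp_hyperparameters(meta$hyperparameters$alpha,
                                meta$hyperparameters$beta,
                                meta$hyperparameters$lambda)
  psi <- if (file.exists(file.path(dir, "psi_train.tsv")))
    read_matrix_txt(file.path(dir, "psi_train.tsv"))
  schedule <- if (!is.null(meta$schedule))
    sampling_schedule(meta$schedule$iterations, meta$schedule$burn_in,
                      meta$schedule$thin, meta$schedule$chains,
                      meta$schedule$seed)
  new_model(read_matrix_txt(file.path(dir, "pi.tsv")),
            read_matrix_txt(file.path(dir, "theta.tsv")),
            psi, p, hyper, labels = meta$labels, vocabulary = vocab,
            schedule = schedule)
}
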