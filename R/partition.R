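#' Partition the global topic space among labels
#'
#' Splits the K global topics into disjoint contiguous blocks: the B
#' background topics come first (indices `1..B`), then each of the L
#' observed labels receives `topics_per_label` consecutive topics, so
#' `K = m*L + B`.  With `background_topics = 0` the background label is
#' disabled and the model degenerates (at `m = 1`) to Labeled-LDA.
#'
#' @param L number of observed labels.
#' @param topics_per_label m, topics owned by each observed label (>= 1).
#' @param background_topics B, size of the background subset (0 disables).
#' @return object of class `pftp_partition`: `K`, `L`, `m`, `B`, `Lext`
#'   (number of extended labels), `subsets` (list of 1-based topic index
#'   vectors per extended label, background last), `sizes`.
#' @examples
#' p <- make_partition(319, 3, 1)   # K = 958, background topic is 1
#' p$subsets[[288]]                 # 863 864 865
#' @export
make_partition <- function(L, topics_per_label, background_topics = 1L) {
  L <- as.integer(L); m <- as.integer(topics_per_label)
  B <- as.integer(background_topics)
  if (is.na(L) || L < 1L) pftp_config_error("L must be >= 1")
  if (is.na(m) || m < 1L) pftp_config_error("topics_per_label must be >= 1")
  if (is.na(B) || B < 0L) pftp_config_error("background_topics must be >= 0")
  K <- m * L + B
  subsets <- lapply(seq_len(L), function(l) B + (l - 1L) * m + seq_len(m))
  if (B > 0L) subsets <- c(subsets, list(seq_len(B)))
  Lext <- L + as.integer(B > 0L)
  structure(list(K = K, L = L, m = m, B = B, Lext = Lext,
                 subsets = subsets,
                 sizes = vapply(subsets, length, integer(1))),
            class = "pftp_partition")
}

#' @export
print.pftp_partition <- function(x, ...) {
  cat(sprintf("Topic partition: K = %d (%d labels x %d topics + %d background)\n",
              x$K, x$L, x$m, x$B))
  invisible(x)
}

validate_partition <- function(partition) {
  all_idx <- sort(unlist(partition$subsets))
  if (!identical(all_idx, seq_len(partition$K)))
    pftp_internal_error("topic subsets do not partition 1..K")
  invisible(TRUE)
}

# 0-based contiguous layout handed to the C++ sampler.
partition_layout <- function(partition) {
  starts <- vapply(partition$subsets, function(s) s[1L] - 1L, integer(1))
  list(start = starts, size = partition$sizes)
}

#' Serialize / read a topic partition as JSON
#'
#' The JSON maps each label id to its 1-based topic indices plus a
#' `"background"` entry; subsets must be contiguous index blocks.
#'
#' @param partition a `pftp_partition`.
#' @param labels character vector of the L observed label ids.
#' @param path file path.
#' @return `read_partition()` returns a list with elements `partition`
#'   and `labels`.
#' @export
write_partition <- function(partition, labels, path) {
  stopifnot(inherits(partition, "pftp_partition"),
            length(labels) == partition$L)
  obs <- setNames(partition$subsets[seq_len(partition$L)], labels)
  out <- c(obs, list(background = if (partition$B > 0L)
    partition$subsets[[partition$Lext]] else integer(0)))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) pftp_data_error(paste("no such file:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!"background" %in% names(obj))
    pftp_data_error("partition JSON lacks a 'background' entry")
  labels <- setdiff(names(obj), "background")
  sizes <- vapply(obj[labels], length, integer(1))
  if (length(unique(sizes)) != 1L)
    pftp_data_error("uneven per-label subset sizes are not supported")
  B <- length(obj$background)
  p <- make_partition(length(labels), sizes[1L], B)
  got <- c(lapply(obj[labels], as.integer),
           if (B > 0L) list(as.integer(obj$background)))
  if (!identical(unname(got), unname(p$subsets)))
    pftp_data_error("partition JSON is not in the contiguous background-first layout")
  list(partition = p, labels = labels)
}

#' Model hyperparameters
#'
#' Symmetric Dirichlet concentrations: `alpha` (label -> topic), `beta`
#' (document -> label) and `lambda` (topic -> word).  `"auto"` resolves
#' the standard heuristics `alpha = 50/K` and `lambda = 200/W`.
#'
#' @param alpha numeric > 0 or `"auto"` (requires `K`).
#' @param beta numeric > 0; the document-label concentration.
#' @param lambda numeric > 0 or `"auto"` (requires `W`).
#' @param K,W topic-space and vocabulary sizes, needed for `"auto"`.
#' @return object of class `pftp_hyper` (list `alpha`, `beta`, `lambda`).
#' @export
pftp_hyperparameters <- function(alpha = "auto", beta = 0.01,
                                 lambda = "auto", K = NULL, W = NULL) {
  if (identical(alpha, "auto")) {
    if (is.null(K)) pftp_config_error("alpha = 'auto' requires K")
    alpha <- 50 / K
  }
  if (identical(lambda, "auto")) {
    if (is.null(W)) pftp_config_error("lambda = 'auto' requires W")
    lambda <- 200 / W
  }
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  lambda <- as.numeric(lambda)
  if (anyNA(c(alpha, beta, lambda)) || alpha <= 0 || beta <= 0 || lambda <= 0)
    pftp_config_error("hyperparameters must be strictly positive")
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "pftp_hyper")
}

#' Gibbs sampling schedule
#'
#' @param iterations total sweeps.
#' @param burn_in sweeps discarded before retaining samples
#'   (`burn_in < iterations`).
#' @param thin sweep interval between retained samples.
#' @param chains number of independent chains (reported separately, never
#'   averaged across chains).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `pftp_schedule`; `n_retained` gives
#'   `floor((iterations - burn_in) / thin)`.
#' @export
sampling_schedule <- function(iterations = 2000L, burn_in = 1000L,
                              thin = 50L, chains = 1L, seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin); chains <- as.integer(chains)
  if (thin < 1L) pftp_config_error("thin must be >= 1")
  if (burn_in < 0L || burn_in >= iterations)
    pftp_config_error("burn_in must satisfy 0 <= burn_in < iterations")
  if (chains < 1L) pftp_config_error("chains must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = chains, seed = as.integer(seed),
                 n_retained = (iterations - burn_in) %/% thin),
            class = "pftp_schedule")
}
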