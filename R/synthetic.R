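#' Simulate from the generative process
#'
#' The simulator draws a ground-truth model and labeled corpora from the
#' model's own generative story: per extended label a topic mixture
#' `pi_l ~ Dirichlet(alpha)` on its subset, per topic a word distribution
#' `theta_k ~ Dirichlet(lambda)` on the vocabulary, and per document a
#' label mixture `psi_d ~ Dirichlet(beta)` over its active labels,
#' followed by token-wise draws `l ~ psi_d`, `z ~ pi_l`, `w ~ theta_z`.
#' It targets the model's assumptions, not real proteome k-mer
#' statistics, and exports every ground truth for recovery experiments.
#'
#' @name pftp-synthetic
NULL

rdirichlet1 <- function(n_dim, conc) {
  g <- rgamma(n_dim, shape = conc, rate = 1)
  if (sum(g) == 0) g[sample.int(n_dim, 1L)] <- 1  # numeric underflow guard
  g / sum(g)
}

# Deterministic synthetic vocabulary: the first W k-mers (lexicographic)
# over the 20-letter alphabet, with k chosen just large enough.
synthetic_vocabulary <- function(W) {
  k <- 1L
  while (20^k < W) k <- k + 1L
  blocks <- AA_ALPHABET
  while (k > 1L) {
    blocks <- as.vector(outer(sort(AA_ALPHABET), sort(blocks), paste0))
    k <- k - 1L
  }
  blocks <- sort(blocks)[seq_len(W)]
  structure(list(blocks = blocks, size = W), class = "pftp_vocab")
}

#' Draw a ground-truth model
#'
#' @param L number of observed labels.
#' @param m topics per observed label.
#' @param B background topics (0 disables the background label).
#' @param W vocabulary size.
#' @param hyper a `pftp_hyper`; its `alpha`/`lambda` are the generative
#'   Dirichlet concentrations.
#' @param seed integer seed.
#' @param labels optional label ids (default `"L1"..."LL"`).
#' @return a `pftp_model` whose `pi`/`theta` are the true parameters.
#' @export
sample_model <- function(L, m, B, W,
                         hyper = pftp_hyperparameters(0.5, 0.5, 0.1),
                         seed = 1L, labels = paste0("L", seq_len(L))) {
  partition <- make_partition(L, m, B)
  set.seed(seed)
  pi <- matrix(0, partition$Lext, partition$K)
  for (l in seq_len(partition$Lext)) {
    sub <- partition$subsets[[l]]
    pi[l, sub] <- rdirichlet1(length(sub), hyper$alpha)
  }
  theta <- t(vapply(seq_len(partition$K),
                    function(k) rdirichlet1(W, hyper$lambda), numeric(W)))
  new_model(pi, theta, psi_train = NULL, partition = partition,
            hyper = hyper,
            labels = c(labels, if (B > 0L) "__background__"),
            vocabulary = synthetic_vocabulary(W))
}

#' Simulate a labeled corpus from a ground-truth model
#'
#' @param model a `pftp_model` holding true `pi`/`theta` (see
#'   [sample_model()]).
#' @param D number of documents.
#' @param labels_per_doc observed labels per document under the
#'   `"fixed"` scheme.
#' @param tokens_per_doc tokens per document (mean under `"poisson"`).
#' @param label_scheme `"fixed"` (uniform choice of `labels_per_doc`
#'   distinct labels) or `"bernoulli"` (each label on with probability
#'   `label_prob`, redrawn until at least one is on).
#' @param label_prob Bernoulli probability for `label_scheme = "bernoulli"`.
#' @param tokens_scheme `"fixed"` or `"poisson"`.
#' @param seed integer seed (fixed seed gives a bit-identical corpus).
#' @param doc_prefix document id prefix.
#' @return object of class `pftp_synthetic`: `bow`, `label_matrix`,
#'   `annotations`, true `psi` (documents x extended labels), true token
#'   assignments `l`, `z` (document-major order) and the generating
#'   `model`.
#' @export
sample_corpus <- function(model, D, labels_per_doc = 2L,
                          tokens_per_doc = 120L,
                          label_scheme = c("fixed", "bernoulli"),
                          label_prob = 0.3,
                          tokens_scheme = c("fixed", "poisson"),
                          seed = 1L, doc_prefix = "doc") {
  stopifnot(inherits(model, "pftp_model"))
  label_scheme <- match.arg(label_scheme)
  tokens_scheme <- match.arg(tokens_scheme)
  p <- model$partition
  L <- p$L
  if (label_scheme == "fixed" && (labels_per_doc < 1L || labels_per_doc > L))
    pftp_config_error("labels_per_doc must be in 1..L")
  set.seed(seed)
  doc_ids <- sprintf("%s%04d", doc_prefix, seq_len(D))
  lab_mat <- matrix(0L, D, p$Lext,
                    dimnames = list(doc_ids, model$labels))
  psi <- matrix(0, D, p$Lext, dimnames = list(doc_ids, model$labels))
  n_tok <- if (tokens_scheme == "fixed") rep.int(as.integer(tokens_per_doc), D)
           else rpois(D, tokens_per_doc)
  l_all <- vector("list", D); z_all <- vector("list", D)
  counts <- matrix(0L, D, model$vocabulary$size,
                   dimnames = list(doc_ids, model$vocabulary$blocks))
  beta <- model$hyper$beta
  for (d in seq_len(D)) {
    obs <- if (label_scheme == "fixed") {
      sample.int(L, labels_per_doc)
    } else {
      repeat {
        on <- which(runif(L) < label_prob)
        if (length(on)) break
      }
      on
    }
    lab_mat[d, obs] <- 1L
    if (p$B > 0L) lab_mat[d, p$Lext] <- 1L
    act <- which(lab_mat[d, ] == 1L)
    psi[d, act] <- rdirichlet1(length(act), beta)
    n <- n_tok[d]
    if (n > 0L) {
      l <- act[sample.int(length(act), n, replace = TRUE,
                          prob = psi[d, act])]
      z <- vapply(l, function(li) {
        sub <- p$subsets[[li]]
        sub[sample.int(length(sub), 1L, prob = model$pi[li, sub])]
      }, integer(1))
      w <- vapply(z, function(zi)
        sample.int(model$vocabulary$size, 1L, prob = model$theta[zi, ]),
        integer(1))
      counts[d, ] <- tabulate(w, nbins = model$vocabulary$size)
      # store truths in the document-major, vocabulary-order token layout
      ord <- order(w)
      l_all[[d]] <- l[ord]; z_all[[d]] <- z[ord]
    } else {
      l_all[[d]] <- integer(0); z_all[[d]] <- integer(0)
    }
  }
  annotations <- lapply(seq_len(D), function(d)
    model$labels[which(lab_mat[d, seq_len(L)] == 1L)])
  names(annotations) <- doc_ids
  structure(list(bow = new_bow(model$vocabulary, doc_ids, counts),
                 label_matrix = lab_mat, annotations = annotations,
                 psi = psi, l = unlist(l_all), z = unlist(z_all),
                 model = model),
            class = "pftp_synthetic")
}

#' @export
print.pftp_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic corpus: %d docs, %d tokens, K = %d, W = %d\n",
              nrow(x$bow$counts), sum(x$bow$doc_totals),
              x$model$partition$K, x$model$vocabulary$size))
  invisible(x)
}

#' Total-variation distance between two probability vectors
#' @param p,q probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Match estimated topics to true topics within each label subset
#'
#' Topics inside a label's subset are exchangeable a priori, so estimated
#' and true topic-word distributions are compared after the within-subset
#' permutation minimizing the summed total-variation distance (exhaustive
#' search; subsets larger than 6 are rejected).
#'
#' @param theta_hat,theta_true K x W topic-word matrices sharing
#'   `partition`.
#' @param partition a `pftp_partition`.
#' @return list with `mean_tv` (mean matched TV over all K topics),
#'   `per_topic_tv` and `permutation` (per extended label, the order of
#'   true topics matched to the estimated ones).
#' @export
match_topics <- function(theta_hat, theta_true, partition) {
  stopifnot(inherits(partition, "pftp_partition"),
            all(dim(theta_hat) == dim(theta_true)),
            nrow(theta_hat) == partition$K)
  per_tv <- numeric(partition$K)
  perm_out <- vector("list", partition$Lext)
  for (l in seq_len(partition$Lext)) {
    sub <- partition$subsets[[l]]
    n <- length(sub)
    if (n > 6L)
      pftp_config_error("subsets larger than 6 topics are not supported by exhaustive matching")
    cost <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      tv_distance(theta_hat[sub[i], ], theta_true[sub[j], ])))
    perms <- permutations(n)
    tot <- apply(perms, 1L, function(pr)
      sum(cost[cbind(seq_len(n), pr)]))
    best <- perms[which.min(tot), ]
    per_tv[sub] <- cost[cbind(seq_len(n), best)]
    perm_out[[l]] <- best
  }
  list(mean_tv = mean(per_tv), per_topic_tv = per_tv,
       permutation = perm_out)
}

#' Write a simulated corpus to disk
#'
#' Writes the training-visible inputs (bag-of-words triplets, vocabulary,
#' annotation TSV, label universe) under `dir` and the ground truths
#' (true mixtures and assignments) under `dir/truth/`, so truths never
#' mix with the training inputs.
#'
#' @param synth a `pftp_synthetic`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  stopifnot(inherits(synth, "pftp_synthetic"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_bow(synth$bow, file.path(dir, "bow.tsv"), file.path(dir, "vocabulary.txt"))
  obs <- synth$model$labels[seq_len(synth$model$partition$L)]
  writeLines(obs, file.path(dir, "label_universe.txt"))
  ann <- vapply(names(synth$annotations), function(id)
    paste0(id, "\t", paste(synth$annotations[[id]], collapse = ",")),
    character(1))
  writeLines(ann, file.path(dir, "labels.tsv"))
  truth <- list(psi = synth$psi, l = synth$l, z = synth$z,
                pi = synth$model$pi, theta = synth$model$theta)
  jsonlite::write_json(truth, file.path(dir, "truth", "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
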