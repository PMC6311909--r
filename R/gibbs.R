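#' Collapsed training conditional for one token
#'
#' Probability of each admissible (label, topic) pair for a token of word
#' `word` in document `doc`, given counts from which the token itself has
#' already been removed (the usual "minus current token" convention).
#' The unnormalized weight of a candidate (l, k), l active in the
#' document and k in label l's subset, is
#' `(beta + N_dl) * (alpha + N_lk) / (alpha*K_l + N_l) *
#'  (lambda + N_kw) / (lambda*W + N_k)`;
#' the constant document-level denominator of the label factor is dropped.
#'
#' @param state a `pftp_state` whose counts exclude the token in question.
#' @param doc 1-based document index.
#' @param word 1-based vocabulary index of the token.
#' @param hyper a `pftp_hyper`.
#' @return data frame with columns `label`, `topic` (1-based) and `prob`
#'   (normalized over the candidates).
#' @export
training_conditional <- function(state, doc, word, hyper) {
  stopifnot(inherits(state, "pftp_state"), inherits(hyper, "pftp_hyper"))
  lay <- partition_layout(state$partition)
  res <- pftp_cond_weights_cpp(state$N_dl, state$N_lk, state$N_kw,
                               state$N_l, state$N_k, doc - 1L, word - 1L,
                               state$active[[doc]] - 1L, lay$start, lay$size,
                               state$W, hyper$alpha, hyper$beta, hyper$lambda)
  data.frame(label = res$label + 1L, topic = res$topic + 1L,
             prob = res$prob)
}

#' Collapsed log joint of the current assignments
#'
#' Log of the collapsed joint distribution of (labels, topics, words)
#' given the admissibility constraints and symmetric priors, up to an
#' assignment-independent constant; the sampler's convergence diagnostic.
#'
#' @param state a `pftp_state`.
#' @param hyper a `pftp_hyper`.
#' @return a single numeric value.
#' @export
collapsed_log_joint <- function(state, hyper) {
  lay <- partition_layout(state$partition)
  pftp_log_joint_cpp(state$N_dl, state$N_lk, state$N_kw,
                     lapply(state$active, function(a) a - 1L),
                     lay$start, lay$size,
                     hyper$alpha, hyper$beta, hyper$lambda)
}

run_sweeps <- function(state, hyper, iterations, burn_in, thin,
                       log_every = 0L, record = FALSE, verbose = FALSE) {
  lay <- partition_layout(state$partition)
  pftp_gibbs_train_cpp(state$doc - 1L, state$word - 1L,
                       lapply(state$active, function(a) a - 1L),
                       lay$start, lay$size, state$D, state$K, state$W,
                       state$Lext, hyper$alpha, hyper$beta, hyper$lambda,
                       state$l - 1L, state$z - 1L,
                       as.integer(iterations), as.integer(burn_in),
                       as.integer(thin), as.integer(log_every),
                       record, verbose)
}

update_state <- function(state, res) {
  state$l <- res$l + 1L
  state$z <- res$z + 1L
  state$N_dl <- res$N_dl; state$N_lk <- res$N_lk; state$N_kw <- res$N_kw
  state$N_d <- res$N_d; state$N_l <- res$N_l; state$N_k <- res$N_k
  state
}

#' Run Gibbs sweeps over a state
#'
#' Visits every token once per sweep in fixed document-major order; for
#' each token the current assignment is removed from the counts, a new
#' (label, topic) pair is drawn jointly from [training_conditional()] and
#' the counts are restored.  Uses R's RNG, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param state a `pftp_state`.
#' @param hyper a `pftp_hyper`.
#' @param sweeps number of full sweeps.
#' @param record keep the per-sweep assignment trace (attributes
#'   `trace_l`, `trace_z`, one row per sweep, 1-based)?
#' @return the updated `pftp_state`.
#' @export
gibbs_sweep <- function(state, hyper, sweeps = 1L, record = FALSE) {
  stopifnot(inherits(state, "pftp_state"), inherits(hyper, "pftp_hyper"))
  res <- run_sweeps(state, hyper, iterations = sweeps, burn_in = sweeps,
                    thin = 1L, record = record)
  state <- update_state(state, res)
  if (record) {
    attr(state, "trace_l") <- res$trace_l + 1L
    attr(state, "trace_z") <- res$trace_z + 1L
  }
  state
}

#' Posterior-mean estimates from a single state
#'
#' Plug-in posterior means given the current counts:
#' `psi_dl = (beta + N_dl) / (beta*L_d + N_d)` over the document's active
#' labels, `pi_lk = (alpha + N_lk) / (alpha*K_l + N_l)` for k in label
#' l's subset (0 elsewhere), and
#' `theta_kw = (lambda + N_kw) / (lambda*W + N_k)`.
#'
#' @param state a `pftp_state`.
#' @param hyper a `pftp_hyper`.
#' @return a `pftp_model` (elements `pi`, `theta`, `psi_train`,
#'   `partition`, `hyper`, plus label/vocabulary metadata).
#' @export
estimate_from_state <- function(state, hyper) {
  stopifnot(inherits(state, "pftp_state"))
  p <- state$partition
  pi <- matrix(0, p$Lext, p$K)
  for (l in seq_len(p$Lext)) {
    sub <- p$subsets[[l]]
    pi[l, sub] <- (hyper$alpha + state$N_lk[l, sub]) /
      (hyper$alpha * length(sub) + state$N_l[l])
  }
  theta <- (hyper$lambda + state$N_kw) /
    (hyper$lambda * state$W + state$N_k)
  psi <- matrix(0, state$D, p$Lext)
  for (d in seq_len(state$D)) {
    a <- state$active[[d]]
    psi[d, a] <- (hyper$beta + state$N_dl[d, a]) /
      (hyper$beta * length(a) + state$N_d[d])
  }
  new_model(pi, theta, psi, p, hyper,
            labels = colnames(state$label_matrix),
            vocabulary = state$bow$vocabulary,
            doc_ids = state$bow$doc_ids)
}

new_model <- function(pi, theta, psi_train, partition, hyper, labels,
                      vocabulary, doc_ids = NULL, log_joint = NULL,
                      schedule = NULL) {
  structure(list(pi = pi, theta = theta, psi_train = psi_train,
                 partition = partition, hyper = hyper, labels = labels,
                 vocabulary = vocabulary, doc_ids = doc_ids,
                 log_joint = log_joint, schedule = schedule),
            class = "pftp_model")
}

#' @export
print.pftp_model <- function(x, ...) {
  cat(sprintf("PFTP model: K = %d topics, %d extended labels, W = %d\n",
              x$partition$K, x$partition$Lext, ncol(x$theta)))
  invisible(x)
}

#' Train the model by collapsed Gibbs sampling
#'
#' Initializes assignments uniformly, runs `schedule$iterations` sweeps,
#' and averages the per-state posterior-mean estimates
#' ([estimate_from_state()]) over the retained (post burn-in, thinned)
#' samples.  Averaging point estimates within a chain is sound here
#' because the label-topic correspondence is pinned by the partition, so
#' no label switching can occur across samples.  Multiple chains are run
#' independently (seeds `seed + chain - 1`) and returned as a list, never
#' averaged together.
#'
#' @param bow a `pftp_bow`.
#' @param label_matrix binary matrix from [build_label_matrix()].
#' @param partition a `pftp_partition`.
#' @param hyper a `pftp_hyper` (see [pftp_hyperparameters()]).
#' @param schedule a `pftp_schedule`; defaults to the standard training
#'   schedule (2000 sweeps, 1000 burn-in, thin 50).
#' @param verbose print the collapsed log-joint every 100 sweeps.
#' @return a `pftp_model`, or a list of them when `schedule$chains > 1`.
#'   The element `log_joint` traces the convergence diagnostic.
#' @export
pftp_train <- function(bow, label_matrix, partition, hyper = NULL,
                       schedule = sampling_schedule(), verbose = FALSE) {
  stopifnot(inherits(bow, "pftp_bow"), inherits(partition, "pftp_partition"),
            inherits(schedule, "pftp_schedule"))
  validate_partition(partition)
  if (is.null(hyper))
    hyper <- pftp_hyperparameters(K = partition$K, W = bow$vocabulary$size)
  if (schedule$n_retained < 1L)
    pftp_config_error("schedule retains no samples (burn_in/thin too large)")
  one_chain <- function(chain_seed) {
    state <- init_state(bow, label_matrix, partition, seed = chain_seed)
    res <- run_sweeps(state, hyper, schedule$iterations, schedule$burn_in,
                      schedule$thin, log_every = 100L, verbose = verbose)
    new_model(res$pi_mean, res$theta_mean, res$psi_mean, partition, hyper,
              labels = colnames(label_matrix),
              vocabulary = bow$vocabulary, doc_ids = bow$doc_ids,
              log_joint = res$log_joint, schedule = schedule)
  }
  if (schedule$chains == 1L) return(one_chain(schedule$seed))
  lapply(seq_len(schedule$chains) - 1L,
         function(c) one_chain(schedule$seed + c))
}
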