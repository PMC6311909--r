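# Independent brute-force oracles.  Everything in this file recomputes
# quantities directly from their definitions (explicit loops, log-Gamma
# sums, exhaustive enumeration) without touching the package's sampler or
# metric code paths.

# Collapsed log joint of a full assignment configuration, computed from
# the raw token table by direct log-Gamma evaluation.  `tokens` is a data
# frame with columns doc, word, l, z (1-based); `active` a list of active
# extended labels per doc; `subsets` the per-extended-label topic sets.
oracle_log_joint <- function(tokens, active, subsets, K, W, alpha, beta,
                             lambda, D = length(active)) {
  lj <- 0
  for (d in seq_len(D)) {
    act <- active[[d]]
    Ld <- length(act)
    Nd <- sum(tokens$doc == d)
    lj <- lj + lgamma(beta * Ld) - lgamma(beta * Ld + Nd)
    for (l in act) {
      Ndl <- sum(tokens$doc == d & tokens$l == l)
      lj <- lj + lgamma(beta + Ndl) - lgamma(beta)
    }
  }
  for (l in seq_along(subsets)) {
    Kl <- length(subsets[[l]])
    Nl <- sum(tokens$l == l)
    lj <- lj + lgamma(alpha * Kl) - lgamma(alpha * Kl + Nl)
    for (k in subsets[[l]]) {
      Nlk <- sum(tokens$l == l & tokens$z == k)
      lj <- lj + lgamma(alpha + Nlk) - lgamma(alpha)
    }
  }
  for (k in seq_len(K)) {
    Nk <- sum(tokens$z == k)
    lj <- lj + lgamma(lambda * W) - lgamma(lambda * W + Nk)
    for (w in seq_len(W)) {
      Nkw <- sum(tokens$z == k & tokens$word == w)
      lj <- lj + lgamma(lambda + Nkw) - lgamma(lambda)
    }
  }
  lj
}

# Conditional distribution of one held-out token's (label, topic) pair by
# evaluating the collapsed joint at every admissible completion.
oracle_conditional <- function(rest_tokens, held_doc, held_word, active,
                               subsets, K, W, alpha, beta, lambda) {
  cand <- do.call(rbind, lapply(active[[held_doc]], function(l)
    data.frame(label = l, topic = subsets[[l]])))
  lj <- vapply(seq_len(nrow(cand)), function(i) {
    full <- rbind(rest_tokens,
                  data.frame(doc = held_doc, word = held_word,
                             l = cand$label[i], z = cand$topic[i]))
    oracle_log_joint(full, active, subsets, K, W, alpha, beta, lambda)
  }, numeric(1))
  w <- exp(lj - max(lj))
  cand$prob <- w / sum(w)
  cand
}

# Random admissible instance on a tiny problem.
random_instance <- function(n_tokens, L_obs = 2L, m = 1L, B = 1L, W = 3L,
                            D = 2L) {
  partition <- make_partition(L_obs, m, B)
  Lext <- partition$Lext
  lab <- matrix(0L, D, Lext)
  for (d in seq_len(D)) lab[d, sample.int(L_obs, sample(1:L_obs, 1L))] <- 1L
  if (B > 0L) lab[, Lext] <- 1L
  doc <- sort(sample.int(D, n_tokens, replace = TRUE))
  word <- integer(n_tokens); l <- integer(n_tokens); z <- integer(n_tokens)
  for (n in seq_len(n_tokens)) {
    word[n] <- sample.int(W, 1L)
    act <- which(lab[doc[n], ] == 1L)
    l[n] <- act[sample.int(length(act), 1L)]
    sub <- partition$subsets[[l[n]]]
    z[n] <- sub[sample.int(length(sub), 1L)]
  }
  list(tokens = data.frame(doc = doc, word = word, l = l, z = z),
       label_matrix = lab, partition = partition, W = W, D = D,
       active = lapply(seq_len(D), function(d) which(lab[d, ] == 1L)))
}

# Build a pftp_bow directly from token words (doc-major).
bow_from_tokens <- function(tokens, D, W) {
  vocab <- structure(list(blocks = sprintf("B%02d", seq_len(W)), size = W),
                     class = "pftp_vocab")
  counts <- matrix(0L, D, W,
                   dimnames = list(sprintf("d%03d", seq_len(D)), vocab$blocks))
  for (n in seq_len(nrow(tokens)))
    counts[tokens$doc[n], tokens$word[n]] <- counts[tokens$doc[n], tokens$word[n]] + 1L
  pftp:::new_bow(vocab, rownames(counts), counts)
}

# Reorder a token table into the package's canonical document-major,
# word-sorted token order so assignments can be loaded into a state.
canonical_order <- function(tokens) tokens[order(tokens$doc, tokens$word), ]

# ---- independently coded Labeled-LDA (one topic per label, no background)

# Conditional over labels for one token, counts excluding the token.
llda_conditional <- function(N_dl, N_kw, N_k, d, w, active, beta, lambda, W) {
  wgt <- vapply(active, function(l)
    (beta + N_dl[d, l]) * (lambda + N_kw[l, w]) / (lambda * W + N_k[l]),
    numeric(1))
  wgt / sum(wgt)
}

llda_estimates <- function(N_dl, N_kw, active, beta, lambda, W) {
  theta <- sweep(lambda + N_kw, 1L, lambda * W + rowSums(N_kw), "/")
  psi <- matrix(0, nrow(N_dl), ncol(N_dl))
  for (d in seq_len(nrow(N_dl))) {
    a <- active[[d]]
    psi[d, a] <- (beta + N_dl[d, a]) / (beta * length(a) + sum(N_dl[d, ]))
  }
  list(theta = theta, psi = psi)
}

# ---- brute-force multi-label metrics (definition-level loops)

bf_hamming <- function(truth, pred) {
  s <- 0
  for (d in seq_len(nrow(truth)))
    for (l in seq_len(ncol(truth)))
      s <- s + (truth[d, l] != pred[d, l])
  s / (nrow(truth) * ncol(truth))
}

bf_rank <- function(s) {
  # rank of each label under descending score, ties broken by label index
  ord <- integer(length(s))
  remaining <- seq_along(s)
  for (r in seq_along(s)) {
    best <- remaining[which.max(s[remaining])]
    ord[r] <- best
    remaining <- setdiff(remaining, best)
  }
  match(seq_along(s), ord)
}

bf_one_error <- function(truth, scores) {
  errs <- c()
  for (d in seq_len(nrow(truth))) {
    if (!any(truth[d, ])) next
    top <- which(bf_rank(scores[d, ]) == 1L)
    errs <- c(errs, !truth[d, top])
  }
  mean(errs)
}

bf_average_precision <- function(truth, scores) {
  vals <- c()
  for (d in seq_len(nrow(truth))) {
    ys <- which(truth[d, ])
    if (!length(ys)) next
    rnk <- bf_rank(scores[d, ])
    acc <- 0
    for (y in ys)
      acc <- acc + sum(rnk[ys] <= rnk[y]) / rnk[y]
    vals <- c(vals, acc / length(ys))
  }
  mean(vals)
}

bf_pr_area <- function(pos, s) {
  stopifnot(sum(pos) > 0)
  prec <- c(); rec <- c()
  for (t in sort(unique(s), decreasing = TRUE)) {
    pred <- s >= t
    prec <- c(prec, sum(pos & pred) / sum(pred))
    rec <- c(rec, sum(pos & pred) / sum(pos))
  }
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  a <- 0
  for (i in seq_len(length(rec) - 1L))
    a <- a + (rec[i + 1L] - rec[i]) * (prec[i] + prec[i + 1L]) / 2
  a
}

bf_pr_per_label <- function(truth, scores) {
  per <- rep(NA_real_, ncol(truth))
  for (l in seq_len(ncol(truth)))
    if (any(truth[, l])) per[l] <- bf_pr_area(truth[, l], scores[, l])
  ok <- !is.na(per)
  n_l <- colSums(truth)[ok]
  list(per = per, macro = mean(per[ok]),
       weighted = sum(per[ok] * n_l / sum(n_l)))
}
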