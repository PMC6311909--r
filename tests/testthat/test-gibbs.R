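test_that("conditional on a fresh empty-count state is symmetric", {
  # With zero counts the conditional is uniform over admissible labels and
  # uniform within each label's subset (the within-subset Dirichlet
  # normalizes per label); with equal subset sizes this is uniform over
  # all admissible (label, topic) pairs.
  vocab <- build_vocabulary(list(c("AA", "CC", "GG")))
  bow <- build_bow(list(d1 = character(0)), vocab)
  hy <- pftp_hyperparameters(0.7, 0.7, 0.7)
  p1 <- make_partition(2, 1, 1)     # equal subset sizes: 1, 1, 1
  st1 <- state_from_assignments(bow, matrix(1L, 1, 3), p1,
                                integer(0), integer(0))
  cond1 <- training_conditional(st1, doc = 1, word = 2, hy)
  expect_equal(cond1$prob, rep(1 / 3, 3))
  p2 <- make_partition(2, 2, 1)     # unequal sizes: 2, 2, 1
  st2 <- state_from_assignments(bow, matrix(1L, 1, 3), p2,
                                integer(0), integer(0))
  cond2 <- training_conditional(st2, doc = 1, word = 2, hy)
  expect_equal(nrow(cond2), 5L)     # 2 + 2 + 1 admissible pairs
  by_label <- tapply(cond2$prob, cond2$label, sum)
  expect_equal(as.vector(by_label), rep(1 / 3, 3))  # uniform over labels
  expect_equal(cond2$prob[cond2$label == 1L], rep(1 / 6, 2))
})

test_that("inactive labels have exactly zero probability", {
  partition <- make_partition(2, 2, 1)
  vocab <- build_vocabulary(list(c("AA", "CC")))
  bow <- build_bow(list(d1 = "AA", d2 = "CC"), vocab)
  lab <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 2, 3, byrow = TRUE)
  st <- init_state(bow, lab, partition, seed = 1)
  cond <- training_conditional(st, doc = 1, word = 1,
                               pftp_hyperparameters(0.5, 0.5, 0.5))
  # label 2 is not admissible in doc 1: absent from the candidate set
  expect_false(any(cond$label == 2L))
  expect_true(all(cond$label %in% c(1L, 3L)))
  expect_equal(sum(cond$prob), 1, tolerance = 1e-12)
})

test_that("sweeps conserve tokens and keep counts in sync", {
  tm <- sample_model(2, 2, 1, 10, seed = 2)
  synth <- sample_corpus(tm, 10, 1, 25, seed = 3)
  st <- init_state(synth$bow, synth$label_matrix, tm$partition, seed = 4)
  hy <- pftp_hyperparameters(0.5, 0.5, 0.5)
  total <- length(st$doc)
  set.seed(5)
  st <- gibbs_sweep(st, hy, sweeps = 20)
  expect_equal(sum(st$N_d), total)
  expect_equal(sum(st$N_l), total)
  expect_equal(sum(st$N_k), total)
  expect_true(validate_state(st))
  # support invariant after sweeping
  for (n in seq_along(st$doc)) {
    expect_true(st$label_matrix[st$doc[n], st$l[n]] == 1L)
    expect_true(st$z[n] %in% st$partition$subsets[[st$l[n]]])
  }
})

test_that("posterior-mean estimates match their closed forms", {
  partition <- make_partition(2, 3, 1)   # K_l = 3 for observed labels
  vocab <- build_vocabulary(list(c("AA", "CC", "GG")))
  hy <- pftp_hyperparameters(1, 1, 1)
  # all-zero counts: uniform on every support
  bow0 <- build_bow(list(d1 = character(0)), vocab)
  lab <- matrix(1L, 1, 3)
  st0 <- state_from_assignments(bow0, lab, partition, integer(0), integer(0))
  est0 <- estimate_from_state(st0, hy)
  expect_equal(est0$pi[1, partition$subsets[[1]]], rep(1 / 3, 3))
  expect_equal(unname(est0$theta[1, ]), rep(1 / 3, 3))
  expect_equal(unname(est0$psi_train[1, ]), rep(1 / 3, 3))
  # a single token assigned (l1, first topic of l1, word 1), alpha = 1:
  # pi = (1 + 1) / (K_l + 1)
  bow1 <- build_bow(list(d1 = "AA"), vocab)
  st1 <- state_from_assignments(bow1, lab, partition,
                                l = 1L, z = partition$subsets[[1]][1])
  est1 <- estimate_from_state(st1, hy)
  expect_equal(est1$pi[1, partition$subsets[[1]][1]], 2 / (3 + 1))
  # normalization of every returned vector
  expect_equal(rowSums(est1$pi), rep(1, 3), tolerance = 1e-12)
  expect_equal(rowSums(est1$theta), rep(1, 7), tolerance = 1e-12)
  expect_equal(rowSums(est1$psi_train), 1, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  tm <- sample_model(2, 2, 1, 15, seed = 6)
  synth <- sample_corpus(tm, 15, 1, 20, seed = 7)
  sch <- sampling_schedule(60, 30, 10, seed = 123)
  m1 <- pftp_train(synth$bow, synth$label_matrix, tm$partition,
                   schedule = sch)
  m2 <- pftp_train(synth$bow, synth$label_matrix, tm$partition,
                   schedule = sch)
  expect_identical(m1$pi, m2$pi)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$psi_train, m2$psi_train)
})

test_that("a strongly separated corpus pins each label's topic on its word", {
  # label-1 proteins contain only AA, label-2 proteins only CC
  docs <- c(lapply(1:30, function(i) rep("AA", 50)),
            lapply(1:30, function(i) rep("CC", 50)))
  names(docs) <- sprintf("p%02d", 1:60)
  vocab <- build_vocabulary(docs)
  bow <- build_bow(docs, vocab)
  lab <- cbind(rep(c(1L, 0L), each = 30), rep(c(0L, 1L), each = 30), 1L)
  partition <- make_partition(2, 1, 1)
  model <- pftp_train(bow, lab, partition,
                      schedule = sampling_schedule(200, 100, 20, seed = 31))
  # default hyperparameters: alpha = 50/K, lambda = 200/W
  expect_equal(model$hyper$alpha, 50 / 3)
  k1 <- partition$subsets[[1]][1]; k2 <- partition$subsets[[2]][1]
  expect_gte(model$theta[k1, which(vocab$blocks == "AA")], 0.9)
  expect_gte(model$theta[k2, which(vocab$blocks == "CC")], 0.9)
})

test_that("the collapsed log-joint diagnostic is traced and consistent", {
  tm <- sample_model(3, 1, 1, 20, seed = 16)
  synth <- sample_corpus(tm, 40, 2, 40, seed = 17)
  hy <- tm$hyper
  model <- pftp_train(synth$bow, synth$label_matrix, tm$partition,
                      hyper = hy,
                      schedule = sampling_schedule(200, 100, 20, seed = 18))
  lj <- model$log_joint
  expect_equal(lj$sweep, c(100, 200))
  expect_true(all(is.finite(lj$log_joint)))
  # the R-side diagnostic agrees with a direct log-Gamma evaluation of
  # the collapsed joint on a small hand-checked state
  st <- state_from_assignments(synth$bow, synth$label_matrix, tm$partition,
                               synth$l, synth$z)
  tokens <- data.frame(doc = st$doc, word = st$word, l = st$l, z = st$z)
  ref <- oracle_log_joint(tokens, st$active, tm$partition$subsets,
                          tm$partition$K, st$W, hy$alpha, hy$beta, hy$lambda)
  expect_equal(collapsed_log_joint(st, hy), ref, tolerance = 1e-10)
})

test_that("label-level word distributions are recovered and improve with data", {
  # The identifiable quantity of the model is each label's word
  # distribution phi_l = sum_k pi_lk theta_k (individual topics within a
  # subset are exchangeable along a likelihood ridge); phi recovery must
  # be good and improve with document length.
  hyper_gen <- pftp_hyperparameters(0.5, 0.5, 0.1)
  tm <- sample_model(4, 2, 1, 60, hyper_gen, seed = 41)
  phi_true <- tm$pi %*% tm$theta
  phi_tv <- function(nd) {
    tr <- sample_corpus(tm, 150, 2, nd, seed = 42)
    model <- pftp_train(tr$bow, tr$label_matrix, tm$partition,
                        hyper = hyper_gen,
                        schedule = sampling_schedule(300, 150, 30,
                                                     seed = 43))
    phi_hat <- model$pi %*% model$theta
    mean(vapply(seq_len(nrow(phi_hat)), function(l)
      tv_distance(phi_hat[l, ], phi_true[l, ]), numeric(1)))
  }
  tv_short <- phi_tv(30L)
  tv_long <- phi_tv(240L)
  expect_lt(tv_long, 0.12)
  expect_lt(tv_long, tv_short)
})

test_that("multiple chains are returned separately, never averaged", {
  tm <- sample_model(2, 1, 1, 10, seed = 20)
  synth <- sample_corpus(tm, 10, 1, 15, seed = 21)
  ms <- pftp_train(synth$bow, synth$label_matrix, tm$partition,
                   schedule = sampling_schedule(40, 20, 10, chains = 2,
                                                seed = 22))
  expect_length(ms, 2L)
  expect_s3_class(ms[[1]], "pftp_model")
  expect_false(identical(ms[[1]]$theta, ms[[2]]$theta))
})
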