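test_that("sampled model vectors are normalized on their supports", {
  tm <- sample_model(3, 2, 1, 30, seed = 1)
  expect_equal(rowSums(tm$pi), rep(1, 4), tolerance = 1e-12)
  expect_equal(rowSums(tm$theta), rep(1, 7), tolerance = 1e-12)
  for (l in seq_len(4)) {
    off <- setdiff(seq_len(tm$partition$K), tm$partition$subsets[[l]])
    expect_true(all(tm$pi[l, off] == 0))
  }
})

test_that("a huge concentration gives numerically uniform mixtures", {
  tm <- sample_model(2, 3, 1, 10,
                     pftp_hyperparameters(1e6, 0.5, 1e6), seed = 2)
  expect_lt(max(abs(tm$pi[1, tm$partition$subsets[[1]]] - 1 / 3)), 1e-2)
  expect_lt(max(abs(tm$theta - 1 / 10)), 1e-2)
})

test_that("sparse lambda yields topics with low word entropy", {
  # E[entropy] of Dirichlet(lambda) draws = digamma(W*lambda+1) - digamma(lambda+1)
  W <- 50; lam <- 0.01
  tm <- sample_model(20, 2, 0, W, pftp_hyperparameters(0.5, 0.5, lam),
                     seed = 3)
  ent <- apply(tm$theta, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  expected <- digamma(W * lam + 1) - digamma(lam + 1)
  expect_lt(mean(ent), 0.5 * log(W))
  expect_lt(abs(mean(ent) - expected), 0.5)
})

test_that("simulated corpora are reproducible and self-consistent", {
  tm <- sample_model(4, 2, 1, 25, seed = 4)
  s1 <- sample_corpus(tm, 20, 2, 30, seed = 5)
  s2 <- sample_corpus(tm, 20, 2, 30, seed = 5)
  expect_identical(s1$bow$counts, s2$bow$counts)
  expect_identical(s1$l, s2$l)
  expect_identical(s1$psi, s2$psi)
  # token assignments match the bag of words
  expect_equal(length(s1$l), sum(s1$bow$doc_totals))
  # empty documents are valid
  s0 <- sample_corpus(tm, 5, 2, 0, seed = 6)
  expect_equal(sum(s0$bow$doc_totals), 0L)
  expect_equal(nrow(s0$bow$counts), 5L)
})

test_that("one active label with m = 1, B = 0 is the degenerate path", {
  tm <- sample_model(3, 1, 0, 12, seed = 7)
  s <- sample_corpus(tm, 8, 1, 20, seed = 8)
  # all z within a doc equal that doc's single label topic
  doc_of_token <- rep(seq_len(8), times = s$bow$doc_totals)
  for (d in 1:8) {
    lab <- which(s$label_matrix[d, ] == 1L)
    expect_true(all(s$z[doc_of_token == d] ==
                      tm$partition$subsets[[lab]][1]))
  }
})

test_that("token-level label frequencies match Dirichlet-multinomial moments", {
  # L = 2, both labels active in every doc (plus background): E[psi] = 1/3.
  # Var(N_dl) per doc = N p(1-p)(N + b0)/(1 + b0) with b0 = 3*beta.
  D <- 2000L; N <- 120L; beta <- 0.5
  tm <- sample_model(2, 1, 1, 30, pftp_hyperparameters(0.5, beta, 0.1),
                     seed = 9)
  s <- sample_corpus(tm, D, 2, N, seed = 10)
  doc_of_token <- rep(seq_len(D), times = s$bow$doc_totals)
  share <- sum(s$l == 1L) / (D * N)
  p <- 1 / 3; b0 <- 3 * beta
  var_doc <- N * p * (1 - p) * (N + b0) / (1 + b0)
  sd_share <- sqrt(var_doc * D) / (D * N)
  expect_lt(abs(share - p), 5 * sd_share)
})

test_that("topic matching recovers within-subset permutations exactly", {
  tm <- sample_model(3, 3, 1, 20, seed = 11)
  p <- tm$partition
  theta_perm <- tm$theta
  perm <- list(c(2L, 3L, 1L), c(1L, 3L, 2L), c(3L, 1L, 2L), 1L)
  for (l in seq_len(p$Lext)) {
    sub <- p$subsets[[l]]
    theta_perm[sub, ] <- tm$theta[sub[perm[[l]]], ]
  }
  mt <- match_topics(theta_perm, tm$theta, p)
  expect_equal(mt$mean_tv, 0, tolerance = 1e-12)
  # m = 1 always matches by identity
  tm1 <- sample_model(2, 1, 1, 10, seed = 12)
  mt1 <- match_topics(tm1$theta, tm1$theta, tm1$partition)
  expect_true(all(vapply(mt1$permutation, identical, logical(1), 1L)))
})

test_that("matched TV equals the brute-force minimum over permutations", {
  set.seed(13)
  p <- make_partition(2, 3, 1)
  W <- 2
  rand_theta <- function() t(vapply(seq_len(p$K), function(k) {
    x <- runif(W); x / sum(x)
  }, numeric(W)))
  th <- rand_theta(); tt <- rand_theta()
  mt <- match_topics(th, tt, p)
  for (l in seq_len(p$Lext)) {
    sub <- p$subsets[[l]]
    perms <- pftp:::permutations(length(sub))
    best <- min(apply(perms, 1, function(pr)
      sum(vapply(seq_along(sub), function(i)
        tv_distance(th[sub[i], ], tt[sub[pr[i]], ]), numeric(1)))))
    expect_equal(sum(mt$per_topic_tv[sub]), best, tolerance = 1e-12)
  }
})

test_that("simulation output keeps truths apart from training inputs", {
  tm <- sample_model(2, 2, 1, 15, seed = 14)
  s <- sample_corpus(tm, 10, 1, 20, seed = 15)
  d <- withr::local_tempdir()
  write_synthetic(s, d)
  expect_true(file.exists(file.path(d, "bow.tsv")))
  expect_true(file.exists(file.path(d, "labels.tsv")))
  expect_true(file.exists(file.path(d, "truth", "truth.json")))
  expect_false(file.exists(file.path(d, "truth.json")))
  back <- read_bow(file.path(d, "bow.tsv"), file.path(d, "vocabulary.txt"))
  expect_equal(back$counts, s$bow$counts)
})
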