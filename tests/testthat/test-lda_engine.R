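test_that("K = 1 collapses to the closed-form phi and log-likelihood", {
  cm <- tiny_counts()
  inp <- as_lda_input(cm)
  fit <- fit_lda(inp, K = 1, iterations = 10, burn_in = 5, seed = 3)
  expect_equal(unname(fit$theta[, 1L]), c(1, 1))
  n_w <- rowSums(inp$matrix)
  G <- nrow(inp$matrix)
  expect_equal(unname(fit$phi[1L, ]),
               unname((n_w + 0.1) / (sum(n_w) + G * 0.1)))
  # log-likelihood by direct substitution
  expect_equal(log_likelihood(fit, inp),
               sum(n_w * log((n_w + 0.1) / (sum(n_w) + G * 0.1))))
})

test_that("identical seed and input give bit-identical theta and phi", {
  sim <- generate_lda_corpus(n_cells = 30, n_genes = 25, n_topics = 3,
                             depth = 60, seed = 8)
  inp <- as_lda_input(sim$counts)
  f1 <- fit_lda(inp, K = 3, iterations = 80, burn_in = 40, seed = 42)
  f2 <- fit_lda(inp, K = 3, iterations = 80, burn_in = 40, seed = 42)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$phi, f2$phi)
})

test_that("theta/phi rows are simplexes and tokens are conserved", {
  sim <- generate_lda_corpus(n_cells = 40, n_genes = 30, n_topics = 4,
                             depth = 70, seed = 12)
  inp <- as_lda_input(sim$counts)
  for (est in c("final", "average")) {
    fit <- fit_lda(inp, K = 4, iterations = 60, burn_in = 30, seed = 2,
                   estimate = est)
    expect_true(all(fit$theta >= 0) && all(fit$phi >= 0))
    expect_equal(unname(rowSums(fit$theta)), rep(1, nrow(fit$theta)),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$phi)), rep(1, fit$K),
                 tolerance = 1e-9)
  }
  fit <- fit_lda(inp, K = 4, iterations = 60, burn_in = 30, seed = 2)
  expect_equal(unname(rowSums(fit$counts_ck)),
               unname(colSums(inp$matrix)))
  expect_equal(sum(fit$counts_kg), sum(inp$matrix))
})

test_that("sampler state frequencies match the enumerated collapsed posterior", {
  m <- matrix(c(2L, 1L, 0L,
                0L, 1L, 2L), nrow = 3)
  cm <- count_matrix(m, c("A", "B", "C"), c("c1", "c2"))
  inp <- as_lda_input(cm)
  toks <- topicgrad:::.expand_tokens(inp$matrix)
  oracle <- enum_collapsed_posterior(toks$doc + 1L, toks$word + 1L,
                                     n_docs = 2, n_words = 3, K = 2,
                                     alpha = 50, beta = 0.1)
  tr <- topicgrad:::.lda_state_trace(inp, K = 2, alpha = 50, beta = 0.1,
                                     iterations = 12000, burn_in = 2000,
                                     seed = 7)
  emp <- trace_state_freq(tr$trace, oracle$states)
  expect_lt(max(abs(emp - oracle$prob)), 0.05)
})

test_that("empty cells get the uniform prior mean and zero likelihood", {
  m <- matrix(c(3L, 2L, 0L, 0L), nrow = 2)
  cm <- count_matrix(m, c("g1", "g2"), c("full", "empty"))
  inp <- as_lda_input(cm)
  expect_true(inp$flagged[["empty"]] || inp$flagged[2L])
  fit <- fit_lda(inp, K = 2, iterations = 30, burn_in = 10, seed = 1)
  expect_equal(unname(fit$theta[2L, ]), c(0.5, 0.5))
  # zero-token cell contributes nothing to the log-likelihood
  p_full <- as.vector(t(fit$phi) %*% fit$theta[1L, ])
  expect_equal(log_likelihood(fit, inp),
               sum(inp$matrix[, 1L] * log(p_full)))
})

test_that("uniform phi gives log-likelihood T*ln(1/G)", {
  G <- 12
  phi <- matrix(1 / G, nrow = 3, ncol = G,
                dimnames = list(NULL, sprintf("g%03d", 1:G)))
  set.seed(4)
  theta <- topicgrad:::.rdirichlet(5, rep(1, 3))
  model <- fake_model(phi, theta)
  m <- matrix(rpois(G * 5, 2), nrow = G,
              dimnames = list(colnames(phi), NULL))
  cm <- count_matrix(m, colnames(phi), sprintf("c%d", 1:5))
  inp <- as_lda_input(cm)
  expect_equal(log_likelihood(model, inp), sum(m) * log(1 / G))
})

test_that("vocabulary mismatch and invalid arguments error", {
  cm <- tiny_counts()
  inp <- as_lda_input(cm)
  expect_error(fit_lda(inp, K = 0), "K")
  expect_error(fit_lda(inp, K = 2, iterations = 10, burn_in = 10),
               "burn_in")
  zero <- count_matrix(matrix(0L, 2, 2), c("a", "b"), c("c1", "c2"))
  expect_error(fit_lda(as_lda_input(zero), K = 2), "zero total tokens")

  fit <- fit_lda(inp, K = 2, iterations = 20, burn_in = 10, seed = 1)
  other <- as_lda_input(count_matrix(matrix(1L, 2, 2), c("x", "y"),
                                     c("c1", "c2")))
  expect_error(log_likelihood(fit, other), "vocabular")
})

test_that("permuting cells permutes theta and leaves converged phi stable", {
  sim <- generate_lda_corpus(n_cells = 80, n_genes = 40, n_topics = 3,
                             depth = 150, anchor_strength = 0.6, seed = 31)
  inp <- as_lda_input(sim$counts)
  set.seed(99)
  perm <- sample(ncol(inp$matrix))
  inp_p <- inp
  inp_p$matrix <- inp$matrix[, perm]
  inp_p$cell_barcodes <- inp$cell_barcodes[perm]

  f1 <- fit_lda(inp, K = 3, iterations = 400, burn_in = 200, seed = 5,
                estimate = "average")
  f2 <- fit_lda(inp_p, K = 3, iterations = 400, burn_in = 200, seed = 6,
                estimate = "average")
  mt <- match_topics(f2$phi, f1$phi)
  expect_gt(min(mt$similarity), 0.98)
  expect_lt(max(abs(f2$phi[order(mt$permutation), ] - f1$phi)), 0.02)
})
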