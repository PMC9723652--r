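test_that("simulated corpora respect token budgets and are reproducible", {
  sim <- generate_lda_corpus(n_cells = 30, n_genes = 40, n_topics = 4,
                             depth = 120, seed = 3)
  expect_equal(unname(Matrix::colSums(sim$counts$counts)), rep(120, 30))
  expect_equal(unname(rowSums(sim$truth$theta_true)), rep(1, 30),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(sim$truth$phi_true)), rep(1, 4),
               tolerance = 1e-12)

  sim2 <- generate_lda_corpus(n_cells = 30, n_genes = 40, n_topics = 4,
                              depth = 120, seed = 3)
  expect_identical(as.matrix(sim$counts$counts),
                   as.matrix(sim2$counts$counts))
  expect_identical(sim$truth$phi_true, sim2$truth$phi_true)

  # anchor blending guarantees each anchor at least strength/block mass,
  # putting anchors in the upper tail of their own topic's distribution
  block <- 40 %/% 4
  for (k in 1:4) {
    a_idx <- match(sim$truth$anchor_genes[[k]], sim$counts$gene_names)
    expect_true(all(sim$truth$phi_true[k, a_idx] >= 0.5 / block))
    ord <- sim$counts$gene_names[order(-sim$truth$phi_true[k, ])]
    expect_true(all(sim$truth$anchor_genes[[k]] %in% ord[1:(2 * block)]))
  }
  expect_error(generate_lda_corpus(depth = 0), "depth")
  expect_error(generate_lda_corpus(anchor_strength = 1), "anchor_strength")
})

test_that("per-cell gene frequencies converge to the planted mixture", {
  sim <- generate_lda_corpus(n_cells = 5, n_genes = 100, n_topics = 3,
                             depth = 50000, seed = 17)
  expected <- sim$truth$theta_true %*% sim$truth$phi_true # N x G
  freq <- t(as.matrix(sim$counts$counts)) / 50000
  # multinomial error at depth 5e4: a few times sqrt(p/n) ~ 2e-3
  expect_lt(max(abs(freq - expected)), 0.01)
})

test_that("response gradients plant the ramp in the labeled groups", {
  gr <- generate_response_gradient(n_per_group = 200,
                                   groups = c("control", "treated"),
                                   effect_topics = 1, effect_ramp = c(0, 0.3),
                                   n_genes = 60, n_topics = 5, depth = 100,
                                   seed = 29)
  th <- gr$truth$theta_true[, 1L]
  lab <- gr$truth$group_labels
  diff_mean <- mean(th[lab == "treated"]) - mean(th[lab == "control"])
  expect_equal(diff_mean, 0.3, tolerance = 0.05)
  expect_equal(unname(rowSums(gr$truth$theta_true)), rep(1, 400),
               tolerance = 1e-9)
  expect_identical(gr$counts$cell_groups, lab)

  expect_error(generate_response_gradient(groups = c("a", "b"),
                                          effect_ramp = c(0, 0.1, 0.2)),
               "per group")
  expect_error(generate_response_gradient(effect_topics = 99), "range")
})

test_that("match_topics solves the assignment problem optimally", {
  set.seed(37)
  phi <- topicgrad:::.rdirichlet(5, rep(0.2, 40))
  id <- match_topics(phi, phi)
  expect_identical(id$permutation, 1:5)
  expect_equal(id$similarity, rep(1, 5), tolerance = 1e-12)

  perm <- sample(5)
  mt <- match_topics(phi[perm, ], phi)
  expect_identical(mt$permutation, perm)
  expect_equal(mt$mean_similarity, 1, tolerance = 1e-12)

  # Hungarian equals brute-force enumeration over all K! permutations
  for (s in 1:8) {
    set.seed(100 + s)
    K <- sample(2:6, 1)
    a <- topicgrad:::.rdirichlet(K, rep(0.5, 25))
    b <- topicgrad:::.rdirichlet(K, rep(0.5, 25))
    sim_mat <- topicgrad:::.cosine_matrix(a, b)
    got <- match_topics(a, b)
    best <- bf_best_permutation(sim_mat)
    expect_equal(sum(got$similarity), best$total, tolerance = 1e-12)
  }
  expect_error(match_topics(phi, phi[, 1:10]), "shape")
})

test_that("a zero ramp leaves groups exchangeable", {
  g0 <- generate_response_gradient(n_per_group = 80, groups = c("a", "b"),
                                   effect_topics = 1, effect_ramp = c(0, 0),
                                   n_genes = 100, depth = 200, seed = 61)
  sc <- signature_score(g0$counts, g0$truth$anchor_genes[[1L]], seed = 9)
  p <- wilcox.test(sc[g0$counts$cell_groups == "a"],
                   sc[g0$counts$cell_groups == "b"])$p.value
  expect_gt(p, 0.01)
})
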