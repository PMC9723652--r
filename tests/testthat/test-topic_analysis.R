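test_that("top_genes orders by phi with lexicographic tie-break", {
  phi <- rbind(c(0.4, 0.4, 0.1, 0.1),
               c(0.1, 0.2, 0.3, 0.4))
  colnames(phi) <- c("B", "A", "D", "C")
  model <- fake_model(phi)
  # two equal maxima: "A" wins the tie lexicographically
  expect_identical(top_genes(model, 1, 1)$genes, "A")
  # n = G returns the whole ordered vocabulary
  expect_identical(top_genes(model, 2, 10)$genes, c("C", "D", "A", "B"))
  expect_equal(top_genes(model, 2, 2)$scores, c(0.4, 0.3))
  expect_error(top_genes(model, 3), "topic")
  expect_error(top_genes(model, 1, 0), "n must")
})

test_that("normalize_cell_scores z-scores theta per topic", {
  phi <- matrix(0.25, 2, 4, dimnames = list(NULL, letters[1:4]))
  theta <- cbind(c(0.2, 0.4), c(0.8, 0.6))
  model <- fake_model(phi, theta)
  z <- normalize_cell_scores(model)
  expect_identical(z$score_kind, "z_theta")
  # hand z-score: [0.2, 0.4] -> z = [-0.7071, +0.7071]
  expect_equal(unname(z$scores[, 1L]), c(-0.7071, 0.7071),
               tolerance = 1e-4)
  expect_equal(unname(colMeans(z$scores)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z$scores, 2, var)), c(1, 1), tolerance = 1e-6)

  flat <- fake_model(phi, cbind(c(0.5, 0.5), c(0.5, 0.5)))
  # one warning per constant column
  suppressWarnings(expect_warning(zf <- normalize_cell_scores(flat),
                                  "constant"))
  expect_true(all(zf$scores == 0))

  one <- fake_model(phi, matrix(c(0.4, 0.6), 1))
  expect_error(normalize_cell_scores(one), "one cell")
})

test_that("signature_score is zero under exchangeable signatures", {
  # constant expression: signature mean equals control mean exactly
  m <- matrix(4L, 30, 10)
  cm <- count_matrix(m, sprintf("g%02d", 1:30), sprintf("c%02d", 1:10))
  sc <- signature_score(cm, c("g01", "g05"), seed = 3)
  expect_equal(unname(sc), rep(0, 10))

  # signature = the whole universe: controls come from the same pool
  set.seed(8)
  m2 <- matrix(rpois(30 * 20, 5), 30, 20)
  cm2 <- count_matrix(m2, sprintf("g%02d", 1:30), sprintf("c%02d", 1:20))
  sc2 <- signature_score(cm2, cm2$gene_names, n_ctrl = 200, seed = 5)
  expect_lt(max(abs(sc2)), 0.2)

  expect_error(signature_score(cm2, c("zz1", "zz2")), "no signature gene")
  expect_warning(signature_score(cm2, c("g01", "zz1"), seed = 1), "absent")
})

test_that("signature_score separates cells with planted program activity", {
  sim <- generate_lda_corpus(n_cells = 200, n_genes = 200, n_topics = 5,
                             depth = 500, seed = 77)
  k <- 2L
  active <- sim$truth$theta_true[, k] > 0.5
  expect_gte(sum(active), 10) # planted truth populates both classes
  sc <- signature_score(sim$counts, sim$truth$anchor_genes[[k]], seed = 4)
  # rank agreement with the planted labels (AUC from the Wilcoxon statistic)
  w <- wilcox.test(sc[active], sc[!active])$statistic
  auc <- w / (sum(active) * sum(!active))
  expect_gte(auc, 0.9)
  # per-cell values travel with the cells under permutation
  perm <- sample(length(sc))
  cm_p <- count_matrix(sim$counts$counts[, perm],
                       sim$counts$gene_names,
                       sim$counts$cell_barcodes[perm])
  sc_p <- signature_score(cm_p, sim$truth$anchor_genes[[k]], seed = 4)
  expect_equal(sc_p, sc[perm])
})

test_that("self-transfer scores rank-correlate with theta", {
  sim <- generate_lda_corpus(n_cells = 120, n_genes = 100, n_topics = 4,
                             depth = 300, seed = 13)
  inp <- as_lda_input(sim$counts)
  fit <- fit_lda(inp, K = 4, iterations = 150, burn_in = 75, seed = 6)
  sc <- transfer_topics(fit, sim$counts, n = 25, seed = 2)
  expect_identical(sc$score_kind, "signature")
  for (k in seq_len(4)) {
    expect_gt(cor(sc$scores[, k], fit$theta[, k], method = "spearman"), 0)
  }
})

test_that("transfer drops topics with no gene overlap", {
  phi <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.1, 0.1, 0.7), 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  model <- fake_model(phi)
  tgt <- count_matrix(matrix(1:6, 3, 2), c("x", "y", "z"), c("c1", "c2"))
  # one warning per dropped topic
  suppressWarnings(expect_warning(sc <- transfer_topics(model, tgt, n = 2),
                                  "no signature"))
  expect_equal(ncol(sc$scores), 0L)
})

test_that("topic_overlap counts shared signature genes", {
  sim <- generate_lda_corpus(n_cells = 50, n_genes = 60, n_topics = 3,
                             depth = 100, seed = 23)
  inp <- as_lda_input(sim$counts)
  fit <- fit_lda(inp, K = 3, iterations = 60, burn_in = 30, seed = 2)
  ov <- topic_overlap(fit, fit, n = 10)
  expect_identical(unname(diag(ov)), rep(10L, 3))
  expect_true(all(ov <= 10L))

  phi_a <- matrix(c(0.5, 0.5, 0, 0), 1,
                  dimnames = list(NULL, c("a", "b", "x1", "x2")))
  phi_b <- matrix(c(0.5, 0.5, 0, 0), 1,
                  dimnames = list(NULL, c("u", "v", "y1", "y2")))
  expect_true(all(topic_overlap(fake_model(phi_a), fake_model(phi_b),
                                n = 2) == 0L))
})

test_that("delta_control_zscore centers controls and detects shifts", {
  set.seed(55)
  groups <- rep(c("control", "treated"), each = 100)
  base <- rnorm(200)
  scores <- base + ifelse(groups == "treated", 2 * sd(base), 0)
  dz <- delta_control_zscore(scores, groups, "control")
  expect_equal(median(dz[groups == "control"]), 0)
  expect_gt(median(dz[groups == "treated"]), 1)

  # affine invariance: z-scoring absorbs location and scale
  dz2 <- delta_control_zscore(5 * scores - 3, groups, "control")
  expect_equal(dz2, dz, tolerance = 1e-12)

  # all cells control: median delta 0
  dz3 <- delta_control_zscore(base, rep("control", 200), "control")
  expect_equal(median(dz3), 0)

  expect_error(delta_control_zscore(scores, groups, "nope"), "control")
  expect_error(delta_control_zscore(rep(1, 4), rep("control", 4),
                                    "control"), "variance")
  expect_error(delta_control_zscore(1:3, c("a", "b"), "a"), "length")
})
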