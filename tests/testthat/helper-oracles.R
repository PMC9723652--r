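# Independent oracles and small fixture builders used across the suite.

# Exact collapsed posterior over all K^T topic-assignment states:
# P(z) \propto prod_d prod_k Gamma(n_dk + a)/Gamma(a)
#            * prod_k Gamma(G b)/Gamma(n_k + G b) prod_w Gamma(n_kw + b)/Gamma(b)
enum_collapsed_posterior <- function(doc, word, n_docs, n_words, K,
                                     alpha, beta) {
  T <- length(doc)
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(states, 1L, function(z) {
    n_dk <- matrix(0, n_docs, K)
    n_kw <- matrix(0, K, n_words)
    for (t in seq_len(T)) {
      n_dk[doc[t], z[t]] <- n_dk[doc[t], z[t]] + 1
      n_kw[z[t], word[t]] <- n_kw[z[t], word[t]] + 1
    }
    sum(lgamma(n_dk + alpha) - lgamma(alpha)) +
      sum(lgamma(n_words * beta) -
            lgamma(rowSums(n_kw) + n_words * beta)) +
      sum(lgamma(n_kw + beta) - lgamma(beta))
  })
  p <- exp(lp - max(lp))
  list(states = states, prob = p / sum(p))
}

# Empirical distribution over assignment states from the sampler trace.
trace_state_freq <- function(trace, states) {
  K <- max(states)
  code <- function(m) as.vector((m - 1) %*% K^(seq_len(ncol(m)) - 1))
  emp <- tabulate(match(code(trace + 1L), code(states)),
                  nbins = nrow(states))
  emp / nrow(trace)
}

# Brute-force upper-tail hypergeometric probability by pmf summation.
bf_hyper_upper <- function(overlap, a, b, N) {
  ks <- overlap:min(a, b)
  sum(choose(a, ks) * choose(N - a, b - ks)) / choose(N, b)
}

# Brute-force optimal assignment over all K! permutations.
bf_best_permutation <- function(sim) {
  K <- nrow(sim)
  perms <- .permutations(K)
  tot <- apply(perms, 1L, function(p) sum(sim[cbind(seq_len(K), p)]))
  list(permutation = perms[which.max(tot), ], total = max(tot))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# Minimal hand-built topic model (for closed-form and tie-break tests).
fake_model <- function(phi, theta = NULL, alpha = 50, beta = 0.1) {
  K <- nrow(phi)
  if (is.null(theta)) {
    theta <- matrix(1 / K, nrow = 2, ncol = K)
  }
  if (is.null(colnames(phi))) {
    colnames(phi) <- sprintf("g%03d", seq_len(ncol(phi)))
  }
  rownames(phi) <- paste0("topic_", seq_len(K))
  if (is.null(rownames(theta))) {
    rownames(theta) <- sprintf("c%03d", seq_len(nrow(theta)))
  }
  colnames(theta) <- rownames(phi)
  structure(list(K = K, alpha = alpha, beta = beta, theta = theta,
                 phi = phi, seed = 1L, iterations = 0L, burn_in = 0L,
                 estimate = "final", vocabulary = colnames(phi),
                 cell_barcodes = rownames(theta), cell_groups = NULL,
                 input_digest = NA_character_),
            class = "topic_model")
}

# Tiny deterministic count matrix.
tiny_counts <- function() {
  m <- matrix(c(1L, 2L, 0L,
                0L, 5L, 3L), nrow = 3)
  count_matrix(m, c("geneA", "geneB", "geneC"), c("cell1", "cell2"))
}

cli_path <- function() {
  system.file("cli", "topicgrad.R", package = "topicgrad")
}

run_cli <- function(...) {
  out <- tempfile()
  err <- tempfile()
  status <- withr::with_envvar(
    c(R_LIBS_USER = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2(file.path(R.home("bin"), "Rscript"),
            c(cli_path(), ...), stdout = out, stderr = err))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
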