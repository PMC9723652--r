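#' Fit a latent Dirichlet allocation topic model by collapsed Gibbs sampling
#'
#' Each cell is a document and each unit of the integer input matrix a token
#' of its gene. The sampler integrates out the cell-topic distributions
#' theta and the topic-gene distributions phi, and resamples per-token topic
#' labels from the full conditional
#' \deqn{P(z_i = k \mid \cdot) \propto (n_{dk}^{-i} + \alpha)\,
#'   \frac{n_{kw}^{-i} + \beta}{n_{k\cdot}^{-i} + G\beta}}
#' where the counts exclude token i. Point estimates are
#' \eqn{\theta_{dk} = (n_{dk} + \alpha) / (n_{d\cdot} + K\alpha)} and
#' \eqn{\phi_{kw} = (n_{kw} + \beta) / (n_{k\cdot} + G\beta)}, taken from
#' the final sweep by default or averaged over thinned post-burn-in sweeps.
#'
#' The symmetric prior `alpha` defaults to 50; set `alpha_by_k = TRUE` for
#' the alternative 50/K convention. Runs are reproducible: the same seed and
#' input give bit-identical theta and phi. Cells with zero tokens are
#' skipped by the sampler and receive a uniform theta row (the prior mean).
#'
#' @param input An `lda_input` from [prepare_lda_input()] or
#'   [as_lda_input()].
#' @param K Number of topics (>= 1).
#' @param alpha Symmetric Dirichlet concentration of per-cell topic
#'   mixtures (default 50).
#' @param beta Symmetric Dirichlet concentration of per-topic gene
#'   distributions (default 0.1).
#' @param iterations Total Gibbs sweeps (default 500).
#' @param burn_in Sweeps discarded before estimation (default
#'   `iterations %/% 2`).
#' @param seed Integer seed for the sampler's RNG.
#' @param alpha_by_k If `TRUE`, use `alpha / K` as the per-topic
#'   concentration.
#' @param estimate `"final"` (default) or `"average"` (mean over every
#'   `thin`-th post-burn-in sweep).
#' @param thin Thinning interval for `estimate = "average"` (default 10).
#' @return A `topic_model`: list with `K`, `alpha`, `beta`, `theta`
#'   (cells x K, rows sum to 1), `phi` (K x genes, rows sum to 1),
#'   `counts_ck`, `counts_kg`, `assignments`, `seed`, `iterations`,
#'   `burn_in`, `vocabulary`, `cell_barcodes`.
#' @export
fit_lda <- function(input, K, alpha = 50, beta = 0.1, iterations = 500L,
                    burn_in = iterations %/% 2L, seed = 1L,
                    alpha_by_k = FALSE, estimate = c("final", "average"),
                    thin = 10L) {
  estimate <- match.arg(estimate)
  stopifnot(inherits(input, "lda_input"))
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (iterations <= burn_in || burn_in < 0) {
    stop("need iterations > burn_in >= 0", call. = FALSE)
  }
  toks <- .expand_tokens(input$matrix)
  if (length(toks$doc) == 0L) {
    stop("input has zero total tokens", call. = FALSE)
  }
  a <- if (alpha_by_k) alpha / K else alpha
  G <- nrow(input$matrix)
  N <- ncol(input$matrix)

  set.seed(seed)
  res <- .gibbs_lda_cpp(toks$doc, toks$word, N, G, as.integer(K),
                        a, beta, as.integer(iterations),
                        as.integer(burn_in),
                        if (estimate == "average") 1L else 0L,
                        as.integer(thin), 0L)
  theta <- res$theta
  empty <- colSums(input$matrix) == 0L
  if (any(empty)) theta[empty, ] <- 1 / K
  dimnames(theta) <- list(input$cell_barcodes, paste0("topic_", seq_len(K)))
  phi <- res$phi
  dimnames(phi) <- list(paste0("topic_", seq_len(K)), input$gene_names)

  structure(list(K = as.integer(K), alpha = a, beta = beta,
                 theta = theta, phi = phi,
                 counts_ck = res$counts_ck, counts_kg = res$counts_kg,
                 assignments = res$assignments,
                 seed = as.integer(seed), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), estimate = estimate,
                 vocabulary = input$gene_names,
                 cell_barcodes = input$cell_barcodes,
                 cell_groups = input$cell_groups,
                 input_digest = .digest_input(input)),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf(
    "topic_model: K=%d, %d cells x %d genes (alpha=%g, beta=%g, seed=%d)\n",
    x$K, nrow(x$theta), ncol(x$phi), x$alpha, x$beta, x$seed))
  invisible(x)
}

# expand the integer matrix into 0-based (doc, word) token vectors
.expand_tokens <- function(m) {
  nz <- which(m > 0L, arr.ind = TRUE)
  cnt <- m[nz]
  list(doc = rep.int(nz[, 2L] - 1L, cnt),
       word = rep.int(nz[, 1L] - 1L, cnt))
}

.digest_input <- function(input) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(as.integer(input$matrix), f)
  unname(tools::md5sum(f))
}

# Raw post-burn-in assignment-state draws on a (tiny) corpus; used to check
# the sampler against the exactly enumerated collapsed posterior.
.lda_state_trace <- function(input, K, alpha, beta, iterations, burn_in,
                             seed, trace_every = 1L) {
  toks <- .expand_tokens(input$matrix)
  set.seed(seed)
  res <- .gibbs_lda_cpp(toks$doc, toks$word, ncol(input$matrix),
                        nrow(input$matrix), as.integer(K), alpha, beta,
                        as.integer(iterations), as.integer(burn_in),
                        0L, 1L, as.integer(trace_every))
  list(trace = res$trace, doc = toks$doc, word = toks$word)
}

#' Log-likelihood of data under a fitted topic model
#'
#' Per-token mixture likelihood: returns
#' \eqn{\sum_d \sum_{i} \ln \sum_k \theta_{dk} \phi_{k w_i}}, summing over
#' every token of every cell. Always <= 0; empty cells contribute 0.
#'
#' @param model A `topic_model`.
#' @param input An `lda_input` over the same vocabulary.
#' @return A single non-positive number.
#' @export
log_likelihood <- function(model, input) {
  stopifnot(inherits(model, "topic_model"), inherits(input, "lda_input"))
  if (!identical(model$vocabulary, input$gene_names)) {
    stop("model and input vocabularies differ", call. = FALSE)
  }
  # p[g, d] = sum_k theta[d, k] * phi[k, g]; weight by token counts
  p <- t(model$phi) %*% t(model$theta)
  sum(input$matrix * log(p))
}
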