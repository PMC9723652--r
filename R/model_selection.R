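#' Perplexity of a topic model on a dataset
#'
#' The exponential of the negative mean per-token log-likelihood,
#' `exp(-L / T)` with `L = log_likelihood(model, input)` and `T` the total
#' token count. Lower is better; a uniform topic-gene model over G genes has
#' perplexity exactly G, and a model that predicts every token with
#' probability 1 approaches 1.
#'
#' @param model A `topic_model`.
#' @param input An `lda_input` over the same vocabulary.
#' @return A single number >= 1 (up to smoothing).
#' @export
perplexity <- function(model, input) {
  stopifnot(inherits(input, "lda_input"))
  tot <- sum(input$matrix)
  if (tot == 0) stop("input has zero total tokens", call. = FALSE)
  exp(-log_likelihood(model, input) / tot)
}

#' Rate of perplexity change across a topic sweep
#'
#' `rpc_i = |P(k_{i+1}) - P(k_i)| / (k_{i+1} - k_i)`: the absolute change in
#' perplexity per added topic, for each adjacent pair of the sweep. Plotted
#' against K this gives the elbow plot used to choose the number of topics.
#'
#' @param k_values Strictly increasing integer vector (length >= 2).
#' @param perplexities Perplexity at each K.
#' @return Non-negative numeric vector of length `length(k_values) - 1`.
#' @export
rpc <- function(k_values, perplexities) {
  if (length(k_values) != length(perplexities) || length(k_values) < 2L) {
    stop("k_values and perplexities must have equal length >= 2",
         call. = FALSE)
  }
  if (any(diff(k_values) <= 0)) {
    stop("k_values must be strictly increasing", call. = FALSE)
  }
  abs(diff(perplexities)) / diff(k_values)
}

#' Select the elbow K from a rate-of-perplexity-change curve
#'
#' Returns the K at the onset of the low plateau. The default `"drop"`
#' method selects the K between the two adjacent RPC values with the largest
#' relative drop `(rpc_i - rpc_{i+1}) / rpc_i`: the point where the RPC
#' collapses onto its plateau. This is robust to the sweep-to-sweep sampler
#' noise that perturbs both the steep region and the plateau. The
#' `"first_plateau"` method instead returns the right endpoint of the first
#' adjacent pair at which the RPC stops decreasing (`rpc_{i+1} >= rpc_i`),
#' falling back to `"drop"` when the RPC decreases everywhere; it locates
#' the plateau onset exactly on noise-free curves but is fragile on sampled
#' ones. An RPC with no decrease anywhere returns the second K with a
#' warning.
#'
#' @param k_values Strictly increasing integer vector (length >= 3).
#' @param rpc_values RPC vector of length `length(k_values) - 1` from
#'   [rpc()].
#' @param method `"drop"` (default) or `"first_plateau"`.
#' @return The selected K (an element of `k_values`).
#' @export
select_elbow <- function(k_values, rpc_values,
                         method = c("drop", "first_plateau")) {
  method <- match.arg(method)
  if (length(k_values) < 3L) {
    stop("need at least 3 k_values to define a plateau", call. = FALSE)
  }
  if (length(rpc_values) != length(k_values) - 1L) {
    stop("length(rpc_values) must be length(k_values) - 1", call. = FALSE)
  }
  d <- diff(rpc_values)
  if (all(d >= 0)) {
    warning("RPC never decreases; no elbow", call. = FALSE)
    return(k_values[2L])
  }
  if (method == "first_plateau") {
    nondec <- which(d >= 0)
    if (length(nondec) > 0L) return(k_values[nondec[1L] + 1L])
  }
  head_rpc <- rpc_values[-length(rpc_values)]
  drops <- ifelse(head_rpc > 0, -d / head_rpc, -Inf)
  k_values[which.max(drops) + 1L]
}

#' Sweep the number of topics and select the elbow K
#'
#' Fits one model per K (with a deterministic per-K seed offset), records
#' training-set perplexities, computes the rate of perplexity change and
#' selects the elbow K via [select_elbow()].
#'
#' @param input An `lda_input`.
#' @param k_values Strictly increasing integers (default `seq(10, 100, 10)`).
#' @param alpha,beta,iterations,burn_in,alpha_by_k Passed to [fit_lda()].
#' @param seed Base seed; model for `k_values[i]` uses `seed + i - 1`.
#' @param keep_models Retain the fitted models in the result (default
#'   FALSE).
#' @return A `model_sweep`: list with `k_values`, `perplexities`, `rpc`,
#'   `selected_k`, `seed` and optionally `models`.
#' @export
sweep_topics <- function(input, k_values = seq(10L, 100L, by = 10L),
                         alpha = 50, beta = 0.1, iterations = 500L,
                         burn_in = iterations %/% 2L, seed = 1L,
                         alpha_by_k = FALSE, keep_models = FALSE) {
  if (length(k_values) < 2L || any(diff(k_values) <= 0)) {
    stop("k_values must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  models <- vector("list", length(k_values))
  perps <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    fit <- tryCatch(
      fit_lda(input, K = k_values[i], alpha = alpha, beta = beta,
              iterations = iterations, burn_in = burn_in,
              seed = seed + i - 1L, alpha_by_k = alpha_by_k),
      error = function(e) {
        stop(sprintf("fit failed at K = %d: %s", k_values[i],
                     conditionMessage(e)), call. = FALSE)
      })
    perps[i] <- perplexity(fit, input)
    if (keep_models) models[[i]] <- fit
  }
  r <- rpc(k_values, perps)
  sel <- if (length(k_values) >= 3L) select_elbow(k_values, r) else
    k_values[2L]
  structure(list(k_values = as.integer(k_values), perplexities = perps,
                 rpc = r, selected_k = as.integer(sel), seed = seed,
                 models = if (keep_models) models else NULL),
            class = "model_sweep")
}

#' @export
print.model_sweep <- function(x, ...) {
  cat(sprintf("model_sweep over K = %s; selected K = %d\n",
              paste(x$k_values, collapse = ","), x$selected_k))
  invisible(x)
}

#' Export a sweep as an elbow-plot-ready table
#'
#' @param sweep A `model_sweep`.
#' @param path Optional TSV path; if given, the table is written there.
#' @return A data.frame with columns `k`, `perplexity`, `rpc` (RPC is NA for
#'   the first K).
#' @export
sweep_table <- function(sweep, path = NULL) {
  stopifnot(inherits(sweep, "model_sweep"))
  df <- data.frame(k = sweep$k_values, perplexity = sweep$perplexities,
                   rpc = c(NA_real_, sweep$rpc))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
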