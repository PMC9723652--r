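#' Top-gene signature of a topic
#'
#' The `n` genes with the highest topic-gene probability phi for a topic,
#' in descending order; ties are broken lexicographically by gene name so
#' the signature is a deterministic function of phi.
#'
#' @param model A `topic_model`.
#' @param topic Topic index in `1..K`.
#' @param n Signature size (default 50, capped at the vocabulary size).
#' @return A `gene_signature`: list with `topic_id`, ordered `genes` and
#'   their `scores` (phi values).
#' @export
top_genes <- function(model, topic, n = 50L) {
  stopifnot(inherits(model, "topic_model"))
  if (length(topic) != 1L || topic < 1 || topic > model$K) {
    stop("topic must be in 1..K", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  row <- model$phi[topic, ]
  genes <- colnames(model$phi)
  ord <- order(-row, genes)
  take <- seq_len(min(n, length(row)))
  structure(list(topic_id = as.integer(topic),
                 genes = genes[ord][take],
                 scores = unname(row[ord][take])),
            class = "gene_signature")
}

#' Z-normalized cell-topic scores
#'
#' Standardizes each topic's theta column across cells (sample standard
#' deviation), yielding per-cell topic activities comparable across topics.
#' Constant columns are returned as zeros with a warning.
#'
#' @param model A `topic_model` fitted on more than one cell.
#' @return A `cell_score_table`: list with `scores` (cells x K),
#'   `score_kind = "z_theta"` and `group_labels`.
#' @export
normalize_cell_scores <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  n <- nrow(model$theta)
  if (n < 2L) stop("need more than one cell to z-score", call. = FALSE)
  z <- apply(model$theta, 2L, function(col) {
    s <- stats::sd(col)
    if (s == 0) {
      warning("constant theta column; z-scores set to 0", call. = FALSE)
      rep(0, n)
    } else {
      (col - mean(col)) / s
    }
  })
  dimnames(z) <- dimnames(model$theta)
  structure(list(scores = z, score_kind = "z_theta",
                 group_labels = model$cell_groups),
            class = "cell_score_table")
}

#' @export
print.cell_score_table <- function(x, ...) {
  cat(sprintf("cell_score_table (%s): %d cells x %d columns\n",
              x$score_kind, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Binned-control gene signature score
#'
#' Module-score style scoring: for each cell, the mean log-normalized
#' expression of the signature genes minus the mean over control genes.
#' Genes are binned into `n_bins` equal-frequency bins of average
#' expression, and `n_ctrl` control genes are drawn (with replacement) from
#' the bin of each signature gene, so the control pool matches the
#' signature's expression profile. Counts are library-size normalized to the
#' median depth and log1p transformed. Signature genes absent from the data
#' are dropped with a warning.
#'
#' @param counts A [count_matrix] of raw counts.
#' @param signature Character vector of signature genes.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Seed for control sampling.
#' @return Named numeric vector: one score per cell.
#' @export
signature_score <- function(counts, signature, n_bins = 25L, n_ctrl = 100L,
                            seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  signature <- unique(trimws(signature))
  present <- signature[signature %in% counts$gene_names]
  if (length(present) == 0L) {
    stop("no signature gene present in the data", call. = FALSE)
  }
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present),
            " signature gene(s) absent from the data; dropped",
            call. = FALSE)
  }
  expr <- .log_normalize(counts$counts)
  avg <- Matrix::rowMeans(expr)
  n_bins <- min(n_bins, length(avg))
  # equal-frequency bins of average expression
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = n_bins, labels = FALSE,
                         include.lowest = TRUE))
  names(bins) <- counts$gene_names

  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- counts$gene_names[bins == bins[[g]]]
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }), use.names = FALSE)

  sig_mean <- Matrix::colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- counts$cell_barcodes
  out
}

# library-size normalize to the median depth, then log1p
.log_normalize <- function(m) {
  depth <- Matrix::colSums(m)
  target <- stats::median(depth[depth > 0])
  sf <- ifelse(depth > 0, target / depth, 0)
  log1p(m %*% Matrix::Diagonal(x = sf))
}

#' Transfer topics onto a new dataset
#'
#' Scores each source topic on the cells of a target dataset: the topic's
#' top-`n` gene signature is evaluated with [signature_score()] on the raw
#' target counts. Topics whose signature shares no gene with the target are
#' dropped with a warning.
#'
#' @param source A fitted `topic_model`.
#' @param target A [count_matrix] (the new dataset).
#' @param n Signature size per topic (default 50).
#' @param n_bins,n_ctrl Passed to [signature_score()].
#' @param seed Seed for control-gene sampling.
#' @return A `cell_score_table` with one column per retained source topic
#'   and `score_kind = "signature"`.
#' @export
transfer_topics <- function(source, target, n = 50L, n_bins = 25L,
                            n_ctrl = 100L, seed = 1L) {
  stopifnot(inherits(source, "topic_model"),
            inherits(target, "count_matrix"))
  cols <- list()
  for (k in seq_len(source$K)) {
    sig <- top_genes(source, k, n)$genes
    if (!any(sig %in% target$gene_names)) {
      warning("topic ", k, " shares no signature gene with the target; ",
              "dropped", call. = FALSE)
      next
    }
    cols[[paste0("topic_", k)]] <- suppressWarnings(
      signature_score(target, sig, n_bins = n_bins, n_ctrl = n_ctrl,
                      seed = seed + k))
  }
  scores <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(target$cell_barcodes), ncol = 0,
           dimnames = list(target$cell_barcodes, NULL))
  structure(list(scores = scores, score_kind = "signature",
                 group_labels = target$cell_groups),
            class = "cell_score_table")
}

#' Gene overlap between the topics of two models
#'
#' Entry (i, j) counts the genes shared by the top-`n` signature of topic i
#' of `model_a` and topic j of `model_b`; a model compared against itself
#' has `n` on the diagonal.
#'
#' @param model_a,model_b Fitted `topic_model` objects.
#' @param n Signature size (default 50).
#' @return A `K_a` x `K_b` integer matrix.
#' @export
topic_overlap <- function(model_a, model_b, n = 50L) {
  stopifnot(inherits(model_a, "topic_model"),
            inherits(model_b, "topic_model"))
  sigs_a <- lapply(seq_len(model_a$K), function(k) top_genes(model_a, k, n)$genes)
  sigs_b <- lapply(seq_len(model_b$K), function(k) top_genes(model_b, k, n)$genes)
  out <- matrix(0L, model_a$K, model_b$K,
                dimnames = list(rownames(model_a$phi), rownames(model_b$phi)))
  for (i in seq_len(model_a$K)) {
    for (j in seq_len(model_b$K)) {
      out[i, j] <- length(intersect(sigs_a[[i]], sigs_b[[j]]))
    }
  }
  out
}

#' Delta-control Z-score of per-cell scores
#'
#' Quantifies treatment response against a baseline condition: the scores
#' are z-scored across all cells and the median z of the control-label
#' cells is subtracted, so control cells have median delta exactly 0 and
#' responding groups shift away from it. Invariant to affine transformation
#' of the input scores.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param groups Per-cell group labels (same length).
#' @param control_label The label of the baseline group.
#' @return Numeric vector of per-cell deltas (names preserved).
#' @export
delta_control_zscore <- function(scores, groups, control_label) {
  if (length(scores) != length(groups)) {
    stop("scores and groups must have the same length", call. = FALSE)
  }
  if (!control_label %in% groups) {
    stop("control label '", control_label, "' not present in groups",
         call. = FALSE)
  }
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    stop("scores have zero variance", call. = FALSE)
  }
  z <- (scores - mean(scores)) / s
  z - stats::median(z[groups == control_label])
}
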