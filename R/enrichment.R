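#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `overlap` shared genes between a set of
#' size `set_a_size` and an independent draw of `set_b_size` genes from a
#' universe of `universe_size` genes: `P(X >= overlap)` with X
#' hypergeometric. Computed with [stats::phyper()]; `overlap = 0` gives
#' exactly 1.
#'
#' @param overlap Observed intersection size.
#' @param set_a_size,set_b_size Sizes of the two gene sets within the
#'   universe.
#' @param universe_size Total number of genes considered.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(overlap, set_a_size, set_b_size,
                             universe_size) {
  if (any(c(overlap, set_a_size, set_b_size, universe_size) < 0) ||
      set_a_size > universe_size || set_b_size > universe_size ||
      overlap > min(set_a_size, set_b_size) ||
      overlap < max(0, set_a_size + set_b_size - universe_size)) {
    stop("inconsistent hypergeometric sizes", call. = FALSE)
  }
  stats::phyper(overlap - 1, set_a_size, universe_size - set_a_size,
                set_b_size, lower.tail = FALSE)
}

#' Hypergeometric enrichment of topic signatures in gene sets
#'
#' For every (topic, gene set) pair: restricts the set to the gene universe,
#' counts its overlap with the topic's top-`n` signature, and computes the
#' upper-tail hypergeometric p-value. P-values are Benjamini-Hochberg
#' adjusted across all pairs. Each topic's top factor is the set with the
#' smallest raw p-value (ties: larger overlap, then set name).
#'
#' @param model A fitted `topic_model`.
#' @param sets A `gene_set_collection` from [read_gene_sets()] (or a named
#'   list of character vectors).
#' @param n Signature size (default 50).
#' @param universe `"dataset"` (default: the model vocabulary) or
#'   `"intersection"` (vocabulary restricted to genes annotated in any set).
#' @return A data.frame of class `enrichment_table` with columns `topic_id`,
#'   `set_name`, `overlap`, `signature_size`, `set_size_in_universe`,
#'   `universe_size`, `p_value`, `adjusted_p`; per-topic top factors are in
#'   `attr(, "top_factors")`.
#' @export
enrich_topics <- function(model, sets, n = 50L,
                          universe = c("dataset", "intersection")) {
  universe <- match.arg(universe)
  stopifnot(inherits(model, "topic_model"))
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named", call. = FALSE)
  }
  vocab <- model$vocabulary
  univ <- switch(universe,
                 dataset = vocab,
                 intersection = intersect(vocab,
                                          unique(unlist(sets,
                                                        use.names = FALSE))))
  if (length(univ) == 0L) stop("empty gene universe", call. = FALSE)

  sets_u <- lapply(sets, function(s) intersect(unique(trimws(s)), univ))
  rows <- list()
  for (k in seq_len(model$K)) {
    sig <- intersect(top_genes(model, k, n)$genes, univ)
    for (s in names(sets_u)) {
      ov <- length(intersect(sig, sets_u[[s]]))
      p <- if (length(sig) == 0L || length(sets_u[[s]]) == 0L) 1 else
        hypergeom_pvalue(ov, length(sets_u[[s]]), length(sig),
                         length(univ))
      rows[[length(rows) + 1L]] <- data.frame(
        topic_id = k, set_name = s, overlap = ov,
        signature_size = length(sig),
        set_size_in_universe = length(sets_u[[s]]),
        universe_size = length(univ), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- stats::p.adjust(tab$p_value, method = "BH")

  top_factors <- vapply(seq_len(model$K), function(k) {
    sub <- tab[tab$topic_id == k, ]
    sub <- sub[order(sub$p_value, -sub$overlap, sub$set_name), ]
    sub$set_name[1L]
  }, character(1L))
  names(top_factors) <- rownames(model$phi)
  attr(tab, "top_factors") <- top_factors
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
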