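#' Select highly variable genes
#'
#' Ranks genes by the variance of their clipped, standardized counts under a
#' mean-variance trend: the expected variance of each gene is taken from a
#' local (loess) regression of log10 variance on log10 mean, counts are
#' standardized by the expected standard deviation, clipped at sqrt(N), and
#' genes are ranked by the variance of the clipped values. Ties are broken
#' by gene name so the ranking is fully deterministic.
#'
#' @param counts A [count_matrix].
#' @param n_features Number of genes to return (default 5000); capped at the
#'   number of genes present.
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @return Character vector of at most `n_features` gene names, most
#'   variable first.
#' @export
select_variable_genes <- function(counts, n_features = 5000L,
                                  loess_span = 0.3) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(n_features) != 1L || n_features <= 0) {
    stop("n_features must be a positive integer", call. = FALSE)
  }
  m <- counts$counts
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  # E[x^2] - mu^2, with the n/(n-1) sample correction
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / max(n - 1L, 1L)
  v[v < 0] <- 0

  std_var <- numeric(length(mu))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 10L && n > 1L) {
    lx <- log10(mu[ok])
    ly <- log10(v[ok])
    exp_sd <- numeric(length(mu))
    if (stats::sd(lx) < 0.05) {
      # means (nearly) equal: the trend is a constant, and a local fit on
      # degenerate x would chase noise in y
      exp_sd[ok] <- sqrt(10^mean(ly))
    } else {
      fit <- stats::loess(ly ~ lx, span = loess_span, degree = 2)
      exp_sd[ok] <- sqrt(10^stats::fitted(fit))
    }
    clip <- sqrt(n)
    tm <- methods::as(m, "TsparseMatrix")
    gi <- tm@i + 1L
    keep <- ok[gi]
    gi <- gi[keep]
    xv <- tm@x[keep]
    z_nz <- pmin(pmax((xv - mu[gi]) / exp_sd[gi], -clip), clip)
    # zeros contribute z = -mu/sd each, clipped
    z0 <- pmin(mu[ok] / exp_sd[ok], clip)
    nnz <- tabulate(gi, nbins = length(mu))[ok]
    ssq <- unname(tapply(z_nz^2, factor(gi, levels = which(ok)), sum,
                         default = 0))
    std_var[ok] <- (ssq + (n - nnz) * z0^2) / (n - 1L)
  } else {
    # too few informative genes for a trend: fall back to dispersion
    std_var[ok] <- v[ok] / mu[ok]
  }
  ord <- order(-std_var, counts$gene_names)
  counts$gene_names[ord][seq_len(min(n_features, length(mu)))]
}

#' Centered log-ratio transform
#'
#' CLR maps a composition onto ratios against its geometric mean:
#' `CLR(x)_i = ln((x_i + c) / g(x + c))` with
#' `g(y) = (y_1 ... y_G)^(1/G)`. The pseudo-count `c` is added to every
#' component before taking logs so zero counts are defined. Components of
#' the result sum to zero, and on strictly positive input with `c = 0` the
#' transform is invariant to rescaling of `x` (sequencing depth).
#'
#' @param x Non-negative numeric vector (one cell's counts over genes).
#' @param pseudo_count Non-negative shift added to each component
#'   (default 1); must be positive if `x` contains zeros.
#' @return Numeric vector of the same length, summing to zero.
#' @export
clr_transform <- function(x, pseudo_count = 1) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    stop("x must be a finite numeric vector", call. = FALSE)
  }
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  if (pseudo_count < 0) stop("pseudo_count must be >= 0", call. = FALSE)
  y <- x + pseudo_count
  if (any(y <= 0)) {
    stop("zero components require a positive pseudo_count", call. = FALSE)
  }
  ly <- log(y)
  ly - mean(ly)
}

#' Prepare the LDA input from raw counts
#'
#' For each cell: subset the counts to the selected vocabulary, apply
#' [clr_transform()], clamp negative CLR values (genes below the cell's
#' geometric mean) to zero, multiply by `scale_factor`, and round half away
#' from zero to the nearest integer. The result is the non-negative integer
#' "pseudo-count" matrix that the collapsed Gibbs sampler treats as a bag
#' of words. Cells whose whole row rounds to zero are retained but flagged.
#'
#' @param counts A [count_matrix].
#' @param genes Vocabulary: a non-empty subset of `counts$gene_names`
#'   (defaults to all genes).
#' @param scale_factor Positive multiplier applied to the clamped CLR values
#'   (default 10).
#' @param pseudo_count Shift used inside the CLR transform (default 1).
#' @return An `lda_input`: list with integer `matrix` (genes x cells),
#'   `gene_names`, `cell_barcodes`, `cell_groups`, `scale_factor`,
#'   `pseudo_count` and logical `flagged` marking all-zero cells.
#' @export
prepare_lda_input <- function(counts, genes = counts$gene_names,
                              scale_factor = 10, pseudo_count = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  if (!all(genes %in% counts$gene_names)) {
    stop("genes must be a subset of counts$gene_names", call. = FALSE)
  }
  if (scale_factor <= 0) stop("scale_factor must be positive", call. = FALSE)
  m <- as.matrix(counts$counts[genes, , drop = FALSE])
  ly <- log(m + pseudo_count)
  clr <- sweep(ly, 2L, colMeans(ly), "-")
  clr[clr < 0] <- 0
  out <- floor(clr * scale_factor + 0.5) # half away from zero (all >= 0)
  storage.mode(out) <- "integer"
  flagged <- colSums(out) == 0L
  if (any(flagged)) {
    warning(sum(flagged), " cell(s) have an all-zero row after the CLR ",
            "transform and are flagged", call. = FALSE)
  }
  structure(list(matrix = out, gene_names = genes,
                 cell_barcodes = counts$cell_barcodes,
                 cell_groups = counts$cell_groups,
                 scale_factor = scale_factor, pseudo_count = pseudo_count,
                 flagged = flagged),
            class = "lda_input")
}

#' Treat raw counts directly as the LDA bag of words
#'
#' Bypasses the CLR step: each unit of each count is one token. Useful when
#' the input is already a token-count matrix, e.g. a simulated
#' Dirichlet-multinomial corpus.
#'
#' @param counts A [count_matrix].
#' @param genes Optional vocabulary subset (default: all genes).
#' @return An `lda_input`.
#' @export
as_lda_input <- function(counts, genes = counts$gene_names) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  if (!all(genes %in% counts$gene_names)) {
    stop("genes must be a subset of counts$gene_names", call. = FALSE)
  }
  m <- as.matrix(counts$counts[genes, , drop = FALSE])
  storage.mode(m) <- "integer"
  structure(list(matrix = m, gene_names = genes,
                 cell_barcodes = counts$cell_barcodes,
                 cell_groups = counts$cell_groups,
                 scale_factor = NA_real_, pseudo_count = NA_real_,
                 flagged = colSums(m) == 0L),
            class = "lda_input")
}

#' @export
print.lda_input <- function(x, ...) {
  cat(sprintf("lda_input: %d genes x %d cells, %d tokens (%d cell(s) flagged)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix),
              sum(x$flagged)))
  invisible(x)
}

#' Write an LDA input matrix as dense TSV
#'
#' @param input An `lda_input`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lda_input <- function(input, path) {
  stopifnot(inherits(input, "lda_input"))
  df <- as.data.frame(input$matrix, check.names = FALSE)
  colnames(df) <- input$cell_barcodes
  df <- cbind(gene = input$gene_names, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LDA input matrix from dense TSV
#'
#' @param path TSV written by [write_lda_input()] (first column gene names,
#'   header row barcodes).
#' @return An `lda_input`.
#' @export
read_lda_input <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  structure(list(matrix = m, gene_names = as.character(df[[1L]]),
                 cell_barcodes = colnames(df)[-1L], cell_groups = NULL,
                 scale_factor = NA_real_, pseudo_count = NA_real_,
                 flagged = colSums(m) == 0L),
            class = "lda_input")
}
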