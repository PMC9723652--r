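#' Construct a gene-by-cell count matrix
#'
#' The central container for raw expression data: a genes x cells matrix of
#' non-negative integer counts with unique gene names, unique cell barcodes,
#' and optional per-cell group labels (e.g. treatment or time point).
#'
#' @param counts A genes x cells matrix (dense or \pkg{Matrix} sparse) of
#'   non-negative integer counts.
#' @param gene_names Character vector of unique gene identifiers, one per row.
#' @param cell_barcodes Character vector of unique cell barcodes, one per
#'   column.
#' @param cell_groups Optional character vector of per-cell group labels
#'   (same length as `cell_barcodes`).
#' @return An object of class `count_matrix` with elements `counts` (a
#'   `dgCMatrix`), `gene_names`, `cell_barcodes` and `cell_groups`.
#' @export
count_matrix <- function(counts, gene_names = rownames(counts),
                         cell_barcodes = colnames(counts),
                         cell_groups = NULL) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_names) || is.null(cell_barcodes)) {
    stop("gene_names and cell_barcodes are required", call. = FALSE)
  }
  gene_names <- as.character(gene_names)
  cell_barcodes <- as.character(cell_barcodes)
  if (length(gene_names) != nrow(counts)) {
    stop("length(gene_names) != nrow(counts)", call. = FALSE)
  }
  if (length(cell_barcodes) != ncol(counts)) {
    stop("length(cell_barcodes) != ncol(counts)", call. = FALSE)
  }
  if (anyDuplicated(gene_names)) {
    stop("gene_names must be unique", call. = FALSE)
  }
  if (anyDuplicated(cell_barcodes)) {
    stop("cell_barcodes must be unique", call. = FALSE)
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(cell_groups)) {
    cell_groups <- as.character(cell_groups)
    if (length(cell_groups) != length(cell_barcodes)) {
      stop("cell_groups must have exactly one label per barcode",
           call. = FALSE)
    }
  }
  dimnames(counts) <- list(gene_names, cell_barcodes)
  structure(list(counts = counts, gene_names = gene_names,
                 cell_barcodes = cell_barcodes, cell_groups = cell_groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$cell_groups)) {
    tab <- table(x$cell_groups)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports the 10x-style Matrix Market layout (a directory holding
#' `matrix.mtx`, `features.tsv` and `barcodes.tsv`, genes in rows) and a
#' dense TSV (first column gene names, header row barcodes).
#'
#' @param path Directory (for `mtx_dir`) or file (for `dense_tsv`).
#' @param format One of `"mtx_dir"` or `"dense_tsv"`.
#' @param metadata Optional path to a headerless two-column TSV mapping cell
#'   barcode to group label; labels are attached as `cell_groups`.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv"),
                        metadata = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
    mtx <- .find_one(path, c("matrix.mtx", "matrix.mtx.gz"))
    feat <- .find_one(path, c("features.tsv", "genes.tsv", "features.tsv.gz",
                              "genes.tsv.gz"))
    bc <- .find_one(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    m <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)
    if (nrow(features) != nrow(m)) {
      stop(sprintf("matrix declares %d genes but features file has %d rows",
                   nrow(m), nrow(features)), call. = FALSE)
    }
    if (nrow(barcodes) != ncol(m)) {
      stop(sprintf("matrix declares %d cells but barcodes file has %d rows",
                   ncol(m), nrow(barcodes)), call. = FALSE)
    }
    gene_names <- features[[min(2L, ncol(features))]]
    if (anyDuplicated(gene_names)) gene_names <- features[[1L]]
    cm <- count_matrix(m, gene_names, barcodes[[1L]])
  } else {
    if (!file.exists(path) || dir.exists(path)) {
      stop("not a file: ", path, call. = FALSE)
    }
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("non-numeric entries in dense TSV", call. = FALSE)
    cm <- count_matrix(m, df[[1L]], colnames(df)[-1L])
  }
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, header = FALSE,
                            stringsAsFactors = FALSE)
    groups <- md[[2L]][match(cm$cell_barcodes, md[[1L]])]
    if (anyNA(groups)) {
      stop("metadata is missing labels for some barcodes", call. = FALSE)
    }
    cm$cell_groups <- as.character(groups)
  }
  cm
}

.find_one <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing ", candidates[1L], " in ", dir, call. = FALSE)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `mtx_dir` writes `matrix.mtx`,
#' `features.tsv` and `barcodes.tsv` into `path`, `dense_tsv` writes a
#' single TSV.
#'
#' @param x A [count_matrix].
#' @param path Output directory (`mtx_dir`) or file (`dense_tsv`).
#' @param format One of `"mtx_dir"` or `"dense_tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_matrix"))
  if (format == "mtx_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(x$gene_names, x$gene_names, "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(x$cell_barcodes, file.path(path, "barcodes.tsv"))
    if (!is.null(x$cell_groups)) {
      utils::write.table(
        data.frame(x$cell_barcodes, x$cell_groups),
        file.path(path, "groups.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    }
  } else {
    df <- as.data.frame(as.matrix(x$counts), check.names = FALSE)
    df <- cbind(gene = x$gene_names, df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each tab-separated line holds a set name, a description and the member
#' genes. Member genes are whitespace-stripped and deduplicated within a
#' set; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class `gene_set_collection`;
#'   set descriptions are kept in the `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    g <- unique(trimws(f[-(1:2)]))
    g[nzchar(g)]
  })
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s) in GMT file", call. = FALSE)
  }
  names(sets) <- nms
  structure(sets, descriptions = vapply(fields, `[[`, "", 2L),
            class = c("gene_set_collection", "list"))
}

#' Write a fitted topic model to a directory
#'
#' Writes the cell-topic matrix theta (cells x K), the topic-gene matrix phi
#' (K x genes), the per-topic top-gene lists, and a JSON run manifest
#' recording K, the priors, seed, iteration counts and an input digest.
#' Values are serialized with 6 significant digits; [read_model()] restores
#' them exactly at that precision.
#'
#' @param model A `topic_model` from [fit_lda()].
#' @param out_dir Output directory (created if missing).
#' @param n_top Number of top genes per topic to list (default 50).
#' @return `out_dir`, invisibly.
#' @export
write_model <- function(model, out_dir, n_top = 50L) {
  stopifnot(inherits(model, "topic_model"))
  if (file.exists(out_dir) && !dir.exists(out_dir)) {
    stop("out_dir is an existing file: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(m) {
    d <- dimnames(m)
    m <- matrix(sprintf("%.6g", m), nrow = nrow(m), dimnames = d)
    m
  }
  theta <- fmt(model$theta)
  utils::write.table(
    cbind(barcode = model$cell_barcodes, as.data.frame(theta)),
    file.path(out_dir, "theta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  phi <- fmt(model$phi)
  utils::write.table(
    cbind(topic = rownames(model$phi), as.data.frame(phi)),
    file.path(out_dir, "phi.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  n_top <- min(n_top, ncol(model$phi))
  tops <- do.call(rbind, lapply(seq_len(model$K), function(k) {
    sig <- top_genes(model, k, n_top)
    data.frame(topic = k, rank = seq_along(sig$genes), gene = sig$genes)
  }))
  utils::write.table(tops, file.path(out_dir, "top_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(K = model$K, alpha = model$alpha, beta = model$beta,
                   seed = model$seed, iterations = model$iterations,
                   burn_in = model$burn_in, estimate = model$estimate,
                   n_cells = nrow(model$theta), n_genes = ncol(model$phi),
                   input_digest = model$input_digest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a topic model written by [write_model()]
#'
#' @param dir Directory written by [write_model()].
#' @return A `topic_model` with theta, phi and the manifest metadata (the
#'   sampler count tables are not serialized).
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  th <- utils::read.delim(file.path(dir, "theta.tsv"), check.names = FALSE)
  ph <- utils::read.delim(file.path(dir, "phi.tsv"), check.names = FALSE)
  theta <- as.matrix(th[, -1L, drop = FALSE])
  rownames(theta) <- th[[1L]]
  phi <- as.matrix(ph[, -1L, drop = FALSE])
  rownames(phi) <- ph[[1L]]
  structure(list(K = manifest$K, alpha = manifest$alpha,
                 beta = manifest$beta, theta = theta, phi = phi,
                 counts_ck = NULL, counts_kg = NULL, assignments = NULL,
                 seed = manifest$seed, iterations = manifest$iterations,
                 burn_in = manifest$burn_in, estimate = manifest$estimate,
                 vocabulary = colnames(phi),
                 cell_barcodes = rownames(theta),
                 input_digest = manifest$input_digest),
            class = "topic_model")
}
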