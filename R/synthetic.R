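#' Simulate a Dirichlet-multinomial corpus with planted topics
#'
#' Generates counts from the LDA generative process: each topic's gene
#' distribution phi_k is drawn from Dirichlet_G(beta_gen) and blended with a
#' disjoint anchor block (a fraction `anchor_strength` of the topic's mass
#' spread uniformly over its `floor(G/K)` anchor genes), each cell's topic
#' mixture theta_d is drawn from Dirichlet_K(alpha_gen), and each of the
#' `depth` tokens of a cell picks a topic from theta_d and then a gene from
#' that topic's phi. Anchor blocks make the planted topics identifiable, so
#' recovery of phi and of the anchor genes can be asserted.
#'
#' @param n_cells,n_genes,n_topics Corpus dimensions (defaults 500, 200, 5).
#' @param alpha_gen Dirichlet concentration of the true cell-topic mixtures
#'   (default 1: uniform over the simplex, giving both dominant-topic and
#'   mixed cells).
#' @param beta_gen Dirichlet concentration of the topic-gene base
#'   distributions (default 0.1, mirroring the sparse topic prior used when
#'   fitting).
#' @param depth Tokens per cell (default 500, fixed).
#' @param anchor_strength Fraction of each topic's mass placed on its anchor
#'   block, in `[0, 1)` (default 0.5).
#' @param seed Integer seed; fixed seed gives a bit-identical corpus.
#' @return List with `counts` (a [count_matrix]) and `truth` (a
#'   `synthetic_truth`: `theta_true` N x K, `phi_true` K x G,
#'   `anchor_genes` per topic, `group_labels`, `depth`, `seed`).
#' @export
generate_lda_corpus <- function(n_cells = 500L, n_genes = 200L,
                                n_topics = 5L, alpha_gen = 1,
                                beta_gen = 0.1, depth = 500L,
                                anchor_strength = 0.5, seed = 1L) {
  if (min(n_cells, n_genes, n_topics) < 1L) {
    stop("all sizes must be >= 1", call. = FALSE)
  }
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (anchor_strength < 0 || anchor_strength >= 1) {
    stop("anchor_strength must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  gene_names <- sprintf("gene%03d", seq_len(n_genes))
  block <- n_genes %/% n_topics

  phi <- .rdirichlet(n_topics, rep(beta_gen, n_genes))
  anchor_genes <- vector("list", n_topics)
  if (block >= 1L && anchor_strength > 0) {
    for (k in seq_len(n_topics)) {
      idx <- ((k - 1L) * block + 1L):(k * block)
      anchor <- numeric(n_genes)
      anchor[idx] <- 1 / block
      phi[k, ] <- (1 - anchor_strength) * phi[k, ] +
        anchor_strength * anchor
      anchor_genes[[k]] <- gene_names[idx]
    }
  } else {
    anchor_genes <- lapply(seq_len(n_topics), function(k) character(0))
  }
  theta <- .rdirichlet(n_cells, rep(alpha_gen, n_topics))

  counts <- .sample_corpus(theta, phi, depth)
  dimnames(counts) <- NULL
  cm <- count_matrix(counts, gene_names,
                     sprintf("cell%04d", seq_len(n_cells)))
  truth <- structure(list(theta_true = theta, phi_true = phi,
                          anchor_genes = anchor_genes,
                          gene_names = gene_names,
                          group_labels = NULL, depth = depth, seed = seed),
                     class = "synthetic_truth")
  list(counts = cm, truth = truth)
}

#' Simulate a labeled treatment-response gradient
#'
#' Emulates a time-course design: cells carry ordered group labels (e.g.
#' control, 3h, 12h, ...) and the planted mass of the effect topic(s) ramps
#' up across the group order. For a cell in group g, a mass
#' `effect_ramp[g]` (split across the effect topics) is added to the effect
#' topics and the remaining topics are renormalized to the leftover mass, so
#' group mean effect-topic theta exceeds the baseline by the ramp value up
#' to Dirichlet noise. A zero ramp makes the groups exchangeable.
#'
#' @param n_per_group Cells per group.
#' @param groups Ordered character vector of group labels (length >= 2).
#' @param effect_topics Integer indices of the ramping topics (default 1).
#' @param effect_ramp Numeric vector, one added-mass value per group,
#'   non-decreasing for a monotone gradient; values in `[0, 1)`.
#' @param n_genes,n_topics,alpha_gen,beta_gen,depth,anchor_strength As in
#'   [generate_lda_corpus()].
#' @param seed Integer seed.
#' @return List with `counts` (labeled [count_matrix]) and `truth`
#'   (`synthetic_truth` with `group_labels`).
#' @export
generate_response_gradient <- function(n_per_group = 100L,
                                       groups = c("control", "t24h",
                                                  "t48h", "t72h"),
                                       effect_topics = 1L,
                                       effect_ramp = c(0, 0.1, 0.2, 0.3),
                                       n_genes = 200L, n_topics = 5L,
                                       alpha_gen = 1, beta_gen = 0.1,
                                       depth = 500L, anchor_strength = 0.5,
                                       seed = 1L) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(effect_ramp) != length(groups)) {
    stop("effect_ramp must have one value per group", call. = FALSE)
  }
  if (any(effect_ramp < 0) || any(effect_ramp >= 1)) {
    stop("effect_ramp values must be in [0, 1)", call. = FALSE)
  }
  if (any(effect_topics < 1L) || any(effect_topics > n_topics)) {
    stop("effect_topics out of range", call. = FALSE)
  }
  base <- generate_lda_corpus(n_cells = n_per_group * length(groups),
                              n_genes = n_genes, n_topics = n_topics,
                              alpha_gen = alpha_gen, beta_gen = beta_gen,
                              depth = depth,
                              anchor_strength = anchor_strength,
                              seed = seed)
  theta <- base$truth$theta_true
  labels <- rep(groups, each = n_per_group)

  for (g in seq_along(groups)) {
    r <- effect_ramp[g]
    if (r == 0) next
    rows <- which(labels == groups[g])
    add <- r / length(effect_topics)
    for (d in rows) {
      th <- theta[d, ]
      eff <- pmin(th[effect_topics] + add, 0.999)
      rest <- setdiff(seq_len(n_topics), effect_topics)
      leftover <- 1 - sum(eff)
      th[rest] <- if (sum(th[rest]) > 0) th[rest] * leftover / sum(th[rest])
      else leftover / length(rest)
      th[effect_topics] <- eff
      theta[d, ] <- th
    }
  }
  # resample counts under the adjusted mixtures (same seed-derived stream)
  counts <- .sample_corpus(theta, base$truth$phi_true, depth)
  cm <- count_matrix(counts, base$counts$gene_names,
                     base$counts$cell_barcodes, cell_groups = labels)
  truth <- base$truth
  truth$theta_true <- theta
  truth$group_labels <- labels
  list(counts = cm, truth = truth)
}

#' Draw a twin corpus from an existing planted truth
#'
#' Samples a new set of cells (fresh theta draws) from the same planted
#' topic-gene distributions, e.g. as a transfer target whose ground-truth
#' mixtures are known.
#'
#' @param truth A `synthetic_truth` from [generate_lda_corpus()].
#' @param n_cells Number of new cells.
#' @param alpha_gen Dirichlet concentration for the new theta draws.
#' @param depth Tokens per cell (default: the truth's depth).
#' @param seed Integer seed.
#' @return List with `counts` and `truth` (sharing `phi_true` and
#'   `anchor_genes` with the source).
#' @export
twin_corpus <- function(truth, n_cells = 300L, alpha_gen = 1,
                        depth = truth$depth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  K <- nrow(truth$phi_true)
  G <- ncol(truth$phi_true)
  theta <- .rdirichlet(n_cells, rep(alpha_gen, K))
  counts <- .sample_corpus(theta, truth$phi_true, depth)
  gene_names <- if (!is.null(truth$gene_names)) truth$gene_names else
    sprintf("gene%03d", seq_len(G))
  cm <- count_matrix(counts, gene_names,
                     sprintf("twin%04d", seq_len(n_cells)))
  new_truth <- truth
  new_truth$theta_true <- theta
  new_truth$group_labels <- NULL
  new_truth$seed <- seed
  list(counts = cm, truth = new_truth)
}

# token-wise sampling, vectorized per cell: z ~ theta_d, w ~ phi_z
.sample_corpus <- function(theta, phi, depth) {
  n_cells <- nrow(theta)
  n_genes <- ncol(phi)
  n_topics <- ncol(theta)
  counts <- matrix(0L, n_genes, n_cells)
  for (d in seq_len(n_cells)) {
    z <- sample.int(n_topics, depth, replace = TRUE, prob = theta[d, ])
    nz <- tabulate(z, nbins = n_topics)
    col <- integer(n_genes)
    for (k in which(nz > 0L)) {
      w <- sample.int(n_genes, nz[k], replace = TRUE, prob = phi[k, ])
      col <- col + tabulate(w, nbins = n_genes)
    }
    counts[, d] <- col
  }
  counts
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Match recovered topics to planted topics
#'
#' Solves the optimal one-to-one assignment between the rows of a recovered
#' topic-gene matrix and the rows of the true one, maximizing total cosine
#' similarity (Hungarian algorithm).
#'
#' @param phi_recovered,phi_true K x G matrices with matching shapes.
#' @return List with `permutation` (`permutation[i]` is the true topic
#'   matched to recovered topic i), `similarity` (per-pair cosine) and
#'   `mean_similarity`.
#' @export
match_topics <- function(phi_recovered, phi_true) {
  if (!all(dim(phi_recovered) == dim(phi_true))) {
    stop("phi matrices must have identical shape", call. = FALSE)
  }
  sim <- .cosine_matrix(phi_recovered, phi_true)
  perm <- .hungarian(-sim) # minimize negative similarity
  sims <- sim[cbind(seq_len(nrow(sim)), perm)]
  list(permutation = perm, similarity = sims,
       mean_similarity = mean(sims))
}

.cosine_matrix <- function(a, b) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  na[na == 0] <- 1
  nb[nb == 0] <- 1
  (a %*% t(b)) / outer(na, nb)
}

# Hungarian algorithm (Kuhn-Munkres with potentials), minimizing cost.
# Returns assignment: row i -> column out[i].
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j+1]: row assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  }
  ans
}
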