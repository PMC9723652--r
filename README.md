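# topicgrad

Topic modeling of transcriptional gradients in single-cell RNA-seq.

Clustering forces every cell into exactly one group, but many biological
responses — hormone stimulation time courses above all — move cells along
*continuous* gradients of program activity. `topicgrad` treats each cell as
a document and each gene as a word, and fits a latent Dirichlet allocation
(LDA) model so that every cell is a *mixture* of shared transcriptional
programs ("topics"). The per-cell topic weights quantify where each cell
sits along the underlying gradients; the per-topic gene weights say which
genes drive each program.

It is aimed at analysts of single-cell expression data who want to measure
graded treatment responses (e.g. estrogen stimulation of breast cancer
lines) rather than discrete cluster shifts.

## Model

Counts are first made compositional with a centered log-ratio (CLR)
transform per cell,

    CLR(x)_i = ln( (x_i + c) / g(x + c) ),   g(y) = (y_1 ... y_G)^(1/G),

with pseudo-count `c = 1`; without this step the model is dominated by
highly abundant genes (ribosomal, mitochondrial). Negative values (genes
below the cell's geometric mean) are clamped to zero, scaled (×10) and
rounded, giving the non-negative integer "pseudo-count" matrix the sampler
consumes.

The generative model: for each topic k, φ_k ~ Dirichlet_G(β); for each cell
d, θ_d ~ Dirichlet_K(α); each token draws a topic z ~ θ_d and a gene
w ~ φ_z. A collapsed Gibbs sampler (Rcpp) integrates out θ and φ and
resamples token labels from

    P(z_i = k | ·) ∝ (n_dk + α) · (n_kw + β) / (n_k· + Gβ),

with defaults α = 50, β = 0.1. The number of topics is chosen from an elbow
in the rate of perplexity change (RPC),

    perplexity = exp( −Σ_d log p(w_d) / Σ_d G_d ),
    RPC_i = |P(k_{i+1}) − P(k_i)| / (k_{i+1} − k_i),

swept over K (10–100 by 10 on real data). Downstream: per-topic top-50 gene
signatures, z-normalized cell-topic scores, topic transfer onto other
datasets by binned-control signature scoring, delta-control Z-scores
against a baseline condition, and upper-tail hypergeometric enrichment of
signatures in annotated gene sets (e.g. ChIP-seq-derived TF target sets).

## Worked example

Everything below is reproducible offline — the simulator plants known
topics so the fit can be checked against the truth:

```r
library(topicgrad)

sim   <- generate_lda_corpus(n_cells = 500, n_genes = 200, n_topics = 5,
                             depth = 500, anchor_strength = 0.5, seed = 11)
genes <- select_variable_genes(sim$counts, 200)
inp   <- prepare_lda_input(sim$counts, genes)        # CLR -> clamp -> x10 -> round
fit   <- fit_lda(inp, K = 5, iterations = 300, burn_in = 150, seed = 101)

mt <- match_topics(fit$phi[, sim$counts$gene_names], sim$truth$phi_true)
mt$mean_similarity
#> [1] 0.9815
top_genes(fit, 1, 5)$genes
#> [1] "gene062" "gene081" "gene156" "gene004" "gene032"
```

The mean cosine similarity of 0.98 between the recovered and the planted
topic-gene distributions (after optimal one-to-one matching) says the five
planted programs were recovered almost exactly; each recovered topic's
top-50 signature contains over 90% of its matched truth topic's planted
anchor genes.

Model selection and transfer:

```r
sw <- sweep_topics(inp, k_values = 2:10, iterations = 200, burn_in = 100,
                   seed = 1007)
sw$selected_k
#> [1] 5                       # the planted K

tgt <- twin_corpus(sim$truth, n_cells = 300, seed = 22)   # new cells, same topics
sc  <- transfer_topics(fit, tgt$counts, n = 50, seed = 31)
cor(sc$scores[, 1], tgt$truth$theta_true[, mt$permutation[1]],
    method = "spearman")
#> [1] 0.94                    # transferred scores track the true mixtures
```

A command-line interface wrapping the same functions ships in
`inst/cli/topicgrad.R` (subcommands `simulate`, `preprocess`, `fit`,
`sweep`, `scores`, `transfer`, `overlap`, `delta-z`, `enrich`); every run
writes a JSON manifest of parameters, seed and input digests, and reruns
with the same seed are byte-identical.

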