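---
title: "Inferring transcriptional gradients with CLR-normalized topic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional gradients with CLR-normalized topic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicgrad)
```

## The model

Single-cell treatment responses are often gradients, not discrete states: a
hormone-stimulated culture contains cells at every intermediate stage of
the response. `topicgrad` models a gene-by-cell count matrix with latent
Dirichlet allocation (LDA). Each cell d carries a mixture θ_d over K shared
topics; each topic k is a distribution φ_k over genes. Tokens (units of the
integer input matrix) are generated by drawing a topic from θ_d and then a
gene from φ_z. θ quantifies each cell's position along the inferred
gradients; φ names the genes of each program.

Inference is collapsed Gibbs sampling: θ and φ are integrated out
analytically and only per-token topic labels are resampled from

$$P(z_i = k \mid \cdot) \propto (n_{dk}^{-i} + \alpha)\,
  \frac{n_{kw}^{-i} + \beta}{n_{k\cdot}^{-i} + G\beta},$$

after which point estimates are read off the counts,
θ_dk = (n_dk + α)/(n_d + Kα) and φ_kw = (n_kw + β)/(n_k + Gβ).

### Why CLR normalization

Raw counts hand the model to the most abundant genes (ribosomal,
mitochondrial). Each cell is therefore centered log-ratio transformed:
CLR(x)_i = ln((x_i + 1)/g(x + 1)) with g the geometric mean over all G
components (zeros enter as the pseudo-count). Ratios against the geometric
mean are invariant to sequencing depth on strictly positive data —
`clr_transform(k * x, 0)` equals `clr_transform(x, 0)` — so library size
cancels by construction. The CLR values are scaled (default ×10) and
rounded half away from zero to form the integer "pseudo-count" tokens for
the sampler; half-away-from-zero avoids platform-dependent banker's
rounding.

CLR values are negative for genes below a cell's geometric mean, but LDA
needs non-negative token counts. We clamp negatives to zero before scaling:
this keeps the printed transform intact for the informative (above-mean)
genes and simply assigns no tokens to below-mean genes, which is the
behaviour a bag-of-words model expects from "absent" words. A cell whose
whole row rounds to zero (e.g. a constant cell) is retained but flagged,
skipped by the sampler, and assigned the uniform prior mean θ row.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_features` | 5000 | vocabulary size: most variable genes (variance-stabilized dispersion ranking) |
| `scale_factor` | 10 | CLR-to-token multiplier; larger values resolve finer ratio differences at linear cost in runtime |
| `pseudo_count` | 1 | CLR shift; conventional for count data |
| `alpha` | 50 | per-cell topic concentration; large values give dense mixtures appropriate for gradients (`alpha_by_k = TRUE` switches to the 50/K convention) |
| `beta` | 0.1 | per-topic gene concentration; small values give sparse, interpretable programs |
| `iterations` / `burn_in` | 500 / 250 | Gibbs sweeps; matched to collapsed-Gibbs practice in the single-cell topic-model literature |
| `n` (signatures) | 50 | top genes per topic for signatures, transfer, overlap, enrichment |

θ/φ are estimated from the final sampler state by default;
`estimate = "average"` averages every 10th post-burn-in sweep instead.
Averaging reduces Monte-Carlo noise but mildly blurs label identity if the
chain drifts; the final state is the default because downstream consumers
(signatures, transfer) only need the converged ranking of genes within
topics, and a single converged state is fully reproducible and cheap.

The variable-gene ranking fits a loess trend (span 0.3, degree 2) of log10
variance on log10 mean, standardizes counts by the trend's expected
standard deviation, clips at √N, and ranks genes by the variance of the
clipped values, ties broken by gene name. With fewer than ten
positive-variance genes there is no trend to fit and the ranking falls back
to plain dispersion (variance/mean).

## Model selection

Perplexity on the training data, exp(−Σ log p(w_d) / Σ G_d), is computed
for a sweep of K values (10–100 step 10 on real data). We use the standard
negative-exponent convention so that lower perplexity means a better model;
a uniform model over G genes has perplexity exactly G, which the tests pin
down. The rate of perplexity change RPC_i = |P(k_{i+1}) − P(k_i)| /
(k_{i+1} − k_i) forms an elbow curve.

The elbow K is chosen deterministically as the K between the two adjacent
RPC values with the largest *relative* drop. We also provide a
"first non-decreasing RPC pair" rule (`method = "first_plateau"`), which
reads the plateau onset directly on noise-free curves; on sampled
perplexities, however, sweep-to-sweep sampler noise perturbs both the steep
region and the plateau, and the first non-decreasing pair can fire at
either end — early on a noisy step in the steep region, or deep inside the
plateau. The relative-drop rule keys on the one feature sampler noise does
not fake, the order-of-magnitude collapse of the RPC at the elbow, and is
therefore the default; the test suite exercises it on planted-truth sweeps
(K_true = 5, K = 2..10, ten seeds). Perplexity is evaluated on the training input, as
is customary for this selection heuristic; no held-out split is taken.

## Downstream analyses

* **Signatures** — `top_genes()` takes the n = 50 highest-φ genes per
  topic, ties broken lexicographically so signatures are deterministic.
* **Cell scores** — `normalize_cell_scores()` z-scores each θ column
  (sample SD; constant columns yield zeros with a warning rather than
  NaN).
* **Transfer** — `transfer_topics()` scores each source signature on a new
  dataset with a binned-control module score: genes are binned into 25
  equal-frequency bins of average log-normalized expression and 100 control
  genes per signature gene are drawn (with replacement, seeded) from the
  matching bin; the score is the signature mean minus the control mean.
  Transfer operates on raw target counts (log-normalized to the median
  depth), not on CLR tokens, matching how module scores are used on
  expression data.
* **Delta-control Z-score** — scores are z-scored across *all* cells and
  the median z of the control group is subtracted; control cells then have
  median delta exactly 0 and the statistic is invariant to affine changes
  of the raw scores. Z-scoring globally (rather than within treatment arms)
  keeps one common scale across groups.
* **Enrichment** — upper-tail hypergeometric overlap (`phyper`) between
  each signature and each annotated gene set, restricted to a gene
  universe. The universe defaults to the model vocabulary — the only genes
  the signature could ever contain — with an `"intersection"` mode
  restricting to vocabulary ∩ annotated genes. Both raw and BH-adjusted
  p-values are reported; per-topic top factors are ranked by raw p (ties:
  larger overlap, then set name), so the ranking does not depend on the
  correction.

## The synthetic generator

`generate_lda_corpus()` draws corpora from the model's own generative
process with *anchor blocks*: each topic's Dirichlet_G(β_gen) base
distribution is blended with anchor_strength = 0.5 of mass spread uniformly
over a disjoint block of ⌊G/K⌋ genes. Anchors make the planted topics
identifiable, so recovery (matched cosine similarity, anchor membership of
top-50 signatures) can be asserted; pure Dirichlet draws guarantee no such
identifiability. Defaults emulate a small hormone-response experiment:
N = 500 cells, G = 200 genes, K = 5 programs, 500 tokens per cell, fixed
depth (isolating sampler behaviour from library-size variation; the truth
object records everything needed to check any fit). The free concentration
parameters are α_gen = 1 — a uniform draw over the mixture simplex, giving
both dominant-topic and genuinely mixed cells as in real gradients — and
β_gen = 0.1, mirroring the sparse topic prior used in fitting.

`generate_response_gradient()` adds ordered group labels (a time course)
and ramps the planted mass of chosen effect topics across groups: a cell in
group g gets `effect_ramp[g]` added to its effect topics with the remaining
topics renormalized to the leftover mass, so group means shift by the ramp
value up to Dirichlet noise. A zero ramp produces exchangeable groups and
is used as the null. `twin_corpus()` draws new cells from an existing
planted truth, providing transfer targets with known mixtures.

What the simulations do **not** emulate: dropout curves, ambient RNA,
doublets, batch effects, or any specific cell line's expression structure.
Passing the planted-truth suite shows the estimator and its plumbing are
correct, not that every real dataset has recoverable topic structure.

## Numerical choices and degenerate inputs

* All sampler randomness comes from R's RNG after a single `set.seed`;
  identical seed + input gives bit-identical θ/φ. Sweeps offset the seed
  deterministically per K.
* The unnormalized conditional is accumulated in double precision and
  sampled by inverse CDF on the running sum; at these scales (≤ thousands
  of tokens per cell) no log-space computation is needed.
* Token visitation order is a fixed pass over cells then genes then
  multiplicity; permuting cells therefore changes the sampled chain, and
  exchangeability is asserted on converged φ (tolerance 0.02) rather than
  exactly.
* K = 1 degenerates to the closed form φ_w = (n_w + β)/(n + Gβ), θ ≡ 1;
  zero-token inputs are rejected; empty cells get uniform θ.
* θ/φ are serialized with 6 significant digits — beyond the sampler's
  Monte-Carlo noise floor — and reading a written model reproduces them
  exactly at that precision.
* The Hungarian matcher (Kuhn–Munkres with potentials, O(K³)) gives the
  optimal signature-to-truth assignment; it is cross-checked against
  brute-force enumeration of all K! permutations for K ≤ 6 in the tests.

## Problem sizes in the test suite

The suite validates on corpora of 500 cells × 200 genes (the reference
planted-truth scale: topic recovery, the K = 2..10 sweep, transfer,
gradients) and smaller; the sampler-correctness check uses a 6-token corpus
where the collapsed posterior over all 2⁶ assignment states is enumerable
exactly. These sizes were chosen so that planted effects are several times
larger than Monte-Carlo noise while the entire suite remains quick to run
routinely.

## Known limitations

* The method describes programs; it does not name their upstream
  regulators. Enrichment against ChIP-derived target sets (GMT input) is
  the supported route; how peaks map to target genes is the annotation
  provider's choice, and gene identifiers are matched exactly
  (case-sensitive, whitespace-stripped) with no alias resolution.
* CLR clamping discards below-geometric-mean structure; an intrinsically
  non-negative log-ratio variant would retain it but departs from the
  printed transform.
* Perplexity-based selection on training data tends to flatten, not rise,
  past the true K; the RPC elbow handles this but remains a heuristic.
* Topics are exchangeable across runs: labels, not identities, are stable.
  Compare runs with `topic_overlap()` or `match_topics()`, never by index.
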