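---
title: "Modeling gene contextuality with topic-specific co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene contextuality with topic-specific co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Motivation and model

Enrichment methods (ORA, GSEA) assign function to *sets* of genes and
ignore the biological context in which a single gene matters. `topicnets`
models that context explicitly. The observation behind the method is that
curated gene-set collections carry two complementary signals: the
*documents* describing each set (abstracts, database descriptions) encode
thematic context, while the *gene memberships* encode which genes act
together. The pipeline couples them:

1. **Topics.** Documents are preprocessed into bags of stemmed tokens and
   modeled with latent Dirichlet allocation: each document is a mixture
   $\gamma_d$ over $k$ topics, each topic a distribution $\beta_k$ over
   tokens. A document is assigned to $\arg\max_k \gamma_{dk}$ when
   $\max_k \gamma_{dk} \ge 0.2$; otherwise it stays unassigned, trading
   coverage for assignment specificity.
2. **Networks.** For each topic, every unordered pair of assigned gene
   sets $(S, T)$ contributes the clique over $S \cap T$; the union of
   these cliques, with duplicate edges collapsed, is the topic's simple,
   undirected, unweighted gene co-occurrence network. An edge therefore
   certifies that its two genes were curated together in at least two
   sets of the same theme.
3. **Node metrics.** Per network and gene: unnormalized Brandes
   betweenness (bottleneck genes), eigenvector centrality (hubs connected
   to hubs), local fractal dimension (structural complexity of the
   neighborhood), and the variance of betweenness under repeated minimal
   edge rewiring (sensitivity of the gene's position to small changes in
   curated knowledge). Each column is min–max rescaled to $[0, 1]$ per
   network so genes can be compared across networks of very different
   size.

The modeling assumptions worth stating: documents attached to the same
gene set share its context (their texts are concatenated); co-curation in
set intersections is a meaningful proxy for functional association;
and edge multiplicity beyond the first co-occurrence carries no extra
information (edges are unweighted by design — the network is a knowledge
graph, not an interaction-strength graph).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.2 | minimum posterior mass for document assignment (dimensionless, in (0,1]) |
| `min_freq` | 5 | corpus-wide token frequency below which tokens are pruned, iteratively with emptied documents |
| `k_grid` | 15–30 | candidate topic counts scored by mean pairwise Jensen–Shannon divergence of the $\beta_k$ (argmax wins, ties to the smallest k) |
| `alpha`, `eta` | 50/k, 0.1 | Dirichlet priors on document–topic and topic–token weights |
| `n_iter` (LDA) | 200 | Gibbs sweeps over the corpus |
| `perturb_iter` | 1000 | independent rewiring iterations per network |
| `rewire_rate` | 0.001 | fraction of edges rewired per iteration; floored at one edge so every iteration perturbs the graph |
| `spectrum_length` | 20 | Laplacian eigenvalues kept (largest first, zero-padded) for spectral network comparison |
| `top_terms` | 100 | enriched terms per topic entering the semantic map |
| `r_cap` | 10 | radius cap for the local fractal dimension |

## Text preprocessing

`preprocess_text()` applies, in order: Unicode NFKC normalization;
removal of non-ASCII residues (Greek letters and other non-Latin
alphabets); lowercasing; replacement of digits and punctuation by spaces;
whitespace tokenization; stopword removal; Porter stemming; and removal
of tokens shorter than two characters. The stemmer is implemented in the
package from the classic five-step suffix-stripping algorithm; a frozen
table of canonical input/stem pairs pins its behavior in the tests.

Two deliberate choices: rare-token pruning counts *corpus* frequency (the
sum over documents), not document frequency; and when a gene set has both
abstracts and a description, abstracts win — descriptions are a fallback
for sets without literature. One caveat the tests make explicit: Porter
stemming is not idempotent for stems ending in a lone "s" (e.g.
"response" → "respons" → "respon" if stemmed twice), so pipelines must
stem exactly once; the package's tokenizer does.

## Inference and numerical choices

**LDA backend.** Inference is a collapsed Gibbs sampler written in C++
(Rcpp) that draws from R's RNG, so a fit is bit-reproducible from
`(dtm, k, seed, alpha, eta, n_iter)`. $\beta$ and $\gamma$ are the
smoothed estimates from the final sampler state. The divergence-based
selection score uses the natural logarithm and a plain mean over topic
pairs (monotone-equivalent to weighted variants for the argmax).

**Eigenvector centrality** is computed by power iteration on $A + I$; the
shift removes the sign oscillation of bipartite graphs without changing
eigenvectors. Iteration stops when the max-normalized iterate moves less
than `tol` (default 1e-10) and errors, naming `max_iter`, if it never
does. A dense eigendecomposition serves as the oracle in the tests, never
as the implementation.

**Local fractal dimension.** $M(r)$ counts nodes within distance $r$
(cumulative, excluding the center); the LFD is the least-squares slope of
$\ln M(r)$ on $\ln r$ for $r = 1, \dots, \min(\text{ecc}, 10)$. Nodes
with eccentricity below 2 yield fewer than two points and score 0, which
keeps every node scored rather than dropping rows.

**Perturbation.** Every iteration restarts from the observed graph
(perturbations are independent, not cumulative — the variance is meant to
measure response to *minimal* change from the curated network). One
rewiring deletes a uniformly chosen edge and inserts a uniformly chosen
currently non-adjacent pair; reinsertion is not degree-preserving, since
the point is to let nodes gain and lose edges. On a complete graph the
deleted pair is the only candidate, so the graph is restored and all
variances are exactly zero. Variance uses denominator $n$ (population
variance) on raw betweenness; the rescaled column is insensitive to that
convention.

**Spectral comparison** keeps the 20 *largest* Laplacian eigenvalues
(dominant spectral content), zero-padding smaller networks; the
smallest-first truncation is available via `order = "smallest"` since the
convention is genuinely ambiguous. Distances are plain Euclidean;
log-transformation is left to display code.

**Classical MDS** uses the Torgerson construction on $d = 1 - s$ with
negative eigenvalues clipped to zero, and fixes the sign of each axis so
its first nonzero coordinate is non-negative — embeddings are
bit-reproducible. Similarity is Lin's measure,
$\mathrm{sim}(a,b) = 2\,\mathrm{IC}(\mathrm{MICA}) /
(\mathrm{IC}(a) + \mathrm{IC}(b))$, with information content from
annotation-closure frequencies over the supplied DAG; pairs whose only
common ancestor is a fully annotated root score 0.

**Ties.** Argmax ties (document assignment, topic-count selection) break
to the smallest index; enriched-term ranking breaks ties on adjusted
p-value by raw p-value, then term id. Constant metric vectors rescale to
0.5 everywhere. Rescaling targets the closed interval $[0,1]$; a strictly
open variant is available behind `open = TRUE`.

**Enrichment.** The hypergeometric test is upper-tail
($P(X \ge k)$) after intersecting module, term, and universe; the BH
family is all terms tested for one module; the universe is explicit
(default: network genes present in the annotation collection) because no
external service's internal background can be assumed.

## The synthetic study fixture

`synthetic_config()` plants everything the pipeline is supposed to
recover: `n_topics = 4` topics with disjoint 50-token vocabularies, 60
documents per topic of 50 tokens each, an aligned gene-set collection
(one document per set, 60 sets per topic), per-topic gene pools sized
`genes_per_set / overlap_fraction` (defaults 10 and 0.1, i.e. pool 100)
so that set pairs overlap partially and the resulting networks are
sparse rather than complete, and one hub gene per topic inserted into
*every* set of its topic — making it provably the best-connected node of
its network. Vocabulary tokens are spelled from a consonant-only alphabet
(no vowels, no "s"/"y"): such words are fixed points of the stemmer and
contain no digits, so planted structure survives preprocessing exactly.

What the fixture does *not* emulate: realistic token frequency
distributions (Zipf), document length variation, vocabulary bleed between
themes (available via `background_rate` but off by default), gene sets of
heterogeneous size, and annotation noise. Passing the recovery tests
therefore shows the machinery is correct and well-calibrated on separable
input; it does not certify performance on real corpora, where topics
overlap and assignment accuracy is necessarily lower.

Problem sizes used by the test-suite and the acceptance script — 240
documents, vocabulary 200, four networks of roughly 100 nodes, 500-node
benchmark lattices, oracle comparisons on graphs of up to 7 nodes (500
replicates) — were chosen so a complete run takes about a minute; they
are large enough that every planted structure is recovered with margin.

## Known limitations

- Topic labels are arbitrary: analyses that compare against planted truth
  must match fitted to planted topics (the package does this by majority
  vote over each network's contributing sets).
- Gibbs LDA on degenerate corpora (identical documents over a splittable
  vocabulary) will still specialize tokens across topics; the
  divergence score approaches zero only when the vocabulary cannot split.
- Isolated genes — members of assigned sets that never co-occur in an
  intersection — are absent from the network and hence unscored, by
  construction.
- Eigenvector centrality on a disconnected network concentrates on the
  component with the largest spectral radius; other components score near
  zero. Interpret per-component, or on the giant component.
- The ontology reader handles two-column is-a edge tables only; richer
  relationship types are out of scope.
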