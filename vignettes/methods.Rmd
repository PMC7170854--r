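---
title: "Methods: heterogeneous-network embedding for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-network embedding for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hinmda` treats miRNA-disease association prediction as supervised link
prediction on a heterogeneous information network with five node classes
(miRNA, lncRNA, protein, disease, drug) and nine undirected association
classes joining them. Every (miRNA, disease) pair is represented by a
feature vector with two halves per node:

**Behavior (network) features.** From the binary adjacency $S$ the
random-walk transition matrix $A = D^{-1}S$ is formed ($D$ = degree
diagonal). For each step order $k = 1,\dots,K$ the column-normalized
$k$-step matrix is log-transformed and shifted,
$$X^k_{ij} = \max\!\Big(0,\; \log\frac{A^k_{ij}}{\Gamma_j} - \log\beta\Big),
\qquad \Gamma_j = \sum_p A^k_{pj},$$
and factorized by truncated SVD, $X^k \approx U_d \Sigma_d V_d^\top$, giving
the per-order representation $W^k = U_d \Sigma_d^{1/2}$. The embedding
concatenates all orders, $W = [W^1, \dots, W^K]$. Nodes sharing many short
random-walk paths (e.g. members of one functional community) receive similar
rows.

**Attribute features.** miRNAs: the 64-dimensional 3-mer frequency vector of
the sequence (sliding windows over $\{A,C,G,U\}$, T$\to$U normalized,
components summing to 1). Diseases: the row of the pairwise semantic
similarity matrix computed from MeSH-style DAGs — each disease's ancestors
contribute $D_D(d) = \max\{\Delta \cdot D_D(d') \mid d' \in
\mathrm{children}(d)\}$ with $D_D(D) = 1$, the semantic value is
$DV(D) = \sum_{d \in T(D)} D_D(d)$, and
$$SS(d_i, d_j) = \frac{\sum_{t \in T(d_i) \cap T(d_j)}
\big(D_{d_i}(t) + D_{d_j}(t)\big)}{DV(d_i) + DV(d_j)} \in [0, 1].$$
Both attribute classes pass through a stacked ReLU autoencoder
($h = \mathrm{ReLU}(Wx + p)$, $y = \mathrm{ReLU}(W'h + q)$, MSE loss) so
they share one code dimension.

The fused node vector concatenates attribute code and behavior vector
(64 + 64 = 128 by default); a pair sample concatenates the two node vectors
(256). Positives are the known associations; negatives are an equal number
of uniformly drawn unlabeled pairs; the default classifier is a Random
Forest, evaluated by 5-fold cross-validation.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| $\Delta$ | 0.5 | per-generation decay of ancestor contributions; the literature's customary value, never specified in this line of work |
| $K$, $d$ | 4, 16 | step orders and per-order SVD rank; chosen so the behavior vector is $K \cdot d = 64$ and the fused node vector 128. Only the 128 total is fixed by the design; the split is one consistent choice and both are configurable |
| $\beta$ | $1/N$ | log-shift of $X^k$; keeps only transitions above the uniform rate, the standard choice for this factorization family |
| SAE | one 64-unit layer, 100 epochs, Adam lr $2 \times 10^{-3}$ | minimal architecture satisfying the 64+64 fusion arithmetic; see "Numerical choices" for the initialization |
| RF | 100 trees, mtry $=\lfloor\sqrt{p}\rfloor$, unlimited depth | field-standard defaults; this method family's literature rarely states values |
| negatives | 1:1, sampled once before fold splitting | matches the "combine samples, then split" protocol; per-fold resampling is a documented alternative, not the default |
| threshold | 0.5 | decision threshold for the confusion-matrix panel |

## The synthetic world

`generate_study()` emulates the four inputs (nine edge lists, miRNA FASTA,
disease hierarchy, positives list) with a planted-partition design: nodes of
all five types are assigned to $B$ latent blocks; every association class
draws within-block pairs with probability `p_in` and cross-block pairs with
`p_out` — except miRNA-disease, whose *true* associations are exclusively
within-block draws (cross-block miRNA-disease pairs are all true negatives).
A fraction `observed_frac` (default 0.7) of the true associations becomes
the observed positives (and the network's miRNA-disease edges); the rest is
held-out truth. Sequences are uniform RNA with one planted insertion of a
block-preferred 3-mer; disease DAGs hang off shared per-block ancestor
chains. The attribute signal is deliberately *weak* relative to the network
signal, so the feature-ablation direction (both $>$ attribute-only) is
exercised in the direction reported for real data (network-dominant).

What a green end-to-end test establishes: the pipeline can recover planted
community structure from the network and rank held-out within-block pairs
above chance, deterministically under a seed. What it does not establish:
performance on real association data — real networks have heavy-tailed
degrees, hub miRNAs, and correlated attributes, none of which the generator
models (deliberately; degree realism is a non-goal).

Default sizes (5 blocks; 100/80/120/50/40 nodes per type; `p_in` 0.15,
`p_out` 0.01) give a ~390-node network with ~170 observed positives. At this
scale the default Random Forest reaches a mean cross-validated AUC of about
0.65-0.75 depending on the seed, although the embedding itself separates the
blocks essentially perfectly (within-block cosine similarity ~0.5 versus
~0.05 across). The gap is structural: with pair features built by
*concatenation*, "miRNA block equals disease block" is an XOR-like pattern
in rotated coordinates, which axis-aligned trees learn inefficiently from a
few hundred samples — a rotation-invariant classifier (KNN) reaches 0.88-0.94
on the identical features, and a forest given oracle block indicators
reaches 0.92. Reported performance of this method family on full-scale
association databases (AUC around 0.9) relies on tens of thousands of
training pairs and real-data hub structure. We keep the
concatenation + Random Forest design because it is the method being
implemented; the bundled CART forest matches scikit-learn's on identical
folds, so the limitation is the representation/sample-size regime, not the
implementation.

## Numerical choices

* **SVD**: LAPACK dense SVD throughout — exact and bit-reproducible; network
  sizes in scope (up to a few thousand nodes) pose no problem. Sign
  indeterminacy is fixed by making the largest-magnitude entry of each left
  singular vector positive (the paired right vector is flipped with it).
* **Autoencoder initialization**: randomly initialized ReLU-ReLU
  autoencoders of these widths reliably stall in poor local minima (we
  verified this with Adam, with full-batch L-BFGS on analytic gradients, and
  with an independent MLP implementation). Layers are therefore initialized
  at the optimal *linear* autoencoder (PCA): encoder rows are top principal
  directions, a positive code offset keeps every ReLU in its active regime,
  and the decoder bias undoes the offset; small Gaussian noise
  (sd 0.01) breaks symmetry, Adam refines, and the best end-of-epoch
  parameters are kept so the returned model is never worse than an earlier
  epoch. Final reconstruction loss is below the initial loss on every run in
  the test suite.
* **Ties**: AUC uses average ranks (equivalent to trapezoidal ROC
  integration; all-tied scores give 0.5); AUPR integrates precision over
  recall step-wise with tie groups processed as blocks; candidate rankings
  break score ties by miRNA id.
* **Degenerate inputs**: isolated nodes get zero transition rows and zero
  embeddings (warned, not fatal); diseases without a DAG and miRNAs without
  a sequence get zero attribute vectors by default (`missing = "drop"` is
  the alternative); undefined metric denominators yield `NaN` with a
  warning, never a silent 0.
* **Determinism**: every stochastic step (negative sampling, fold split,
  bootstrap and feature subsampling inside the forest via R's RNG, SAE init
  and batch order, generator streams) is driven by configurable seeds;
  identical config + seed reproduces reports bit-for-bit.

## Design decisions taken where the design was open

* Edges are undirected and unweighted; duplicate and reversed rows collapse;
  self-loops (e.g. protein self-interactions) are dropped, since the
  transition-matrix construction assumes a zero diagonal.
* A row of a typed edge list may be written in either orientation; endpoint
  types are resolved against the identifier registry, and a genuine
  type conflict for one identifier is an error, not a guess.
* One autoencoder per node class (the two attribute spaces have different
  dimensions); both classes are encoded for uniformity, with a configurable
  bypass.
* Negative sampling happens once per experiment, before fold splitting;
  folds are random, not disease-stratified.
* The attribute row of a disease spans all diseases present in the network
  (the matrix dimension equals the disease count).

## Known limitations

* Dense matrices throughout the embedding: memory grows as $N^2$; fine for
  the intended scale, unsuitable for $10^5$-node networks.
* The ReLU decoder cannot reconstruct negative values — coherent for
  frequencies and similarities, wrong for signed features.
* Gaussian Naive Bayes on strongly dependent embedding coordinates is a
  baseline, not a recommendation.
* Negative "non-associations" are unlabeled pairs, not verified negatives —
  the standard caveat of this evaluation protocol.
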