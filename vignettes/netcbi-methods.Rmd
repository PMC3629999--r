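---
title: "Similarity-based inference of miRNA-disease associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based inference of miRNA-disease associations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcbi)
```

## The problem

Experimentally verified associations between microRNAs (miRNAs) and human
disease phenotypes are sparse: a typical curated catalogue links on the
order of a hundred miRNAs to a few dozen OMIM phenotypes through a few
hundred edges. The working assumption behind this package is that
functionally related miRNAs tend to be associated with phenotypically
similar diseases, so the two sides of the bipartite association network
each carry a similarity structure — a miRNA functional similarity matrix
$M$ ($n \times n$) and a disease phenotype similarity matrix $P$
($m \times m$) — that can be exploited to rank unobserved miRNA-phenotype
pairs.

The data model is a bipartite graph $G(M, P, E)$ encoded as a binary
$n \times m$ adjacency matrix $a$, with $a_{ij} = 1$ when miRNA $i$ is
known to associate with phenotype $j$, held in an `assoc_network` object;
the two similarity matrices are `similarity_matrix` objects. There are no
verified negative associations, so every method below scores candidates
using positives only.

## The three scoring schemes

**MBSI** (miRNA-based similarity inference) recommends to miRNA $i$ the
diseases of the miRNAs similar to it:

$$v_{ij} = \frac{\sum_{l \ne i} S(m_i, m_l)\, a_{lj}}
                {\sum_{l \ne i} S(m_i, m_l)}.$$

**PBSI** (phenotype-based similarity inference) recommends to phenotype
$j$ the miRNAs of phenotypes similar to it:

$$v_{ij} = \frac{\sum_{l \ne j} S(p_j, p_l)\, a_{il}}
                {\sum_{l \ne j} S(p_j, p_l)}.$$

Both are weighted averages of binary values, hence bounded in $[0, 1]$ and
invariant to any positive rescaling of their similarity channel. A query
entity with zero similarity support (an all-zero weight vector) has an
undefined average; we define its scores as 0, reading "no similarity
information" as "no recommendation".

**NetCBI** (network-consistency-based inference) uses both channels at
once through graph-Laplacian relevance propagation. Each similarity matrix
is first column-normalized, $\bar M_{\cdot i} = M_{\cdot i} / \sum_k M_{ki}$
(`normalize_columns()`); a zero column stays an all-zero vector, which
preserves its "no information" semantics and keeps $I - \alpha \bar M$
well conditioned. For a binary query indicator $q$ the relevance vector is
the minimizer of a graph-smoothness penalty plus a query-fidelity penalty,
whose closed form is

$$\tilde q = (1 - \alpha)\,(I - \alpha \bar M)^{-1} q, \qquad
  \alpha \in (0, 1),$$

and similarly on the phenotype side with parameter $\beta$. The smoothing
parameters are unitless mixing weights: small values keep the relevance
vector close to the query, large values diffuse it over the similarity
graph. `laplacian_relevance()` computes $\tilde q$ by a linear solve —
never an explicit inverse — and verifies the residual against
$10^{-8}\lVert q \rVert$; for a column-stochastic operator the propagation
conserves mass ($\mathbf{1}^\top \tilde q = \mathbf{1}^\top q$), and the
test suite checks the solution against a truncated Neumann series
$(1-\alpha)\sum_k \alpha^k \bar M^k q$ computed independently.

The NetCBI score of candidate phenotype $j$ for query miRNA $q$ is the
network-consistency correlation

$$\mathrm{NetCBI}(q, j) = \mathrm{corr}\!\left(a\,\tilde p_j,\; \tilde m_q\right),$$

a Pearson correlation between two $n$-vectors: the known associations
projected through phenotype $j$'s relevance profile, and the query's miRNA
relevance profile. It is high when known edges connect miRNAs relevant to
the query with phenotypes relevant to the candidate. Scores lie in
$[-1, 1]$; when either vector has zero variance (for example an empty
network) the correlation is undefined and we define the score as 0, a
neutral value that cannot poison a ranking the way an `NaN` would.

Two computational choices are worth recording. First, all phenotype
relevance profiles $\tilde p_j$ are the columns of
$(1-\beta)(I - \beta \bar P)^{-1}$, so one factorization serves every
candidate; the tests assert this is numerically identical to per-query
solves. Second, in leave-one-out evaluation the removal of a query
miRNA's adjacency row is a rank-one change to $a \tilde P$, so the whole
cross-validation score matrix is obtained from full-network cross-products
with closed-form corrections; a regression test pins this fast path to the
literal per-query removal loop at $10^{-10}$.

## Evaluation protocol

`loocv_mirna_query()` (MBSI, NetCBI) iterates over every miRNA with at
least one association, removes its entire adjacency row — all its disease
associations, including the ones being recovered — scores all phenotypes
on the reduced network, and builds an ROC curve by sweeping the distinct
candidate scores as thresholds: at each threshold the true-positive
fraction is the share of removed (positive) phenotypes scoring at or above
it and the false-positive fraction the share of the others. The curve is
anchored at $(0,0)$ and $(1,1)$ and integrated by the trapezoidal rule,
which is exactly the pairwise-concordance statistic
$P(s_{\text{pos}} > s_{\text{neg}}) + \tfrac12 P(\text{tie})$ — the suite
asserts the two formulations agree on every random toy instance. The
reported figure is the unweighted mean of per-query AUCs (one ROC per
query, not per association). `loocv_phenotype_query()` applies the same
protocol to PBSI with columns in place of rows. Because the MBSI and PBSI
sums skip the held-out row/column index, their reduced-network scores
coincide with full-network scores; the removal is still performed for
protocol uniformity and the equality is a regression test.

Degenerate queries are handled explicitly: a query with no associations
has nothing to hold out and is skipped; a query associated with *every*
candidate has no negatives, its ROC is undefined, and it is excluded from
the average with a warning. Neither case occurs in a benchmark-shaped
catalogue, but the rule matters for other data.

## Parameter selection

`grid_search()` evaluates NetCBI LOOCV on a grid of $(\alpha, \beta)$
pairs, by default $\{0.1, \dots, 0.9\}$ in steps of 0.1 on both axes (the
grid is an argument), and selects the maximizer; ties resolve to the
smallest pair lexicographically so runs are reproducible. Because the
selected point maximizes the same criterion it is evaluated on, its AUC is
optimistically biased; `nested_loocv()` removes that bias by holding each
miRNA out as a validation case, selecting parameters by an inner LOOCV
over the remaining $n - 1$ miRNAs, and scoring the validation miRNA with
the selected pair. The outer AUC is the mean validation AUC, and the
per-fold selections are reported with mean and standard deviation. One
design choice was genuinely open: whether the inner folds should also
shrink the similarity matrices. We keep them full-size — similarity is
side information about entities, not association labels, and dropping a
node would change the column normalization of every other entity — and
only the validation miRNA's association row is hidden from the inner
loop.

## The synthetic generator

`generate_synthetic()` plants the statistical structure the methods assume:
miRNAs and phenotypes are partitioned into paired blocks; similarities are
drawn around `within_sim` inside a block and `between_sim` across blocks
(truncated-normal jitter, symmetrized, unit diagonal); associations are
Bernoulli edges with probability `edge_prob_matched` between paired blocks
and `edge_prob_unmatched` otherwise. The defaults — 60 miRNAs, 30
phenotypes, 3 blocks, similarity contrast 0.7 vs 0.1 with jitter 0.05,
edge probabilities 0.3 vs 0.02 — give a network of roughly benchmark-like
sparsity (about 180 edges, 3 per miRNA) with a clearly planted but noisy
signal, and are the fixed conditions under which the package's recovery
checks run. Truncated-normal jitter was chosen over beta noise for
simplicity. The unit diagonal is a convention of the generator; the
inference code uses whatever diagonal the input files supply, since MBSI
and PBSI exclude the self term explicitly and only NetCBI's normalization
sees it.

Two null controls complement the generator. `generate_null_by_shuffle()`
destroys the similarity-association coupling while preserving both degree
sequences exactly, by repeated random checkerboard swaps (two edges
$(i_1,j_1), (i_2,j_2)$ become $(i_1,j_2), (i_2,j_1)$ when the crossed
pairs are absent); the default of ten attempted swaps per edge is a
standard mixing heuristic. `noise_similarity()` replaces one similarity
channel with structureless symmetric uniform noise, the knockout showing
that MBSI responds to the miRNA channel and PBSI to the phenotype channel.

What the generator does *not* emulate: real miRNA family structure and the
long-tailed, correlated similarity distributions of text-mining scores;
curation biases that make well-studied miRNAs both higher-degree and
better-connected in the similarity resource; and any dependence between
the two similarity channels. Passing recovery tests on synthetic data
therefore demonstrates correctness of the machinery and sensitivity to
planted signal, not expected performance on a particular real catalogue.

On these synthetic conditions the LOOCV ranking of the methods differs
from what heavily curated real catalogues show (here the single-channel
methods can outscore NetCBI, and the tuned smoothing parameters land
mid-grid rather than at 0.1): a balanced block model rewards local
neighbourhood averaging more than global propagation. The acceptance
script recomputes these figures at run time rather than quoting any.

## Sizes and budgets

The test-suite and acceptance-script evaluations use the generator
defaults (60 x 30, five seeds) for recovery checks, 20 x 10 fixtures for
protocol tests, and 8-16 miRNA instances for the brute-force oracles that
re-run every nested fold literally. Nested LOOCV over a 9 x 9 grid at the
default size completes in seconds thanks to the shared factorizations and
the rank-one LOOCV path.

## Limitations

The methods inherit the limits of their inputs: similarity matrices are
consumed as given (asymmetry beyond numerical noise is warned about, not
repaired), and prediction quality is bounded by the quality of those
resources. NetCBI can score miRNAs with no known associations (the query
indicator needs no edges), but evaluation of such queries is impossible by
construction. Scores across methods are not calibrated probabilities —
they are rankings, and should be consumed as such.
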