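---
title: "Biased heat conduction for miRNA-disease ranking: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biased heat conduction for miRNA-disease ranking: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmda)
```

## The model

`heatmda` scores unobserved miRNA-disease pairs by diffusing resources over
a bipartite network built from three ingredients: a binary association
matrix $A$ ($n$ miRNAs $\times$ $q$ diseases), an integrated miRNA
similarity $SM$, and an integrated disease similarity $SD$. The underlying
assumption is the standard one in this field: functionally similar miRNAs
tend to associate with semantically similar diseases, so similarity can
stand in for missing edges.

The pipeline has three stages.

**1. Similarity construction.** Disease similarity comes from ancestor
DAGs in a MeSH-style hierarchy. Model 1 weights an ancestor $t$ of disease
$D$ by a geometric decay $\Delta^{\text{depth}}$ implemented as
$C_D(t) = \max\{\Delta \cdot C_D(t') : t' \text{ child of } t\}$ with
$C_D(D) = 1$; model 2 weights $t$ by its information content
$-\ln(\text{fraction of disease DAGs containing } t)$, so terms shared by
every disease contribute nothing and specific terms dominate. Both models
score a pair by the ratio of shared-term contributions to total semantic
values, which is $1$ for identical DAGs and $0$ for disjoint ones. Where a
disease lacks a DAG — or a miRNA pair lacks functional-similarity coverage
— a Gaussian interaction-profile kernel over the association profiles fills
in. The fusion is branch-wise, governed by an explicit coverage mask, not
by whether the semantic similarity happens to be zero: a pair of diseases
with DAGs but no shared ancestors keeps its semantic similarity of $0$
rather than falling back to the kernel.

**2. Network augmentation.** For a pair $(m_i, d_j)$ with $a_{ij} = 0$,
the miRNA-side augmented matrix $A'$ takes the largest $SM(i, t)$ over
miRNAs $t$ associated with $d_j$, provided it *strictly* exceeds the
threshold $\delta$; otherwise the cell stays $0$. The disease-side matrix
$A''$ mirrors this with $SD$ and threshold $\eta$. Known associations are
never overwritten: cells with $a_{ij} = 1$ are exactly $1$ in both. At a
threshold of $1$ no similarity qualifies and the augmented matrix equals
$A$; lowering the threshold is cellwise monotone.

**3. Two-pass diffusion.** On each augmented network every source node
starts with one unit of resource and splits it equally over its incident
edges; the return pass damps each receiver by $d^{-\gamma}$ of its degree.
The miRNA-side pass produces per-miRNA resources $f'(m_i)$, the
disease-side pass per-disease resources $f''(d_j)$, and
$S(i,j) = \tfrac{1}{2}\bigl(f'(m_i) + f''(d_j)\bigr)$. At $\gamma = 0$ the
return pass is plain heat conduction; small positive $\gamma$ shifts weight
toward low-degree (unpopular) nodes, which is the "biased" part of the
name.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.29 | miRNA-side augmentation threshold (strict, on $SM \in [0,1]$) |
| `eta` | 0.13 | disease-side augmentation threshold (strict, on $SD$) |
| `gamma` | 0.001 | degree-bias exponent of the return pass |
| `semantic_delta` | 0.5 | per-generation decay of model-1 contributions |
| `gip_bandwidth_d`, `gip_bandwidth_m` | 1 | kernel bandwidth factors before normalisation |
| `degree_mode` | `"binary"` | degree of a node in the weighted augmented network |
| `refit_similarity` | `TRUE` | rebuild kernels/fusion/networks per CV fold |

`delta`, `eta` and `gamma` defaults are the published calibration of the
method on the HMDD v2.0 corpus; they are exposed because the right values
are corpus-dependent. `semantic_delta = 0.5` is the conventional decay in
the MISIM lineage of semantic similarity. The bandwidth factors are
dimensionless multipliers of the data-driven normalisation (mean squared
profile norm over the axis's own entities); $1$ leaves the normalisation
untouched. In the small-bandwidth limit every kernel similarity tends to
$1$, which the tests exercise at $10^{-9}$.

## Conventions and numerical choices

* **Profile orientation.** Disease interaction profiles are *columns* of
  $A$ and miRNA profiles are *rows*, consistent with $A$ being miRNAs
  $\times$ diseases.
* **Degrees on a weighted network.** The diffusion equations originate on
  unweighted graphs, so the default degree is the count of nonzero
  incident edges; `degree_mode = "weighted"` (sum of weights) is provided
  as an alternative.
* **Zero-degree nodes.** Isolated nodes are legal (cross-validation folds
  create them): they contribute nothing on the forward pass and receive
  $0$ on the return pass, rather than raising an error.
* **Log base.** Model-2 contributions use the natural logarithm. The
  similarity ratio is scale-invariant, so the base is observable only in
  the per-node contributions.
* **Degenerate corpora.** In a corpus where every term occurs in every
  DAG (for example a single-disease corpus), all model-2 totals are zero;
  affected pairs get similarity $0$ with a warning instead of `NaN`.
* **Strict thresholds.** Augmentation requires $SM > \delta$, not $\geq$;
  at $\delta = 1$ the augmented matrix is exactly $A$.
* **Ties.** Ranking ties are everywhere resolved by midranks in AUCs (so
  the threshold-sweep trapezoid equals the Mann-Whitney statistic to
  within $10^{-12}$) and by miRNA identifier in output tables, making
  every output deterministic.
* **Matrix hygiene.** Similarity matrices are validated on construction:
  asymmetry beyond $10^{-8}$ is an error; values outside $[0,1]$ by up to
  $10^{-6}$ are clipped with a warning, beyond that an error. Scores are
  written with 12 significant digits so write/read/write is a byte-level
  fixed point.

## Cross-validation protocol

Both leave-one-out and k-fold validation rank each held-out association
against the *global* candidate set: every pair with no known association
in the full matrix. The pooled AUC is the mean over held-out pairs of the
fraction of candidates they outscore (ties half-credited).

What is refit per fold was a genuinely open design point. The semantic
similarities and the functional similarity do not derive from $A$, so they
are computed once and shared across folds. With `refit_similarity = TRUE`
(the default) the interaction-profile kernels, the fusion, and both
augmented networks are rebuilt from the masked training matrix, so no
information about the held-out edge reaches its own score. With `FALSE`
every fold is scored by the full-data model — faster, and closer to the
protocol much of this literature appears to use, but the held-out edge
then informs its own rank; the package treats that as an explicitly
labelled shortcut, not the default.

## The synthetic benchmark

The generator plants the assumption the method exploits: `n_blocks`
aligned groups of miRNAs and diseases, association probability `p_in`
(default 0.3) inside aligned blocks and `p_out` (default 0.02) across,
functional similarity near 0.8 within miRNA blocks and 0.1 across with
Gaussian noise (sd 0.05), and DAGs in which same-block diseases share
ancestors below a common root. The default sizes (60 miRNAs, 40 diseases,
4 blocks) keep a full leave-one-out sweep with per-fold refitting at a few
seconds per replicate. DAG scaffolds default to depth 3 with branching 2 —
deep enough that within-block semantic similarity clears `eta` while
cross-block pairs (sharing only the root) do not, mirroring how MeSH
top-level categories behave.

It deliberately does *not* emulate the heavy-tailed degree distributions
of curated association databases, where a few hub diseases carry hundreds
of annotations; block sizes and within-block degrees are homogeneous.

## Known limitations

The score $S(i,j)$ is an *average of two node-level quantities* and
contains no pair-specific term; pairs sharing a miRNA differ only through
$f''(d_j)$ and vice versa. Rankings therefore reflect node-level
prominence — degree structure and neighbourhood popularity — rather than
pair-level affinity. Two consequences matter for interpreting results:

* On real association corpora, node prominence correlates with where new
  associations are found (hub diseases keep accumulating annotations), so
  node-driven rankings can score well in cross-validation there.
* On the symmetric synthetic benchmark above, node prominence is uniform
  by construction, and pair-level block alignment is invisible to a
  node-additive score. Cross-validated AUCs computed by
  `scripts/acceptance.R` on this benchmark sit near chance for both the
  planted and the label-permuted data, slightly *below* 0.5 under the
  refitting protocol because masking a pair's edge depresses exactly that
  pair's two node resources. Passing the other acceptance checks (oracle
  equivalence, hand-worked values, limit behaviour) while the benchmark
  AUC stays at chance is thus a faithful portrait of the method: the
  diffusion is implemented correctly, and its discriminative signal on
  data without degree heterogeneity is limited by design.

Augmentation mitigates this only indirectly (similar nodes gain edges and
therefore resources) and homogenises degrees as a side effect.

A second, smaller limitation: with uniform initial resources the forward
pass is query-independent. A query-conditioned initialisation (seeding
resources from the query's own profile, as recommender-system formulations
of the same diffusion do) would make scores pair-specific, but it is a
different model; the package implements the literal uniform
initialisation.
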