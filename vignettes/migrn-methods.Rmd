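---
title: "Scoring miRNA impact on cell fate genes by shortest-path propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA impact on cell fate genes by shortest-path propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mignet)
```

## The problem and the model

A hallmark of tumorigenesis is the loss of balance between cell
proliferation and apoptosis. miRNAs sit upstream of this balance: each
miRNA represses a set of target genes, and those targets feed signed
regulatory cascades that terminate in "cell fate" genes — genes whose
pathway annotations point directly at proliferation or apoptosis. mignet
quantifies how much each dysregulated miRNA perturbs each downstream
cell fate gene, and ranks miRNAs by their global perturbation.

The model works on a **miGRN** (miRNA–gene regulatory network): a signed
directed graph of gene–gene regulation (+1 activation, −1 inhibition),
back-traced from the cell-fate sink set, with significantly
differentially expressed miRNAs attached as pure sources whose outgoing
target edges are always −1 (miRNAs are assumed repressive).

A perturbation originating at miRNA $i$ is assumed to travel along the
*shortest* directed path to cell fate gene $j$, and to decay linearly
with the path length. The pair impact is

$$I_{ij} = S_{ij} \cdot \log_2(\mathrm{FC}_i) / L_{ij}$$

where $\mathrm{FC}_i$ is the miRNA's mean fold change (cancer over
control), $L_{ij}$ is the number of edges on the shortest path, and
$S_{ij}$ is the product of edge signs along that path (the miRNA's first
hop contributes −1). Per-gene totals sum over the upstream miRNA set,
per-miRNA totals over the reached cell-fate set:

$$I_{\mathrm{gene}-j} = \sum_{i \in R^j} I_{ij}, \qquad
  I_{\mathrm{miR}-i} = \sum_{j \in G^i} I_{ij}.$$

Both sums run over the same pair table, so their grand totals are equal
— a conservation identity the test suite checks to $10^{-9}$ on every
fixture. Unreachable pairs are simply absent from both index sets.

This is a deliberate simplification of full pathway-perturbation models
(which require matrix inversion and bootstrap significance): shortest
paths are cheap, deterministic, and interpretable, at the cost of
ignoring signal carried by longer routes. The package assigns no
statistical significance to impact scores.

## Assumptions worth stating

- **All miRNA target edges are repressive.** Target interaction files
  may carry an annotation column; it is ignored and the sign forced to
  −1.
- **Shortest-path propagation with linear decay.** Longer alternative
  routes contribute nothing; $|I_{ij}| \le |\log_2 \mathrm{FC}_i|$
  always, since $L \ge 1$ and $|S| \le 1$.
- **Only significantly differentially expressed miRNAs are scored** —
  non-significant miRNAs are never attached to the network, so they are
  absent from every sum by construction.
- **The gene universe is not restricted to differentially expressed
  genes.** Back-tracing uses all regulatory relations; expression enters
  only through the miRNA gate and through reporting cell-fate gene DE.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `alpha` | 0.05 | FDR scale | significance gate on BH-adjusted p |
| `fc_threshold` | 1.5 | raw fold change | gate is two-sided: \|log2FC\| > log2(1.5) |
| `pseudocount` | 1 | abundance units | keeps fold changes finite at zero means |
| `method` | `welch` | welch / moderated | DE engine (see below) |
| `policy` | `majority` | majority / lexicographic / all_paths_mean | sign resolution across tied shortest paths |
| `max_depth` | unlimited | edges | optional cap on the back-trace depth |
| `top_k` | 50 | count | length of the critical-miRNA list |

### The differential expression engine

Established DE pipelines would reach for limma here. This package
implements the two-group test in-house — a Welch unequal-variance
t-test by default, and a
`moderated` option that shrinks each feature's pooled variance toward an
empirical-Bayes prior (scaled inverse chi-square, fitted by method of
moments on log variances, i.e. the standard moderated-t construction)
before forming the statistic. The rationale: the method's substance is
the network scoring, which consumes only the significance gate and the
log2 fold change; reproducing limma bit-exactly adds nothing testable.
The prior fit is cross-checked against `limma::squeezeVar` in the test
suite when limma is available.

Tests operate on `log2(x + pseudocount)`; fold changes use group means
of raw abundances with the same pseudocount, matching the "average fold
change" definition while staying finite.

Choices the model itself does not pin down, and what this package
does:

- **One- vs two-sided fold-change gate.** Two-sided
  (`|log2FC| > log2(fc_threshold)`): critical-miRNA lists are expected
  to contain both up- and down-regulated miRNAs, which a one-sided gate
  cannot produce. This is a config-visible choice.
- **Zero-variance features.** p is set to 1.0 and the feature flagged
  `untestable`, rather than returning NaN, so downstream gates are total
  functions. A zero-variance feature can therefore never be significant;
  with any realistic noise this case does not arise.
- **Two BH families.** BH is applied separately to the miRNA matrix and
  the mRNA matrix. The cell-fate gene DE table is the mRNA table gated
  to the cell-fate list *after* adjustment over all mRNAs
  (`readjust_cellfate = TRUE` switches to adjusting within the list
  only).

### Sign resolution across tied shortest paths

Several minimum-length paths may disagree in sign, and nothing in the
model dictates the tie-break. The default `majority` policy
takes the sign held by a strict majority of all shortest paths and
returns 0 on a tie — the pair is then flagged ambiguous and contributes
nothing. Majority is order-independent and reproducible across graph
back-ends, which is why it is the default; `lexicographic` (sign of the
path minimal in node-id order) and `all_paths_mean` (sign of the mean of
path signs) are selectable. Path enumeration is bounded to the minimum
length, so it terminates even on cyclic graphs.

### Other network-construction decisions

- Duplicate edges with conflicting signs: strict mode errors, lenient
  mode keeps the first occurrence and logs the conflict (the source
  databases are merged without a stated resolution rule).
- Unknown interaction strings (e.g. "binding") default to +1 — a
  sign-preserving pass-through — because dropping them can disconnect
  the graph; `unknown_sign = NA` excludes them instead.
- Self-loops are dropped: they cannot lie on a shortest path to a
  distinct target.
- Back-tracing is not depth-limited by default; `max_depth` is exposed
  for users who want a bounded neighbourhood.
- Node identifiers are opaque, case-sensitive strings; no symbol
  normalization is attempted. miRNA arm identifiers (-5p/-3p) are
  treated verbatim, never merged.
- The ranking key is $|I_{\mathrm{miR}}|$ descending with lexicographic
  id tie-break — an absolute-magnitude key is the only one consistent
  with top lists that mix up- and down-regulated miRNAs.
- Per-miRNA class averages (mean impact on proliferation vs apoptosis
  genes) are emitted under **two denominators** — genes of the class the
  miRNA actually reaches (`avg_I_*`) and all class genes in the network
  (`avg_I_*_all`) — since both readings of "average impact on a class"
  are defensible; no default is claimed as "the" definition.

## What the synthetic generator emulates

`synthetic_spec()` + `simulate_migrn()` generate the four pipeline
inputs from one integer seed: a layered signed gene graph whose final
layer is the cell-fate set, a miRNA target map, group-structured
lognormal expression for both feature sets, and a groups file.

The stated world of the defaults: 40 genes in 3 layers, 12 cell-fate
genes split proliferation:apoptosis in the 97:28 proportion of the
curated 125-gene list, 15 miRNAs, edge density 0.3, inhibition fraction
0.3, noise SD 0.5 on the log2 scale, 20 cancer + 20 control samples.
Background miRNAs carry true log2 fold changes uniform in ±0.5 —
deliberately *below* the log2(1.5) ≈ 0.585 gate, so background
attachment is rare and driven by noise, as in a benchmark where only
planted drivers should matter. Planted drivers override this with a
stated effect and target a fixed fraction (default 30%) of the *first*
layer, so their signal must traverse the full depth of the graph. Genes
directly targeted by a driver are shifted by −log2FC/2 in the cancer
group, exercising the cell-fate DE path.

The layered (DAG-like) topology keeps shortest paths unique with high
probability, isolating the impact formula's behaviour; `cyclic = TRUE`
adds sparse back-edges to exercise cycle handling. Randomness is drawn
under a temporary RNG state (network from `seed`, expression from
`seed + 1`) and the caller's stream is restored, so no global state
leaks.

**What the generator does not emulate** — and what a green test
therefore does not establish: TCGA count distributions, library-size and
batch effects, realistic miRNA target multiplicity, correlated
gene-gene expression, or the curation quality of real pathway databases.
Recovery of a planted driver shows the pipeline's plumbing and the
ranking key are sound, not that the method's biological conclusions
transfer.

## Numerical choices

- BH adjustment delegates to `stats::p.adjust(method = "BH")` and is
  verified against an independently coded step-up oracle to $10^{-12}$.
- Shortest-path lengths come from igraph's BFS; unreachable pairs are
  `NA`, never 0 or a numeric infinity.
- Output tables serialize floats with 6 significant digits, making
  repeated runs byte-identical (a property the acceptance suite checks
  by md5).
- The trigamma inversion inside the moderated-t prior fit uses Newton
  iteration with the standard asymptotic fallbacks at both extremes.
- Degenerate inputs: empty significant-miRNA sets, cell-fate genes
  missing from the edge universe, and genes with no upstream miRNA all
  produce warnings/flags and zero contributions, never errors.

## Known limitations

- Shortest-path propagation ignores all longer routes; two networks
  differing only in redundant long paths score identically.
- No significance is attached to impact scores.
- Expression matrices are consumed as-is: no normalization, no batch
  correction (out of scope by design).
- Non-coding regulators other than miRNAs (lncRNA, circRNA) are not
  modelled.

## A worked example

The canonical two-hop topology — `mir-5` inhibits `Gene1`, which
promotes the cell-fate gene `Gene*`:

```{r toy}
edges <- data.frame(source = "Gene1", target = "Gene*",
                    sign = 1L, kind = "gene_gene")
cf <- data.frame(gene_id = "Gene*", fate_class = "proliferation")
net <- trace_upstream(edges, cf)
de <- data.frame(feature_id = "mir-5", log2fc = 2.25,
                 significant = TRUE)
targets <- data.frame(source = "mir-5", target = "Gene1",
                      sign = -1L, kind = "mirna_gene")
net <- attach_mirnas(net, targets, de)
pair_impacts(net, de)
```

The path has length $L = 2$ and sign $S = (-1)\times(+1) = -1$, so an
up-regulated miRNA (log2FC = 2.25) exerts impact
$I = -1 \times 2.25 / 2 = -1.125$ on `Gene*`: over-expression of the
miRNA represses the cell-fate gene.
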