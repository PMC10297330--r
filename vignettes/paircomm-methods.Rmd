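---
title: "Inferring intercellular crosstalk from coculture RNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring intercellular crosstalk from coculture RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircomm)
```

## The experimental design the package models

`paircomm` analyses a coculture experiment with two cell populations —
dermal papilla cells (DPCs), the inductive fibroblast population of the
hair follicle, and hair matrix cells (HMCs), the proliferating epithelial
population they instruct. Each population is profiled by bulk RNA-seq in
monoculture and in direct coculture with the other, giving four groups
(DPC, DPCsCO, HMC, HMCsCO) with replicated libraries (three per group in
the default design). The premise is that genes induced by coculture in
one cell type, when they encode ligands whose receptors are induced in
the other (or the same) cell type, mark active communication channels.

## Expression quantification and QC

Counts are converted to FPKM,

$$\mathrm{FPKM}_{gs} = \frac{c_{gs} \cdot 10^9}{\ell_g \, N_s},$$

with $\ell_g$ the transcript length in bp and $N_s$ the library size.
FPKM is used for expression filtering (a gene is *expressed* in a group
when its group-mean FPKM reaches 1 — the mean, rather than an all- or
any-replicate rule, because with three replicates a single dropout should
not veto an otherwise clearly expressed gene) and for sample-level QC.

QC operates on $\log_2(\mathrm{FPKM}+1)$: raw FPKM spans four to five
orders of magnitude, and principal components of the untransformed matrix
reflect only a handful of extreme genes. The pseudocount of 1 keeps zeros
at zero. PCA treats samples as observations (centered, not scaled);
Pearson correlation and average-linkage hierarchical clustering on the
distance $1-r$ summarize between-sample structure. Two conventions make
the output deterministic: each principal component is oriented so that
its largest-magnitude gene loading is positive, and dendrogram ties are
resolved by `hclust`'s standard ordering. All genes enter QC by default
(an expressed-only restriction is available through the expression
filter), since global similarity is the quantity of interest.

The `ddct_fold_change()` utility implements the classical
$2^{-\Delta\Delta C_t}$ relative quantification used when validating
candidate genes by qPCR against a reference gene and control condition.

## The differential-expression model

Each two-group contrast is tested with a negative-binomial Wald test on
normalized counts. Normalization uses median-of-ratios size factors
computed on the contrast's samples and rescaled to geometric mean 1.
Per gene, with group means $\mu_A,\mu_B$ of normalized counts, the effect
is

$$\widehat{\mathrm{lfc}} = \log_2\frac{\mu_A + \tfrac12}{\mu_B + \tfrac12},$$

the pseudocount handling groups with mean zero. The NB variance is
$\mu + \alpha\mu^2$. The dispersion $\alpha$ is estimated per gene by
method of moments from the within-group variances, then **moderated**
toward the across-gene median $\alpha_0$ (computed over genes with base
mean ≥ 1):

$$\alpha^* = \frac{d_0\,\alpha_0 + d_g\,\hat\alpha_g}{d_0 + d_g},
\qquad d_g = n_A + n_B - 2,\; d_0 = 10,$$

floored at $10^{-8}$. The Wald statistic divides the log2 fold change by
a delta-method standard error from the moderated variance of each group
mean, and two-sided p-values use a $t$ reference with $d_g + d_0$ degrees
of freedom. BH adjustment runs over the tested genes; genes with all-zero
counts are excluded first (changing the BH denominator accordingly) and
reported separately.

Why moderation, and why a $t$ reference? At $n = 3$ per group the raw
method-of-moments dispersion carries roughly $d_g = 4$ degrees of freedom
of noise. Plugging it into a Wald statistic with a normal reference is
anti-conservative (empirically, ≈10% of null genes reach p < 0.05);
switching to a $t_4$ reference restores calibration but destroys power —
with a handful of truly regulated genes among thousands, the BH threshold
sits deep in the $t_4$ tail and even eight-fold changes are missed. This
is precisely the failure mode that empirical-Bayes DE methods solve by
sharing dispersion information across genes, and the moderation above is
a minimal version of that idea: no mean-dispersion trend is fitted, a
single prior weight $d_0 = 10$ (mild relative to limma-style fits, which
often estimate larger prior df) pulls each gene toward the experiment-wide
typical dispersion, and the reference df rises to $d_g + d_0$, mirroring
the posterior-df accounting of moderated statistics. Under the simulated
study conditions (dispersion 0.05, triplicates) the null fraction of
p < 0.05 sits near 0.05, Poisson data stay conservative, and planted
eight-fold effects are recovered essentially completely. The cost, as
with any moderation without a trend, is mild miscalibration for genes
whose true dispersion departs far from the experiment-wide typical value;
for designs with many replicates the moderation matters little since
$d_g$ dominates.

DEGs use the conventional rule: $|\mathrm{lfc}| \ge 1$ (inclusive) and
adjusted p $< 0.05$ (strict). Externally computed contrast tables can be
supplied through `read_contrast_table()` to bypass the internal test
entirely.

## Roles, signatures and core molecules

DEG symbols are screened against a CellTalkDB-dialect ligand-receptor
table and a TF catalog. Roles are deliberately non-exclusive — a nuclear
hormone receptor like ESR1 is legitimately both receptor and TF, and
collapsing roles would silently drop communication channels. Cell-type
*signature genes* come from the contrast of the two cocultured groups:
up-side genes belong to the first cell type, down-side genes to the
second, with an optional expression floor in the owning cell type. *Core*
communication molecules for a cell type are the intersection of its
coculture-induced up-set with its signature set, partitioned by role.
Because the composition of multi-set intersections can be analysis-
specific, a generic n-way `intersect_sets()` is exposed rather than
hard-coding one choice.

## Ligand-receptor pairs and the communication score

Both strategies only admit pairs present in the database — no edges are
invented — and only **up**regulated ligands and receptors form pairs by
default (down- or mixed-direction pairing can be explored by supplying
the corresponding DEG sets directly). The communication score is the
product of the two *linear* fold changes, $CS = FC_L \times FC_R$, which
is positive, monotone in both effects, and bilinear (doubling both fold
changes quadruples the score); a log2-scale variant
(`cs_scale = "log2"`, the sum of log2 fold changes) is exposed for
sensitivity analyses. Strategy 2 takes its fold changes as magnitudes
$2^{|\mathrm{lfc}|}$ from the between-coculture contrast itself — the
strategy's own input — rather than mixing in the coculture-vs-monoculture
effects, keeping each strategy self-contained. Pairs are ranked by CS
descending with deterministic lexicographic tie-breaks.

## Signaling axes

Axis inference connects a scored pair's receptor to transcription factors
through a user-supplied directed signaling network (the ligand→receptor
edge comes from the database; the network contributes receptor-and-
downstream edges only). The algorithm is a transparent, depth-bounded
simple-path search: visit only nodes expressed in the receiver cell,
never revisit a node, stop at TF-role nodes that are upregulated in the
receiver, and keep every distinct path with at most `max_intermediates`
(default 3) intermediates. The default depth covers the axis shapes seen
in this biology — e.g. the activin cascade
INHBA→ACVR2A/ACVR2B→ACVR1/ACVR1B→SMAD3 has one intermediate — while
keeping enumeration tractable; the search is provably equivalent to
exhaustive enumeration under the same constraints (property-tested
against a recursive oracle). Requiring the terminal TF to be upregulated
(not merely expressed) follows the package's DEG-centric reading of the
design; a permissive variant is a one-argument change
(`receiver_up_tfs = <expressed TFs>`). TF hub importance within a network
is ranked by total degree in the induced TF subgraph, with lexicographic
tie order.

Gene-set enrichment, where needed, is a plain hypergeometric upper-tail
test with BH adjustment across terms.

## The simulator: what it emulates and what it does not

`simulate_experiment()` draws NB counts
($\mathrm{var} = \mu + \alpha\mu^2$, default $\alpha = 0.05$) for the
4-group × 3-replicate design, with log-normal gene baselines
(meanlog $\log 100$, sdlog 1.5 — a typical bulk RNA-seq abundance
spread), log-normal sample depths (sdlog 0.1 around 1.5 million reads),
and uniform 500–5000 bp gene lengths. Fixture-named genes (everything
mentioned by the built-in ligand-receptor, TF and network fixtures) sit
at a fixed baseline of 200 mean counts so the communication machinery is
reliably expressed, as ligand/receptor systems active in these cells
would be. Planted log2 effects are specified per (symbol, group):
signature genes at +4 in both groups of their cell type, coculture-
induced crosstalk molecules at +3 in one cocultured group. Because
effects are planted in log2 units per group, the ground truth — expected
DEG directions, pairs per mode and strategy, and axes — is derived
*analytically* from the planted table (the axis truth by an independent
recursive path enumeration), never by running the pipeline on itself.

The default fixture plants, among others, the autocrine
LEP→LEPR loop in cocultured DPCs, the paracrine IL1A→IL1R1 channel from
HMCs to DPCs, and the four-path activin axis family ending at SMAD3 in
HMCs, with decoy database pairs and decoy network branches (e.g. paths
ending at TFs left unregulated) that must *not* be recovered.

What the simulator does not emulate: GC/length bias, batch effects,
heteroskedastic dispersion trends, correlated genes, or read-level
artifacts. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated model, not that real
coculture data will yield communication channels at any particular
sensitivity.

## Problem sizes, tolerances and degenerate inputs

The validation suite uses a 2000-gene null and planted-effect simulation
for DE calibration and a 5000-gene end-to-end fixture (seed 42) for
pair/axis recovery — sizes at which the Monte-Carlo noise of the checked
fractions is comfortably below the asserted margins. Determinism is
checked at the byte level via output checksums. Numerical conventions:
dispersion floor $10^{-8}$; FPKM depth-invariance holds to $10^{-9}$
relative; correlation matrices are validated symmetric positive
semi-definite within $10^{-8}$. Degenerate inputs fail loudly rather
than silently: zero-depth samples, all-constant expression matrices,
contrasts with a single replicate, networks with undeclared edge
endpoints, and count files with fractional or negative entries all raise
errors naming the offending input.

## Known limitations

* The DE model is two-group only — no multi-factor designs, likelihood
  ratio tests, or fold-change shrinkage.
* Human symbols are matched to the study organism by case-insensitive
  equality; an ortholog table can override this, but divergent gene
  families will be under-matched.
* Receptor-complex stoichiometry and antagonists (an IL1RN-type
  antagonist dampening IL1A-IL1R1 signaling) are not modeled in the
  score.
* The communication score is a fold-change product with no significance
  measure attached; it ranks, it does not test.
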