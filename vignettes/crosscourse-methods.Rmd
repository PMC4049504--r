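---
title: "Methods: cross-cell-type analysis of stimulation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cell-type analysis of stimulation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crosscourse compares short transcriptional response time courses — typically
log2 expression measured at a handful of time points after a stimulus such
as TGF-β1 — across cell types and species. This vignette documents the
models behind each stage, the parameters that matter, the numerical choices,
and what the synthetic-study generator does and does not emulate.

## Input model

Each cell type is one `expr_timecourse`: a genes × samples log2 expression
matrix with sample metadata (time in hours, replicate, optional batch). Time
0 is the unstimulated baseline and must be present; every retained time
point needs at least two replicates. Gene identifiers are opaque,
case-sensitive strings; mouse and human genes are never joined by name, only
through a homolog table filtered at an alignment E-value below 1e-30 (strict
`<`; the accompanying bit-scores are carried but not used for filtering).
When replicate labels pair across time points, log2 fold changes are taken
within replicate (`x_t − x_0` on the same chip series); otherwise against
the mean baseline. The choice is declared on the object (`paired`), because
array studies do not always state which applies. A time point missing one
or more replicates — the "bad chip" case — is excluded from the
whole-course profile of that cell type, while the per-timepoint tests keep
whatever complete pairs remain.

Batch structure, when present, is removed before analysis with the
location-scale empirical-Bayes adjustment (ComBat, via sva) on a design that
preserves time effects. A batch confounded 1:1 with time is inestimable and
rejected.

## Whole-course differential expression

The per-timepoint analysis is the standard moderated linear-model test
(limma): a factorial design with time and, for paired designs, replicate
factors; contrast *t* vs 0; residual variances shrunk by
$\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$; BH adjustment across
genes within each time point.

Because few replicates limit per-timepoint power, the primary DE statistic
is a whole-course posterior probability. We commit to a concrete
two-component empirical-Bayes random-effects model on the replicate-mean
fold-change vectors $\bar x_g \in \mathbb R^T$ (non-baseline time points):

$$\bar x_g \sim (1-p)\, N(0, \Sigma/R) + p\, N(0, \Lambda + \Sigma/R)$$

where $R$ is the replicate count, $\Sigma$ the within-gene noise covariance
and $\Lambda$ the covariance of true mean profiles under the alternative.
$\Sigma$ is estimated as the diagonal of the pooled within-gene replicate
scatter, shrunk halfway toward its median — with $T$ small and replicates
few, a full per-gene covariance is unidentifiable, and the pooled diagonal
is a deliberate simplification (it ignores the correlation induced by the
shared baseline chip in paired designs; the mixture's $\Lambda$ absorbs most
of it). $(p, \Lambda)$ are fitted by EM on the marginal likelihood:
initialisation is deterministic ($p = 0.1$, $\Lambda$ from the top-decile
profile norms), the $\Lambda$ update is projected onto the PSD cone, and
convergence requires a relative log-likelihood change below 1e-8 within 500
iterations (weak-signal data can exhaust the budget; the best iterate is
returned with a warning). The posterior probability of differential
expression is the usual two-component odds ratio, and a gene is called DE
over the whole course when the posterior exceeds 0.99 **and** the maximum
absolute log2 fold change reaches 1 (ties at exactly 1.0 are DE-eligible;
the two-fold rule is interpreted as $|\log_2 FC| \ge 1$ uniformly).
Per-timepoint calls use FDR < 0.01 and the same fold-change rule.

## Curve clustering

DE genes (and only DE genes) are clustered on their log fold-change curves —
responses to the stimulus, not absolute expression. Each curve is a
spline-basis expansion of a cluster mean plus isotropic Gaussian noise: a
natural cubic spline with df = min(4, T−1) over the observed grid, falling
back to raw time-point coordinates when T ≤ 3. EM runs from 10
k-means-seeded restarts per K (all randomness behind one seed) and the
number of clusters is chosen by BIC (−2·loglik + params·log n; lower is
better).

The component variances carry a weak inverse-gamma prior (scale = the mean
total variance of the input curves, strength ≈ one curve's worth of
observations). Without it, restarts occasionally converge to spurious
near-zero-variance components — the unbounded-likelihood pathology of
Gaussian mixtures — and BIC then overstates K; this is the same remedy
mclust exposes as `priorControl`. A cell type with fewer than 2·min(K) DE
genes is not clustered at all: all its DE genes are reported as one group,
matching how sparse cell types must be handled in practice.

## Cluster semantic similarity

Functional similarity between clusters from different cell types uses the
Wang measure on the GO-style DAG: each term propagates S-values to its
ancestors with contribution factors 0.8 (`is_a`) and 0.6 (`part_of`), and
two terms are scored by the S-value mass of their shared ancestors relative
to their total mass. Gene-level and cluster-level similarities are
best-match averages (BMA) of the corresponding pairwise matrices; the
gene-to-cluster aggregation is this package's choice, since published
descriptions stop at the gene level. Genes annotated only to a root term
are treated as unannotated and excluded (`NA`), never scored as zero.
Cluster pairs above 0.7 are flagged as highly similar. The biological
process sub-ontology is the intended input.

## Set enrichment, commonality, reproducibility

Each gene receives a ranking score: −ln p (per-timepoint mode) or
−ln(1 − posterior) (whole-course mode), capped at 10⁻¹² before the log so
scores stay finite. Natural logarithm is used; because the association test
is invariant under positive affine rescaling of scores, the base is
cosmetic. Gene sets (KEGG-style pathways, GO terms) are tested by a
univariate logistic regression of set membership on the score, with a 1-df
likelihood-ratio test of the slope; under perfect separation a
Firth-penalised fit takes over (flagged). Sets need at least 5 scored
members and 5 non-members. Term-level p-values are adjusted by
Benjamini–Yekutieli — valid under the strong dependence between overlapping
sets — with significance at FDR < 0.05; gene-level tests use BH, exactly
splitting the two adjustments by use. The universe is all scored genes in
the tested cell type, not the whole annotation.

Plain upper-tail hypergeometric over-representation is provided alongside;
the conditional (child-eliminating) variant of GOstats is deliberately not
reimplemented, since the headline term statistics rest on the logistic test.

Commonality intersects the significant sets across all cell types and emits
a −log(FDR) matrix for heatmaps. Reproducibility against an independent
validation set reports the overlap count, the rounded percentage, and an
upper-tail hypergeometric p-value in a declared candidate universe. The
bundled 18-gene human-common and 11-gene validated lists reproduce the
published worked example: 11/18 = 61%.

## Promoter motifs

Motif discovery is a deliberately simplified XXmotif-style pipeline:
k-mers (k = 6–10) are counted on both strands (collapsed with reverse
complements), scored against an order-1 Markov background fitted on the
input by a binomial upper-tail test, and the top seeds are expanded to PWMs
by a zero-or-one-occurrence-per-sequence EM (pseudocount 0.1 per base).
Each reported motif's E-value is its seed p-value times the number of
distinct canonical k-mers scored across the whole k range — the full set of
tested hypotheses. An earlier draft multiplied by the count of seeds passing
the 0.01 pre-filter instead; that makes the expected background yield at
E ≤ 1e-3 about 0.1 motifs per run *by construction* (the pre-filter is
itself selection), so the factor was widened to all tested k-mers, after
which pure-background runs yield essentially zero false motifs while
planted-motif recovery (seed p-values around 1e-44 in the test
configurations) is untouched. Motifs at E ≤ 1e-3 are kept and greedily
deduplicated (alignment score > 0.8). Carrier promoters are those with a
log-odds hit at ≥ 80% of the PWM's maximum achievable score, on either
strand.

Instead of BLAST-based masking of local homology, exact duplicated blocks of
≥ 30 bp shared between promoters are masked to N — except blocks present in
more than half of the sequences, which are treated as candidate enrichment
signal rather than pairwise homology (this also keeps the degenerate
all-identical-input case well-defined).

Matching against a reference PWM library is a STAMP-flavoured ungapped
alignment over column offsets (≥ 4 aligned columns), scoring aligned columns
by Pearson correlation of their frequency vectors, on both orientations.
The match E-value is the empirical exceedance fraction among 1000
column-shuffled library PWMs, scaled by library size. TFBS-to-TF mapping is
a user-supplied table; the bipartite TFBS–gene output reports per-TFBS
strength as the mean −ln E over cell types and flags TFBS whose own TF genes
are DE.

## Cross-species comparison

Gene sets are projected across species as the union of all homolog partners
passing the E < 1e-30 filter; many-to-many relations are kept, and a gene
in one namespace overlaps a set in the other iff at least one passing
partner is in it (the counting convention must be fixed somewhere; it is
fixed here, in the reference namespace of the first cell type unless
configured otherwise). Pairwise overlaps report both directional fractions
and their harmonic mean 2/(1/f_A + 1/f_B) — note HM is *not* bounded by
min(f_A, f_B) in general, only by their arithmetic mean — plus a
hypergeometric p-value. The membership matrix and k-way intersections
("in all cell types") come from the same projection.

## Network path analysis

The interactome stage weights every node by the mean whole-course DE
posterior over the organism's cell types (genes measured in no cell type
get weight 0 rather than being dropped, keeping the network connected), and
assigns each edge the distance 2 − (w_u + w_v) ∈ [0, 2], so
minimum-distance paths are maximum-evidence paths. Dijkstra retains the full
shortest-path predecessor DAG; all tied paths (distances equal within 1e-9)
are enumerated by backward traversal, capped at 100 per query because
zero-distance regions make tie counts combinatorial (the cap is flagged).
Per term, only the genes attaining the global minimum distance to the source
are kept as representatives. When the configured source gene is absent from
the network — the mouse ligand case — a configured fallback (e.g. the
receptor) is used and reported. Subnetworks export to GraphML and SIF in
deterministic order.

## The synthetic-study generator

`synthetic_study_config()` defaults encode the emulated design: two species,
four cell types (plus, in the demo, an independent human validation cell
type), five-point time grids in 0–24 h, three replicates, 5% shared-core +
5% cell-type-specific DE genes, effect amplitude 2 log2 units, replicate
noise 0.5 log2 units, and no batch effect unless requested (`batch_sd` is a
free knob: real studies can exhibit strong batch structure without reporting
its magnitude, so no default is pretended). Response shapes are fixed templates on [0, 24] h,
normalised to 0 at baseline and unit peak: early (peak 2 h then decay),
late (sigmoid centred 8 h), transient (peak 4 h, returning to baseline),
monotone (linear in log-time). The homolog map is mostly 1:1 with a
configurable 1:2 fraction and E-values straddling 1e-30 (shared-core pairs
always pass, so the planted core is projectable by construction). Planted
annotations cover 90% of DE genes and 5% of background per planted term;
planted promoters carry one exact motif instance at a uniform position;
planted networks add an Erdős–Rényi background around a high-weight path.

What the generator does **not** emulate: probe-level/array effects (inputs
are already-summarised log2 matrices), heavy-tailed or gene-correlated
noise, annotation incompleteness and bias, scale-free interactome topology,
and realistic promoter composition beyond a fixed GC content. Passing tests
therefore demonstrate correctness of the algorithms under their stated
models and recoverability of planted structure — not performance on real
arrays.

## Problem sizes and reproducibility

The bundled demo (`make_demo` + `run_study`) uses 600 genes per species,
five cell types and 200 bp promoters — sizes chosen so a complete run takes
well under a minute while every planted structure remains recoverable; the
recovery simulations use 2000 genes (DE posterior AUC), 90 curves
(BIC selection), and 100 promoters of 200 bp (motifs). All randomness
derives from explicit integer seeds; identical config + seed gives
byte-identical outputs, which the test suite verifies by checksumming a
rerun. `scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes every headline quantity from scratch.

## Known limitations

- The whole-course mixture treats $\Sigma$ as diagonal; with paired fold
  changes the shared-baseline correlation is absorbed by $\Lambda$, which
  inflates the estimated DE prior $p$ on null-heavy data (the posterior
  ranking, the quantity that matters downstream, is robust to this).
- The logistic set test models membership, not scores; genuinely bimodal
  score distributions within a set can escape it.
- Motif discovery is seed-driven: motifs with no over-represented exact
  k-mer core (highly degenerate motifs) are invisible to it.
- Tie enumeration after Dijkstra is capped; in near-uniform-weight networks
  the returned path set is a sample of the tied optimum, flagged truncated.
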