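# crosscourse

Cross-cell-type analysis of stimulation-response expression time courses.

Many stimuli — TGF-β1 is the motivating case — trigger transcriptional
programs that look different in every cell type, yet share a functional
core. Given short log2 expression time courses (a few time points in 0–24 h,
2–3 replicates) from several cell types and two species, crosscourse asks:
which genes respond at all, which response curves group together, which
biological processes and pathways are hit in *every* cell type, which
promoter motifs sit behind the shared response, and along which
protein-interaction paths could the signal travel?

The toolkit covers the full arc:

- **Whole-course differential expression.** Per-gene posterior probability
  that the entire fold-change profile differs from baseline, from a
  two-component empirical-Bayes random-effects mixture on replicate-mean
  profiles: x̄_g ~ (1−p)·N(0, Σ/R) + p·N(0, Λ + Σ/R), with (p, Λ) fitted by
  EM. A gene is DE when posterior > 0.99 and max_t |log2FC| ≥ 1. Per-timepoint
  moderated tests (limma; FDR_BH < 0.01, |log2FC| ≥ 1) and ComBat batch
  adjustment round out the stage.
- **Curve clustering.** Gaussian mixture over spline-expanded log
  fold-change curves, EM with k-means restarts, number of clusters by BIC.
- **Cluster semantic similarity.** Wang-measure GO similarity
  (S-value decay 0.8/0.6 for is_a/part_of) aggregated by best-match average
  to genes and clusters; pairs > 0.7 are flagged functionally similar.
- **Set enrichment and commonality.** Per-gene ranking scores (−ln p or
  −ln(1 − posterior)) tested against gene sets by univariate logistic
  regression (LRT, Firth fallback), FDR_BY < 0.05, intersected across cell
  types; hypergeometric over-representation; reproducibility statistics
  against an independent validation dataset.
- **Promoter motifs.** Simplified de-novo discovery (k-mer seeds vs Markov
  background, ZOOPS-EM PWM refinement, E ≤ 1e-3) with STAMP-style matching
  to a reference PWM library.
- **Cross-species projection.** Homolog-table joins (E < 1e-30,
  many-to-many), membership matrices, harmonic-mean overlap fractions.
- **Network paths.** Interactome nodes weighted by mean DE posterior, edge
  distance 2 − (w_u + w_v), Dijkstra with all tied minimum-distance paths
  and per-term minimum-distance representatives.
- **Synthetic studies.** A generator that plants DE cores, curve shapes,
  enriched terms, motifs and network paths with known ground truth, so the
  whole pipeline is testable offline.

## Worked example

```r
library(crosscourse)

# a synthetic two-species study with known ground truth
cfg   <- synthetic_study_config(n_genes = 1000, seed = 42)
study <- generate_expression(cfg)

# whole-course DE for one cell type
de <- de_analysis(study$expression$MSC)
glance(de$fit)
#> # A tibble: 1 × 5
#>    p_de n_genes iterations loglik converged
#>   <dbl>   <int>      <int>  <dbl> <lgl>
#> 1 0.250    1000         18 -2497. TRUE

calls <- call_de(de)          # posterior > 0.99 and max |log2FC| >= 1
length(calls$timecourse)
#> [1] 103

# cluster the DE genes' fold-change curves, choosing K by BIC
prof <- subset_profiles(de$profiles, calls$timecourse)
cl   <- select_k_bic(prof, 2:6, seed = 1)
cl$bic_table
#> # A tibble: 5 × 3
#>       K loglik   bic
#>   <int>  <dbl> <dbl>
#> 1     2  -593. 1238.
#> 2     3  -499. 1077.
#> 3     4  -415.  937.   <- selected (lowest BIC)
#> 4     5  -413.  961.
#> 5     6  -413.  989.
```

The study planted 10% DE genes (5% shared core, 5% cell-type-specific) with
amplitude 2 and noise 0.5; `de_analysis` recovers them with posterior AUC
above 0.99, and 103 of the 1000 genes pass the joint posterior/fold-change
call. The four selected clusters correspond to the planted up/down early/late
curve families.

The bundled validation worked example reproduces the published
reproducibility arithmetic from the two printed gene lists:

```r
reproducibility(human_common_de_genes, a549_reproduced_de_genes,
                c(human_common_de_genes, sprintf("G%05d", 1:19982)))
#> # A tibble: 1 × 4
#>   n_common count percent hypergeom_p
#>      <int> <int>   <dbl>       <dbl>
#> 1       18    11      61    6.22e-36
```

11 of the 18 genes DE in both human cell types were reproduced in the
independent A549 time course — 61%, far beyond chance in a 20,000-gene
candidate universe.

For the full pipeline, `make_demo(dir, seed)` writes a complete synthetic
study (expression TSVs, GMT, ontology, promoters FASTA, PWM library, homolog
table, interactomes, config), and `run_study(config)` executes every stage
in order, writes per-stage TSVs, and scores recovery of the planted
structures against the bundled ground truth.

## Scope notes

Inputs are already-normalised log2 matrices: probe summarisation, GEO
downloads, Ensembl promoter extraction and BioGRID/KEGG queries are outside
this package — the corresponding files (TSV/GMT/OBO/FASTA/SIF) are its
interface. See `vignettes/crosscourse-methods.Rmd` for the models,
assumptions, parameter defaults and known limitations.
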