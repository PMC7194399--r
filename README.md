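# ccadigest

Common Components Analysis of anaerobic digester 16S rRNA communities.

## What this is for

Anaerobic co-digestion mixes wastewater sludge with a carbon-rich
co-substrate (e.g. fish waste or garden grass) at several proportions and
monitors both biogas performance and, via 16S rRNA sequencing, the active
microbial community. The resulting OTU count tables are large, sparse,
over-dispersed and compositional, and the community response to the
substrate gradient is spread across dominant *and* subdominant taxa —
exactly the situation where per-taxon bar charts and abundance cutoffs
miss most of the signal.

`ccadigest` is an R package for microbial ecologists and process engineers
analysing such experiments. It implements a complete ordination pipeline:

1. total-sum scaling of counts to relative abundances;
2. partition of OTUs into **ubiquitous** (present in ≥ 2 samples, kept)
   and **scarce** (discarded) sets;
3. **Pareto scaling** (center, divide by √SD);
4. **Common Components Analysis (CCA)** — orthogonal components extracted
   from a salience-weighted association matrix. For component *t* with
   per-variable weights λ (the *salience*), the converged fit satisfies
   the fixed point

   λⱼ ∝ (xⱼᵀt)², Σλⱼ = 1, and *t* = dominant eigenvector of
   W = Σⱼ λⱼ xⱼxⱼᵀ,

   with deflation X ← (I − ttᵀ)X between components. Variables that
   disperse the samples the same way end up weighted together on the same
   component — each component reads as one co-responding community;
5. **S-plot** OTU selection: OTUs whose |covariance| with the scores
   exceeds one standard deviation of the component's covariance vector;
6. interpretation: shared taxonomy cladograms of the selected loadings
   (Newick + GraPhlAn annotation export), per-sample richness, a classical
   1%-abundance overview, and Pearson correlations of component scores
   with digester performance markers (methanogenic pathway indicator,
   NH₄⁺, DIC, acetate, biogas, CO₂).

A synthetic-data generator with planted community gradients
(`generate_synthetic()`) provides ground truth for validating the whole
chain.

## Worked example

```r
library(ccadigest)

d <- generate_synthetic(synthetic_scenario(seed = 42))
d$otu
#> <otu_table> 600 OTUs x 10 samples, 73.2% zero cells

abund  <- total_sum_scale(d$otu)
part   <- prevalence_partition(abund)
part
#> <prevalence_partition> 195 ubiquitous / 405 scarce (threshold: present in >= 2 samples)

scaled <- pareto_scale(abund, keep = part$ubiquitous)
model  <- fit_cca(scaled, n_components = 2)
model
#> <cca_model> 10 samples x 195 variables, 2 component(s)
#>   CC1: 53.9% of total variation, 16 iteration(s)
#>   CC2: 16.8% of total variation, 13 iteration(s)

sel <- select_all_components(model)
recovery_metrics(d$truth, model, sel)[c("score_gradient_r", "F1")]
#> $score_gradient_r
#> [1] 0.9948...
#> $F1
#> [1] 0.868...

rep <- correlation_report(model, abund, d$taxonomy, d$metadata, d$markers)
subset(rep, series == "CC1")
#>   series    target       r  n error
#>      CC1 alpha_app  0.9806 10  <NA>
#>      CC1       NH4 -0.9858 10  <NA>
#>      CC1   acetate  0.0161 10  <NA>
```

Reading the output: CC1 captures 53.9% of the total variation and its
scores track the planted substrate gradient almost perfectly (|r| ≈ 0.99);
the S-plot rule recovers the gradient-responsive OTU groups (F1 ≈ 0.87,
with 69 OTUs selected on CC1 split into positive and negative responders).
CC1 scores correlate strongly and with opposite signs with the two
markers coupled to the gradient (alpha_app +, NH₄⁺ −) and not with the
mixture-coupled marker — the pattern one expects when a component
represents the gradient-responding community.

`run_pipeline()` runs the same chain from a YAML/list config and writes
scores/loadings/saliences/selection tables, cladogram + annotation files,
overview tables, the correlation report and a provenance manifest. A thin
CLI with `run` / `simulate` / `fit` / `report` subcommands lives at
`system.file("cli", "ccadigest.R", package = "ccadigest")`.

## Package layout

- `R/io_formats.R` — validated readers/writers (TSV, optional BIOM).
- `R/preprocess.R` — total-sum scaling, prevalence partition, Pareto.
- `R/cca.R`, `R/splot.R` — the CCA core and S-plot selection.
- `R/interpret.R`, `R/cladogram.R` — richness, overview, correlations,
  taxonomy cladograms.
- `R/synthetic.R` — scenario generator and recovery metrics.
- `R/pipeline.R` — orchestration, config, manifest.
- `vignettes/cca-pipeline.Rmd` — the methods vignette (model,
  parameters, generator design, numerical choices, limitations).
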