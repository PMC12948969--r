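# spfba — spatial flux balance analysis for spot transcriptomics

Sequencing-based spatial transcriptomics (10x Visium / Visium HD, Stereo-seq)
measures gene expression per spatial spot, but says nothing directly about
metabolic *fluxes* — the quantities that distinguish a fermenting Warburg
tumor core from oxidative stroma. `spfba` bridges that gap: it constrains a
constraint-based metabolic model with each spot's transcriptome and returns a
per-spot, per-reaction **Flux Enrichment Score (FES)** in [−1, 1], a signed,
normalized summary of the fluxes the spot's transcriptional state permits.
It is written for computational biologists analysing tumor sections or any
spatially annotated tissue with an SBML metabolic reconstruction.

## Method

For a model with stoichiometric matrix *S* and bounds *v_L ≤ v ≤ v_U*:

1. **RAS** — every reaction with a gene–protein–reaction (GPR) rule gets a
   Reaction Activity Score per spot by substituting transcript abundances
   into the rule: AND → min (complexes), OR → sum (isozymes), standard
   precedence. Unmeasured genes are pruned, not zeroed; reactions without a
   GPR are *undefined*, a distinct state from zero.
2. **FVA** — flux variability analysis on the open-medium model (all
   exchange bounds widened to magnitude 1000) gives each reaction's global
   feasible range [F^l, F^u] under S·v = 0, with no growth objective imposed.
3. **Spot bounds** — each spot's polytope is the global one shrunk per
   reaction by its relative activity:
   U_j^s = F_j^u · RAS_j^s / max_s RAS_j^s, and likewise L_j^s.
   Only ratios enter, so no hard expression threshold is needed.
4. **Corner-based sampling (CB3)** — vertices of each spot's polytope are
   sampled by repeatedly optimising random objectives (weights ~ U[−1, 1],
   rescaled by FVA magnitude, random sense). The **FES** is the centroid of
   the sampled fluxes, normalised by the FVA extreme of matching sign
   (consumption stays negative), with a 99% confidence interval.
   A parsimonious-FBA (pFBA) layer is available as the objective-driven
   baseline.
5. **Spatial statistics** — silhouette-optimised Leiden clustering per layer,
   V-measure against annotations, Welch-t region contrasts,
   Kolmogorov–Smirnov differential maps with 5% fold-change classes,
   RAS–FES concordance, vascularization/proliferation marker scores and
   subsystem-level pathway scores.

The LP core is a bounded-variable two-phase simplex (RcppArmadillo) with
warm-started batch drivers, validated against brute-force vertex enumeration
in the test suite.

## Worked example

The package ships a synthetic generator (toy central-carbon network +
spatially structured counts with known regions), so the full pipeline runs
without downloads:

```r
library(spfba)

net <- make_toy_network()
print(net)
#> metabolic_network: 17 metabolites, 21 reactions, 19 genes, 11 GPR-bearing reactions
#>   exchanges: 6; biomass: BIOMASS

ds  <- simulate_spatial_counts(net, grid = c(10, 10), seed = 7)
cfg <- run_config(model = net, expr = ds$expr, method = "cb3",
                  imputation = "magic", n_samples = 1000, seed = 42)
res <- run_pipeline(cfg)
print(res$fes)
#> fes_matrix [cb3]: 100 spots x 21 reactions, scores in [-0.613, 0.613]

rc <- region_contrast(res$fes$scores[, "EX_lac"], ds$regions,
                      "tumor_core", "stroma")
#> lactate secretion, core vs stroma: +26% (p = 9.2e-23, ***)

tapply(res$fes$scores[, "EX_lac"], ds$regions, mean)
#>  stroma  tumor_core  tumor_interface
#>   0.315       0.398            0.353
tapply(res$fes$scores[, "EX_o2"], ds$regions, mean)
#>  stroma  tumor_core  tumor_interface
#>  -0.466      -0.394           -0.437
```

Positive exchange FES means net secretion, negative means uptake. The
fermentative tumor core secretes more lactate (+26% vs stroma, Welch t-test
p ≈ 1e-22) while consuming less oxygen — the Warburg pattern the generator
encodes, recovered from counts alone.

A thin CLI covers shell use: `Rscript inst/cli/spfba.R simulate ...` writes
SBML + MTX/TSV inputs, `Rscript inst/cli/spfba.R run ...` executes the
pipeline and writes CSV artifacts plus a JSON run manifest. A toy SBML file
is bundled at `inst/extdata/toy_model.xml` for `load_model()` examples.

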