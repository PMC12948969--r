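---
title: "Methods: spatial flux balance analysis with spfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial flux balance analysis with spfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spfba` treats each spatial spot as a metabolic subsystem at steady state.
Given a stoichiometric matrix $S$ (metabolites × reactions) and flux bounds
$v_L \le v \le v_U$, the feasible set of a spot is the polytope
$\{v : S v = 0,\; L^s \le v \le U^s\}$, where the spot-specific bounds
$L^s, U^s$ shrink the globally feasible flux range of each reaction in
proportion to the spot's transcriptional support for it.

The assumptions are those of constraint-based modelling plus two specific to
the spatial setting:

* **Steady state within a spot.** Each spot is an independent, internally
  well-mixed metabolic unit. No inter-spot exchange is modelled: a spot's
  boundary is the open medium, not its neighbours. This keeps the
  per-spot problem a small LP and avoids committing to any particular
  diffusion physics.
* **Transcript abundance bounds capacity, relatively.** A reaction's
  activity score (RAS) rescales its feasible range by
  $RAS_j^s / \max_s RAS_j^s$. Only ratios across spots matter, so no
  absolute expression-to-flux calibration or hard on/off threshold is
  required — and, symmetrically, the method cannot quantify absolute flux.
* **Open medium.** All exchange reactions are widened to magnitude 1000
  (negative = uptake, positive = secretion) before the global flux
  variability analysis (FVA). Exchanges curated as irreversible keep their
  blocked direction; only the permitted one is widened.

# Stage by stage

**RAS.** GPR rules are evaluated with min for AND (a complex is limited by
its scarcest subunit) and sum for OR (isozyme capacities add), honouring
parentheses and AND-over-OR precedence. Genes absent from the expression
matrix are *pruned from the rule*: an OR loses a summand, an AND loses an
argument. The alternative — scoring missing genes as zero — would block
every complex containing a gene the platform simply did not measure, which
is a statement about the assay, not the tissue. A reaction whose genes are
all unmeasured, or which has no GPR (biomass, oxygen diffusion, maintenance),
is *undefined*: downstream it keeps its full FVA range, which is exactly
what "no information" should mean. The same logic leaves reactions whose
RAS is zero in *every* spot unconstrained: a uniformly silent column carries
no relative information, and closing it everywhere would be an absolute
claim the framework avoids.

**FVA.** Run once, globally, on the open-medium model, with no biomass
objective or objective-fraction constraint — the feasible space is delimited
by mass balance and medium alone. Extremes are clipped to the default bounds
to suppress solver round-off.

**Spot bounds.** $U_j^s = F_j^u \cdot RAS_j^s/\max_s RAS_j^s$ and likewise
$L_j^s$. Consequences worth noting: the arg-max spot recovers the exact FVA
range; a spot with zero RAS on an expressed reaction has that reaction
closed; bounds are nested inside the FVA range and preserve the sign
interval (if $F^l \le 0 \le F^u$ then $L \le 0 \le U$).

**Vertex sampling.** Each spot's polytope is sampled by corner-based random
objectives: weights drawn uniformly from $[-1, 1]$ per reaction, divided by
the reaction's FVA magnitude so that wide-range reactions do not dominate
the objective, with a random optimisation sense. Each LP lands on a vertex.
The FVA "magnitude" is taken as $\max(|F^u|, |F^l|)$; a reaction with zero
range gets weight zero (a blocked reaction cannot steer an objective, and a
literal division would be undefined). The sense draw is retained even though
weight-sign symmetry makes it formally redundant — it is part of the
procedure as described, and costs nothing. Sampling is deterministic given
the seed; failed LPs (which do not occur on the bundled models, but are
possible with hostile inputs) are skipped and counted rather than retried,
so the effective sample size in the confidence intervals stays honest.

**FES.** The centroid (mean) of the sampled fluxes — itself feasible, by
convexity — is normalised per reaction: positive values divide by $|F^u|$,
negative by $|F^l|$, zero maps to zero, results clipped to $[-1, 1]$.
Division is by the *magnitude* of the matching extreme so the score keeps
the sign of the flux: a consuming exchange stays negative. (Dividing a
negative flux by a negative minimum would flip its sign and contradict the
consumption-negative convention; the sign-preserving form is the only one
consistent with a score in $[-1,1]$ whose sign means direction.) The
centroid is computed on raw fluxes first and normalised afterwards — the
normalisation is linear only per sign region, and feasibility of the
centroid is a raw-flux-space property. Confidence intervals use the normal
approximation of the mean at level 0.99 by default (a bootstrap percentile
variant is available via `ci_method`); the interval is normalised the same
way and re-ordered so low ≤ score ≤ high.

**pFBA baseline.** Maximise biomass, then minimise $\sum_j |v_j|$ at the
fixed optimum via the standard magnitude-variable LP reformulation
($t_j \ge |v_j|$ through two slack rows per reaction). Any alternative
L1 optimum is accepted. pFBA rows get degenerate confidence intervals.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `medium_bound` | 1000 | open-medium magnitude (flux units of the model) |
| `n_samples` | 10000 | CB3 objectives per spot; the description of the procedure also mentions centroids over 1000 samples, so both scales are in use — the parameter is exposed and the acceptance-scale runs use 1000 |
| `ci_level` | 0.99 | FES confidence level |
| `target_sum` | 1e4 | per-spot total after library-size normalisation |
| `imputation` | "none" | `"magic"` enables the diffusion denoiser (below) |
| grid search | PCs {15, 30, 50}, neighbours {10, 15, 30}, resolution {0.1, 0.25, 0.5, 1.0} | clustering-parameter grids; a grid is part of the procedure but its values are not fixed by it, so these are package defaults |
| `seed` | required | drives weight draws, sense draws, PCA/Leiden and the generator |

LP tolerances are 1e-9 (feasibility and reduced-cost optimality); the
simplex refactorises its basis every iteration via LAPACK, which at these
problem sizes (tens of rows) is cheaper than being wrong. Degeneracy is
handled by switching from Dantzig to Bland's rule after a fixed iteration
budget, which guarantees termination. Fluxes below 1e-9 (relative to the
range scale) are snapped to zero before FES sign dispatch so solver noise
cannot flip a sign.

# Preprocessing choices

Counts are library-size normalised to `target_sum` and `log1p`-transformed.
Zero-count spots are dropped with a warning rather than an error: they are
an expected artifact of binning and tissue edges.

The denoiser behind `imputation = "magic"` is a Markov-affinity diffusion
smoother implemented in the package: adaptive Gaussian kernel on the kNN
graph in PCA space (bandwidth = distance to the `knn`-th neighbour, support
truncated at `3*knn` neighbours), symmetrised, row-normalised, raised to
`t_steps` powers and applied to the log-normalised layer. Defaults
(`knn = 5`, `decay = 1`, `t_steps = 3`) follow the published defaults of
the diffusion-imputation approach. Truncating the kernel support matters:
an untruncated exponential kernel lets many weak long-range affinities
outvote the few strong local ones and the operator collapses toward the
global mean. Any external denoiser can be plugged in as a function.
RAS is computed on the imputed layer when imputation is enabled, otherwise
on the log-normalised layer. Denoising is near-essential for AND-heavy
GPRs under dropout: min() over genes is destroyed by a single spurious
zero.

Clustering builds an undirected union-kNN graph from Euclidean distances in
PCA space and partitions it with Leiden (modularity objective). The
silhouette, computed in the same PCA space, drives a grid search; a
single-cluster result has no silhouette and carries a −1 sentinel, and such
combinations are never selected unless every combination is degenerate (the
result is then flagged). Ties break lexicographically toward the simpler
model: fewer PCs, fewer neighbours, lower resolution.

VisiumHD-style binning sums raw counts in `factor × factor` windows before
any normalisation, removes bins under `min_genes` detected genes, and
assigns the majority annotation only above the `annotation_majority`
proportion (default 0.5), labelling ambiguous bins "Interface".

# Downstream statistics

The V-measure (β = 1) is computed from the contingency table's conditional
entropies; layer comparisons use a one-sided Mann–Whitney test (direction:
first layer greater), with the p = 0.5 convention for all-tied inputs.
Region contrasts report $100 \cdot (\bar{x}_A - \bar{x}_B)/|\bar{x}_B|$
with a Welch t-test — the unequal-variance form is the safe default when
group variances differ, as tumor/stroma scores routinely do. The exact
fold-change denominator is not canonical; it is isolated in one function,
and means within $10^{-6} \cdot \max|x|$ of zero flag the ratio unstable
rather than reporting a meaningless number. Differential maps run a
two-sample Kolmogorov–Smirnov test per reaction and call a direction only
when both p < α (0.05) *and* |fold change| exceeds its threshold (5%);
no multiple-testing correction is applied by default, matching the
single-map usage, with Benjamini–Hochberg behind a flag. Concordance
restricts to reactions passing p < 0.05 and |FC| > 0.2 in both layers and
reports the percentage of sign agreement; an empty passing set is reported
as undefined, not as 0 or 100. Spearman correlations carry Fisher-z
confidence intervals with the Bonett–Wright standard error and can be
combined across samples by inverse-variance weighting on the z scale.

# The synthetic generator

`make_toy_network()` is a 21-reaction central-carbon miniature: glucose
uptake, lumped glycolysis (2 ATP, 2 pyruvate per glucose), reversible LDH
and lactate exchange, mitochondrial pyruvate import, PDH, a lumped TCA
(4 NADH per acetyl-CoA), oxygen-consuming respiration (2.5 ATP per NADH),
glutaminolysis, an ATP maintenance drain and a GPR-free biomass
pseudo-reaction consuming glutamate and ATP. Internal carbon-carrying
reactions are carbon-balanced. Growth is deliberately precursor-limited
(glutamate-fed) with maintenance dominating the ATP budget: in a model this
small, an ATP-dominated biomass would simply mirror respiratory capacity,
whereas real reconstructions feed biomass through many transporter- and
pathway-mediated precursors. The fermentative gene profile includes
glutaminolysis, reflecting the glutamine addiction of proliferative tumor
cells.

`simulate_spatial_counts()` lays three contiguous vertical bands
(tumor core / interface / stroma) on a rectangular grid and maps them to
metabolic regimes: fermentative (glycolysis, LDH, lactate transport and
glutaminolysis scaled by `effect`, PDH divided by it), oxidative (PDH, TCA,
respiration scaled up), hybrid (both sets at `sqrt(effect)`). Three further
features make the counts behave like real annotated tissue rather than a
bare metabolic signal: (i) each region carries a 40-gene identity program —
real tumor/stroma/interface regions differ across broad transcriptional
programs, and without them expression-space neighbourhoods (clustering,
diffusion denoising) are noise-dominated in a panel this small; (ii) tumor
regions get a global metabolic activation of `sqrt(effect)` (interface
`effect^{1/4}`) on all model genes, the enhanced metabolic transcription of
proliferating tissue; (iii) a per-spot log-normal growth-activity factor
jointly scales the model genes and the proliferation markers, encoding the
within-region coupling between replication machinery and metabolic
capacity. Marker pseudo-genes reuse the real endothelial and cell-cycle
panel names so the built-in scores run unmodified. Counts are negative
binomial (`size = 10`) around the scaled means with log-normal library-size
factors (sd 0.3 on the log scale) and Bernoulli dropout; baseline gene
means are log-normal around 30 counts, giving per-spot totals in the low
thousands — the depth scale of real spot transcriptomes.

What the generator does *not* emulate: transcriptome breadth (hundreds, not
tens of thousands of genes), spatial diffusion or neighbour exchange,
platform-specific artifacts (spot swapping, tissue-edge effects), cell-type
mixtures within spots, and any isoform- or protein-level regulation.
Passing the recovery tests therefore shows the machinery propagates a
regime-structured transcriptional signal into the correct flux geography —
not that the method is validated on real tissue.

# Problem sizes in the tests

The acceptance-scale recovery runs use the generator's stated study
conditions — a 20 × 20 grid (400 spots), effect 4, dropout 0.3, five seeds,
1000 samples per spot — and check that the fermentative region shows
significantly higher lactate-secretion FES than the stroma, that the
FES layer out-clusters the pFBA layer against ground truth (each in at
least 4 of 5 seeds), and that biomass FES correlates with the proliferation
score (mean Spearman across the seeds above 0.3). Oracle tests compare FVA
and pFBA against exhaustive vertex enumeration on 50 random networks of up
to 6 reactions; sampler calibration uses a one-dimensional polytope where
the vertex distribution is known exactly. The LP core was additionally
validated during development against an independent interior-point solver
on hundreds of random LPs.

# Known limitations

* No absolute flux quantification; scores are relative to FVA extremes.
* No thermodynamic (loopless) constraints: sampled vertices may contain
  internal cycles, which the FVA normalisation bounds but does not remove.
* One polytope per spot: no spot–spot metabolite trade, so paracrine
  effects (e.g. lactate shuttles) appear only as complementary
  uptake/secretion patterns, not as coupled constraints.
* The vertex sampler targets corners, not the uniform measure; centroids
  are summaries of the vertex distribution, not volume-uniform means.
* Undefined-RAS reactions keep full ranges; in GPR-sparse models large
  parts of the polytope are therefore transcriptome-independent.
* The dense simplex is sized for core models (hundreds of reactions);
  genome-scale reconstructions (tens of thousands) would need a sparse
  LP backend behind the same interfaces.
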