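---
title: "Methods: k-mer association analysis of nodulation competitiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer association analysis of nodulation competitiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizokmer)
```

## The problem

Rhizobial strains compete for the colonization of legume root nodules, and
strains differ consistently in how often they win. The observable phenotype is
*nodule occupancy*: after co-inoculating plants with two fluorescently tagged
strains, each nodule is scored as occupied by the tester strain (green), the
reference competitor (red), or both (mixed), and a strain's occupancy is the
fraction of nodules it holds, averaged over replicate plants. Competitiveness
is largely accessory-genome borne, so `rhizokmer` links the continuous
occupancy phenotype to genotype through k-mers — 13-nucleotide substrings that
act as reference-free variant proxies capturing both SNPs and indels — rather
than through alignment to a single reference genome.

## The association model

For each strain genome every 13-mer window is collapsed to its canonical form
(the lexicographic minimum of the window and its reverse complement), giving a
strain-by-k-mer presence/absence matrix. K-mers present in fewer than two
strains or absent from fewer than two strains carry no two-group contrast and
are rejected (`min_present = min_absent = 2`).

Because bacterial strain panels are clonal, related genomes would otherwise
count as independent evidence. The correction is the classic
sequence-weighting scheme of Gerstein, Sonnhammer and Chothia applied to a
genome dendrogram:

1. **Distance.** Jaccard distance between the full (unfiltered) k-mer
   presence profiles, $d(i,j) = 1 - |K_i \cap K_j|/|K_i \cup K_j|$. This is
   the exact, desk-scale counterpart of the sketch-based genome distances
   (e.g. MinHash) that large-scale tools use to estimate the same quantity.
2. **Tree.** UPGMA (average linkage) with merge height $d/2$, so the tree is
   ultrametric. Ties are broken deterministically toward the lowest strain
   indices, which pins the topology on degenerate (all-equal) inputs.
3. **Weights.** Each edge's length is distributed among the leaves below it
   in proportion to their accumulated weights (equally where those are zero,
   as for clones at distance 0). Weights are normalized to sum to the number
   of strains, so equal weights reduce every downstream formula to its
   unweighted form.

Each retained k-mer is then tested with a **weighted Welch two-sample
t-test** between the strains carrying it and those lacking it. With weights
$w_i$ and phenotype $x_i$, each group uses the weighted mean
$\mu_g = \sum w_i x_i / W_g$, the Kish effective sample size
$n_{\mathrm{eff},g} = W_g^2/\sum w_i^2$, and the variance
$s_g^2 = \sum w_i (x_i - \mu_g)^2 \cdot
n_{\mathrm{eff},g} / ((n_{\mathrm{eff},g}-1) W_g)$; the statistic is
$t = (\mu_1 - \mu_2) / \sqrt{s_1^2/n_{\mathrm{eff},1} +
s_2^2/n_{\mathrm{eff},2}}$ with Welch–Satterthwaite degrees of freedom on
$(s_g^2/n_{\mathrm{eff},g},\; n_{\mathrm{eff},g}-1)$. With equal weights this
is exactly the classic Welch test, a reduction the test suite checks to
1e-10 against `stats::t.test` on 1,000 random data sets. K-mers with
$p > 0.05$ (raw; screening, not inference) are discarded, matching standard
k-mer GWAS practice; Benjamini–Hochberg adjustment is available behind
`adjust = "BH"` but off by default. Zero-variance degeneracies are defined
explicitly: equal group means give $p = 1$; unequal means with zero variance
in both groups clamp $p$ to the smallest positive double rather than zero.

## Phenotypes

Per plant, occupancy fractions are counts over the plant's nodule total;
plants with zero nodules are excluded (occupancy is undefined there) rather
than scored as zero. Per competition, the cell value is the **mean of
per-plant ratios** over the replicate plants — not the ratio of pooled
counts — with the pooled estimator available via `pooled = TRUE` for
sensitivity analysis. Two phenotype modes exist: `single` (nodules held by
the tester alone) and `single_plus_mixed` (adding co-colonized nodules);
the latter dominates the former cell-wise by construction. Values entering
the GWAS are fractions in [0, 1]; percent-scale matrices are divided by 100,
and values above 100 are rejected. Competitor classes follow the standard
occupancy cut-offs — good above 60%, weak below 20% — with both boundary
values assigned to the medium class, since the defining phrases ("higher
than 60%", "below 20%") leave the closed interval [0.20, 0.60] to medium.

Strain grouping uses unscaled, column-centred PCA (SVD, with each
component's sign fixed so its largest-magnitude loading is positive) and a
pseudo-F PERMANOVA on Euclidean distances between occupancy profiles, with
the permutation p-value $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ and
Bonferroni-corrected pairwise tests for more than two groups. Euclidean
distance is the default because the upstream software used for the original
analyses does not document its metric; it is configurable.

## Predictive model

The regression uses the binary presence of the 1,000 lowest-p k-mers. With
~13 strains and ~1,000 features, ordinary least squares is unidentifiable,
so the model is an L1-regularized (lasso) linear regression, the regression
family used by k-mer GWAS tooling, over a log-spaced penalty grid
(0.001–10). Evaluation is nested cross-validation: a seeded random
partition into 3 outer folds (each strain tested exactly once), inner 3-fold
cross-validation choosing the penalty per outer fold (ties toward the
stronger penalty), and per-fold MSE, out-of-sample $R^2$ and Spearman rank
correlation averaged across folds. $R^2$ is computed against the
*training-fold* mean, so it remains defined when a test fold happens to
contain a single phenotype class; Spearman is undefined there and excluded
from the average. The final model is refit on all strains at the modal
inner-selected penalty. By default the feature ranking is global (top-1,000
on all strains, as the reference tooling does), which leaks test strains
into feature selection; `rank_in_fold = TRUE` re-ranks within each training
fold for a leakage-free estimate.

## Mapping k-mers to genomes

Selected k-mers and their reverse complements are exact-matched against
every replicon (1-based, leftmost-base positions on the forward strand;
overlapping occurrences all reported). Each occurrence is classified per
gene: a CDS hit for every gene interval overlapping the match by at least
one base (one k-mer may tag several genes); otherwise a regulatory hit for
every gene whose strand-aware upstream window — 600 nt before the CDS
start, truncated at replicon ends — overlaps the match, with
`distance_to_start` in [1, 600]; otherwise intergenic. CDS context takes
precedence over regulatory at the same occurrence, and a regulatory window
may overlap an adjacent gene's window (both are reported). Summaries count
distinct tagged genes per strain by COG category and ortholog group, tally
genes lacking ortholog annotation as unannotated CDSs, and give the
fraction of ortholog-gene hits per replicon role. Clustered hits (inter-hit
gap at most 5 kb, smaller than the accessory regions of interest but larger
than gene spacing) define candidate regions, reported when their
ortholog-group content occurs in exactly a queried carrier set.

## The synthetic data generator

No public data accompany the package, so a seeded generator produces inputs
with the statistical structure the analysis assumes: 13 strains of three
replicons (a chromosome and pSymA/pSymB-like replicons), a core backbone
shared identically up to per-strain SNPs, a strain-specific tail
(`core_fraction = 0.9` of each replicon is core), and accessory blocks
inserted at fixed intergenic backbone loci in carrier strains only. The
default causal block (2 kb, pSymA-like replicon, 4 of 13 carriers) is a
desk-scale stand-in for the tens-of-kilobases accessory regions real
analyses recover; two decoy blocks with other carrier sets keep the
association stage honest. Background sequence is i.i.d. uniform over
{A,C,G,T}, which maximizes distinct 13-mers and makes block k-mer
collisions rare; collisions that do occur in a strain's private sequence
(its own SNP windows or tail) are repaired by resampling the private base,
while collisions in the shared core are excluded from the recorded truth
set by measurement, so every recorded causal k-mer is verified to occur in
all carriers and no non-carrier. Replicons are linear; no k-mer spans a
circular origin.

Parameter defaults and their reasoning:

* `snp_rate = 0.003` substitutions per core bp per strain: matches the
  terminal-branch scale of core-gene divergence in sequenced *S. meliloti*
  strain panels (core-gene trees for a dozen strains have total branch
  lengths near 0.03 substitutions per site).
* `phenotype_base = 0.25`, `beta = 0.40`, `noise_sd = 0.05`: non-carriers
  sit at 25% occupancy, carriers at 65%, reproducing the good-vs-medium
  contrast of real competition assays on the [0, 1] occupancy scale.
* `plants_per_competition = 6`: the replication level of the competition
  assay design this emulates.
* `nodules_per_plant_mean = 15` (Poisson, conditioned on at least one
  nodule): a typical alfalfa nodule count four weeks post-inoculation.
* `p_mix = 0.15`: mixed (co-colonized) nodules are reported as abundant but
  without a rate; 15% is a plausible default and configurable. Note that
  under the generative model the observable single occupancy is
  `phenotype * (1 - p_mix)`, so estimated occupancies sit slightly below
  the latent phenotype.
* Replicon lengths 12/8/6 kb: desk-scale stand-ins for the megabase-sized
  replicons, chosen so the full pipeline (about 350,000 windows per run)
  executes in seconds; the test suite runs it across 20 seeds.

What the generator does **not** emulate: realistic codon usage or GC
content, genome rearrangements, horizontal transfer, plasmid copy number,
and phenotype heterogeneity among non-carriers (real weak/medium
competitors spread over 0–50% occupancy, while simulated non-carriers are
homogeneous around the base value). Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under controlled signal and noise,
not performance on real genome panels.

## Numerical and design choices

* Canonical k-mers collapse strand, since assemblies have arbitrary
  orientation; the mapping stage searches both strands to match.
* Presence means count ≥ 1; no abundance threshold.
* Association rows sort by p ascending, ties by |t| descending, then k-mer
  string (C-locale radix order), making the table byte-reproducible.
* UPGMA tie-breaking, the PERMANOVA permutation count, fold assignments and
  every stochastic stage are seeded; the pipeline is byte-deterministic for
  fixed inputs and seed.
* A known limitation of the per-k-mer Welch screen at small n: k-mer
  presence patterns that isolate two or three strains with nearly identical
  phenotype values (such patterns arise wherever two strains share SNP
  positions within one window) have near-zero within-group variance and can
  out-rank the true carrier split in p-value. The causal block is still
  recovered by the carrier-set selection and by the regression stage, but
  the single lowest-p k-mer is not guaranteed to be causal under realistic
  SNP densities — worth remembering when interpreting top hits on real
  panels too.
* The simulated study conditions are fixed by `sim_config()` defaults; the
  acceptance script regenerates them from a caller-supplied seed only.

## Problem sizes used by the test suite

Unit tests run a 6-strain, 7-kb fixture; end-to-end properties use the full
13-strain, 26-kb default configuration (20 seeds for recovery and null
checks, 1,000 simulated data sets for PERMANOVA calibration, 1,000 random
data sets for the Welch reduction). These sizes were chosen so the complete
suite finishes in a few minutes on one CPU while keeping every estimate's
Monte-Carlo error well below the asserted margins.
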