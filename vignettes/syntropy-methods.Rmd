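---
title: "Methods: integrative microbiome-metabolome correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative microbiome-metabolome correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`syntropy` analyses paired observations of a microbial community (a 16S
OTU count table) and its chemical environment (a UPLC-MS metabolite
intensity table) from the same subjects. The question throughout is
*syntropy*: how statistically interdependent the two measurements are, and
which taxa, metabolites and imputed functions carry that interdependence.
The pipeline runs, in order: preprocessing; metabolite module construction;
the inter-omic Spearman network under q-value FDR control; global
concordance tests; metabolite-driven microbial clustering; pathway
differentiation tests; SparCC-based community-structure permutation tests;
and putative metabolite identification with cross-region matching.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
establish.

# Preprocessing

OTU tables are rarefied to a common depth (default 30,000 reads per
sample); samples below the target depth are dropped with a warning rather
than erroring, which is the common practice when a few samples undershoot.
Two detection filters follow, both with inclusive "at least" boundaries:
features detected in at least 2 samples are kept, and analytes measured
above background in fewer than 18% of subjects are removed (an analyte at
exactly 18% is retained, because 18% is not *fewer* than 18%). "Above
background" is operationalised as strictly positive after upstream
processing, with the background level configurable, since mass-spectrometry
pipelines differ in what they emit for undetected features. The prevalence
denominator is the number of samples in the merged per-region dataset; when
a subject contributes one sample per region the filter is applied per
region, and this is flagged in the documentation because the alternative
(counting subjects across regions) is also defensible.

Metabolite intensities are log-transformed before any correlation-based
stage (module construction, PCA, coinertia). MS intensities are
multiplicative and right-skewed; Pearson-based machinery (soft-thresholded
adjacency, eigenmetabolites, PCA) behaves far better on the log scale,
while Spearman-based stages are invariant to the transform.

# Metabolite modules

Co-occurring metabolites are collapsed into modules before the inter-omic
screen, because metabolites from one biochemical pathway rise and fall
together and would otherwise contribute thousands of nearly duplicate
tests. The construction is the weighted-correlation-network recipe: an
unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta`, the topological overlap
transform, average-linkage clustering of `1 - TOM`, and a branch cut with a
minimum module size of 10 metabolites.

The soft power `beta` is chosen by [pick_soft_threshold()] as the smallest
candidate whose connectivity distribution is approximately scale-free
(binned log-log regression `R^2 >= 0.8`, with the index zeroed when the
slope is positive); the candidate grid includes high powers (up to 32)
because metabolite correlation matrices are much denser than transcriptome
ones and can need aggressive thresholding. The network is unsigned since
module membership should capture co-regulation regardless of orientation.
The scale-free criterion, however, presumes a scale-free network; on
modular-plus-noise correlation structure its `R^2` sequence is
non-monotone across powers and can land on extreme values, so the
automatic choice in [metabolite_modules()] is constrained to the
conventional unsigned-network range 6-14: the field's sample-size fallback
default at the low end, and at the high end the largest power at which a
strong within-module correlation (~0.8) still retains a few percent
adjacency, beyond which genuine modules fragment in the tree. An explicit
power (for instance the high powers appropriate to very tightly correlated
metabolomes) bypasses the constraint.

The branch cut is adaptive: candidate cut heights are scanned over the
tree's merge heights and the cut producing the most branches of at least
the minimum size wins (ties resolved towards clustering more metabolites,
then towards the higher cut). One guard matters: objects that join the
tree only at its very top share essentially no topological overlap, so
branches are only recognised below 99% of the top merge height; without
this cap, the unclustered noise metabolites coalesce into one spurious
catch-all module. This mirrors the conventional 0.99 static cut for
topological-overlap trees.

The tree cut only *seeds* the modules. Membership is then refined against
the module eigenmetabolites, iterated to a fixed point: modules whose
eigenmetabolites correlate above 0.75 are merged (fragments of one
co-occurrence structure split by an aggressive power); members whose
module-membership correlation |kME| falls below 0.5 are released (loosely
attached noise absorbed by a permissive cut); and unclustered metabolites
with |kME| at or above 0.5 are adopted. The final membership rule is
therefore uniform - a metabolite belongs to the module whose
eigenmetabolite it correlates with at |kME| >= 0.5 - and 0.5 corresponds
to roughly three null standard deviations of a correlation at ~50 samples.
This is the classical weighted-network recipe (cut, kME pruning,
reassignment, close-module merging), and it is what makes the recovered
partition robust to the soft-power choice.

Each module is summarised by its *eigenmetabolite*: the first left singular
vector of the per-metabolite standardised module submatrix, oriented so
its mean correlation with members is positive. Standardising first makes
the summary scale-free; the explained variance (first squared singular
value over the total) is reported per module. Downstream analyses use the
eigenmetabolites concatenated with the raw unclustered metabolites.

Module validity is checked three ways: silhouette width on `1 - Pearson`
distances, cophenetic correlation of the module tree against its input
dissimilarity, and adjusted-Rand agreement with two independent
clusterings (plain average-linkage on `1 - Pearson`, and k-means at the
same k).

# The inter-omic network

Every (OTU, analyte) pair receives a Spearman rank correlation (midranks
for ties), chosen over Pearson because monotone but non-linear
relationships are expected between taxa and metabolites. Pairs with zero
variance on either side have undefined rank correlation and are excluded
with a logged count.

**p-values.** With roughly 10^5 correlations screened at q < 0.2, the only
part of the null distribution that matters is the far tail (p around
alpha/m, i.e. 10^-5 to 10^-6). The classical t approximation to the
Spearman null is anti-conservative there by a factor of 1.5-1.7 at n = 46
(measured against a 2-million-draw permutation null), which inflates the
realised false-discovery rate well above the nominal level; the Edgeworth
series correction degenerates entirely (negative tail mass) for |rho|
beyond about 0.5 at that sample size. The package therefore uses a pooled
sample-permutation null for n >= 10: the analyte table's rows are permuted
(default 200 times), every null |rho| across all pairs is pooled into one
reference distribution, and each observed |rho| receives the add-one
empirical two-sided p. The pooled null is calibrated by construction at the
scale where the FDR screen reads it, with resolution about `1/(200 m)`,
and tied columns contribute their own tie patterns to the pool. Below 10
samples the exact per-pair permutation distribution is used instead.

**q-values.** FDR control uses Storey q-values: `pi0` is estimated on the
lambda grid 0.05-0.95, smoothed with a cubic spline (df = 3) and read at
the end of the grid; when the smoother leaves (0, 1] the estimate falls
back to 1, which reduces the q-values exactly to Benjamini-Hochberg - the
conservative direction. The significance threshold q < 0.2 is strict: an
edge at exactly 0.2 is not called. Genus-level summaries collapse
duplicate metabolite correlations within a genus to a single interaction,
and OTUs lacking genus-rank resolution (empty or bare `g__`) are excluded.

# Global concordance

Both tables are ordinated by PCA under Euclidean geometry (equivalently,
classical scaling of Euclidean distances), and two complementary global
tests are run on the same samples:

* **Symmetric Procrustes.** Both 2-D score configurations are centred and
  scaled to unit sum of squares; the optimal rotation comes from the SVD
  of the cross-product; the statistic is the residual
  `m12^2 = 1 - (sum of singular values)^2`. Significance is by permutation
  of the sample rows of one configuration, `p = (1 + #{congruence >=
  observed}) / (1 + n_perm)`. Two axes are used by default because the
  superimposition is of 2-D PC plots; the axis count is configurable.
* **Coinertia RV.** The RV coefficient
  `trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2))` on the
  column-centred raw tables, with a Monte Carlo row-permutation p. Whether
  coinertia should consume raw centred tables or PCA-reduced ones is
  genuinely ambiguous in the tradition this follows; both are supported
  and raw-centred is the default, since reduction discards covariance
  directions the RV statistic is designed to weigh. Per-feature weights
  (norms of the loadings on the first two coinertia axes) rank features by
  their contribution to the shared structure.

The default permutation count is 999, so the smallest attainable p is
0.001.

# Microbial clusters from metabolite correlations

OTUs are stratified by their *correlation profiles*: rows of the full
(unthresholded) rho matrix, restricted to analytes with at least 2
significant OTU edges. Cells whose rho was undefined are imputed as zero so
that Euclidean geometry sees complete rows (the count is logged).
Clustering is complete-linkage on Euclidean distances, cut to exactly k
groups at the minimal height that yields k; when tied merge heights make k
unattainable by any horizontal cut, the partition is refined by splitting
at internal merges and the event is logged - the same situation the
original analysis hit when "no cut height allowed six" clusters.

The number of clusters is chosen by *prediction strength*: repeated 2-fold
splits, k-means on both halves, test points classified to nearest training
centroid, and `ps(k)` the minimum over test clusters of the fraction of
co-assigned test pairs that the training centroids also co-assign. The
selection threshold 0.8 is the conventional default and is exposed in the
configuration. Cross-region reproducibility is quantified per cluster pair
with a one-sided (greater) Fisher exact test on shared-OTU membership,
Bonferroni-corrected over all k1 x k2 cells at P < 0.05.

# Functional profiles

Imputed per-OTU pathway profiles (the output shape of
16S-based metagenome imputation followed by gene-to-pathway assignment)
are consumed as an OTU x pathway relative-abundance matrix; the
`single_count_profile_convention()` helper emits the identity count table
used to obtain one imputed metagenome per OTU from external tools.
Pathways are tested for differentiation across microbial clusters with the
tie-corrected Kruskal-Wallis H, Bonferroni-corrected over pathways
(P < 0.05), with per-cluster enrichment directions from mean ranks.

The metabolite-metagenome concordance statistic asks, for each identified
metabolite: is the profile of that metabolite's correlations across *all*
OTUs (vector A) concordant with the candidate source pathway's imputed
abundance across the same OTUs (vector B)? Metabolites qualify with at
least 5 significant OTU edges and at least one putative identification;
records are Pearson correlations of A and B, Bonferroni-corrected over the
tested (metabolite, pathway) records, and categorised
positive/negative/not-significant. OTUs with undefined rho are dropped
pairwise and the overlap length is reported per record.

# Community structure of metabolite-associated microbes

SparCC estimates basis (absolute-abundance) correlations from compositional
counts: per Dirichlet posterior draw of the underlying fractions (uniform
prior, which also resolves zeros), log-ratio variances `T_ij` are computed,
basis variances are solved under the sparsity approximation, and the
strongest-correlated pair is iteratively excluded from the linear system
(up to 10 rounds, threshold 0.1) before the median over draws (default 20)
is reported. These defaults follow the reference conventions for the
method and are all configurable.

The permutation test asks whether the OTUs sharing a metabolite
association are more co-structured than random same-size OTU sets from the
same presence-filtered table (presence in at least 6 samples). Four
statistics are read off the group's correlation submatrix - mean positive,
mean negative, counts above 0.2 and below -0.2 - each compared separately
against 1,000 permuted groups with the add-one correction ("stronger"
means larger mean positive, more negative mean negative, larger counts).
Count columns are reported as ordered pairs (hence even numbers) by
default, with an unordered option.

One design choice needs explanation. A group whose members co-vary through
a shared factor with equal loadings leaves *no trace in its own internal
log-ratios*: the factor cancels in every `log(f_i/f_j)`, so SparCC run on
the group's submatrix alone is provably blind to exactly the cooperative
structure the test targets. The default (`scope = "full"`) therefore
estimates SparCC once on the whole table - where sparsity holds and the
group is identifiable against the background - and reads the group's and
every permuted group's statistics off submatrices of that single estimate.
The literal per-group re-run is retained as `scope = "subtable"`. The full
scope is also far cheaper (one estimation instead of 1,001) and makes the
permutation comparison exact, since observed and permuted groups are
evaluated under the same estimate.

Total branch length of a metabolite-associated group is the induced
subtree of the supplied phylogeny (stem above the MRCA excluded; a single
tip has zero length); when no phylogeny is supplied a taxonomy-derived
cladogram with unit branch lengths is the logged surrogate.

# Metabolite identification and cross-region matching

Putative identification is adduct-adjusted exact-mass lookup: for each
adduct rule of the feature's mode (`[M+H]+`, `[M+Na]+` in ESI+; `[M-H]-`,
`[M+Cl]-` in ESI-), the neutral mass is `mz - shift` and database
compounds within 20 ppm (inclusive) are candidates, sorted by |ppm error|.
The proton and sodium shifts carry the electron-mass correction
(+1.007276, +22.989218); the chloride shift (+34.968853) is the atomic
mass without it - a fixed, documented constant choice, as the sub-mDa
difference is far inside the 20 ppm window for any plausible mass. An
origin-class post-filter (mammalian/bacterial/plant) can narrow candidate
lists. The packaged compound table is a small curated set of gut-relevant
compounds with masses computed from molecular formulas; it is a
demonstration fixture, not a replacement for the large public databases.

Two features measured in different regions are declared the same
metabolite only when BOTH |dm/z| <= 0.005 AND |dRT| <= 0.04 minutes (both
inclusive; comparisons carry a 1e-9 guard against floating-point
representation error at exact boundaries). Multi-hit ambiguity is resolved
greedily one-to-one by ascending combined normalised distance, ties broken
by smaller mass difference, which makes the matching symmetric in its
arguments.

# The synthetic-data generator

The generator plants every structure the pipeline claims to recover, so
each stage can be validated against known truth. Its defaults are the
study conditions the package is validated under: 46 subjects per region,
300 OTUs, 200 metabolite features, read depth Poisson around 30,000,
3 metabolite modules of 15-25 members with within-module correlation 0.8,
30 planted OTU-metabolite links at target |Spearman| 0.6 (30% negative),
and 3 planted guilds of 10 OTUs at basis correlation 0.7.

* **Counts.** Basis log-abundances are multivariate normal with
  heterogeneous means (SD 1.5 across OTUs, giving a realistic rank-
  abundance spread) and guild-block correlation; per-sample compositions
  are the softmax, and counts are multinomial at Poisson-varying depth, so
  rarefaction is exercised nontrivially. This log-normal-basis +
  multinomial construction is the standard validation model for
  compositional correlation estimators, which makes truth recovery
  well-defined for SparCC.
* **Metabolites.** Log-intensities are latent-factor module members
  (pairwise correlation = `module_corr`), independent noise, or - for
  planted links - `a x (normal scores of the linked OTU's relative
  abundance) + sqrt(1-a^2) x noise` with `a = 2 sin(pi rho_s / 6)`, the
  Gaussian-copula coefficient whose population Spearman equals the target.
  The contribution is additive and rank-preserving, so Spearman rather
  than Pearson is the natural detector. Intensities are `exp(8 + 0.7 z)`:
  the log-normal form is a modelling convenience (mucosal metabolite
  intensity distributions are not published for this design), not a claim
  about real data.
* **Pathways.** Each planted link gets a linked pathway whose abundance
  across OTUs is a monotone (exponential) function of each OTU's expected
  correlation with the linked metabolite, times log-normal noise - so the
  concordance stage has a planted positive signal.
* **Shared features.** A configurable fraction of metabolite identities
  (always including module members and link metabolites) appears in both
  regions, with N(0, 0.001) m/z and N(0, 0.01) minute jitter in the second
  region; region-unique identities sit on a 0.02 m/z grid, keeping them
  more than 0.01 m/z from every shared mass.
* **Taxonomy and phylogeny.** Seven-rank strings over six phyla with
  Bacteroidetes and Firmicutes dominant (as in colonic mucosa), about 60%
  of OTUs carrying genus-level resolution; a pure-birth tree with positive
  branch lengths covers the OTUs.

What passing synthetic validation does *not* show: the generator has no
batch effects, no saturation or censoring at the detection limit, no
chimeric OTUs, no correlated measurement error between the two platforms,
and its planted links are bivariate monotone by construction. Results on
real mucosal data depend on those nuisances; the validation establishes
correctness of the machinery, not field performance.

# Problem sizes used in validation

The test suite exercises the study-scale conditions (46 samples, 300 OTUs,
200 metabolites) directly for the network, module, SparCC and
community-structure checks; permutation counts are scaled to 199-200 for
the calibration studies (from the 999-1,000 analysis defaults), and the
Monte-Carlo reference intervals frozen into the tests come from 300-1,000
replicate re-simulations of the same generative model
(`scripts/oracles.R`). The pipeline determinism check runs on a smaller
bundle (40 subjects, 60 OTUs, 60 metabolites) twice end to end and
compares output hashes.

# Known limitations

* Storey's `pi0` smoother is read at the end of its lambda grid; with
  fewer than ~100 tests the estimate is unstable and the implementation
  falls back to `pi0 = 1` (plain BH).
* SparCC's sparsity approximation biases dense correlation structure
  towards zero even in full scope; estimates for groups comprising a large
  fraction of the community should be read qualitatively.
* The prediction-strength selector assumes roughly balanced, spherical
  clusters (it classifies by nearest centroid); elongated correlation-
  profile clusters can depress `ps(k)` below 0.8 for the true k.
* Putative identification is mass-only; isomers are indistinguishable and
  every candidate list is exactly that - candidates.
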