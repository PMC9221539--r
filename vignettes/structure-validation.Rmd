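---
title: "Validating predicted structures against crystal ensembles with structval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted structures against crystal ensembles with structval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structval)
```

## The validation problem

Crystal structures of the same protein differ from one another: different
crystallization conditions, different lattices and different resolutions all
move atoms around, mostly in loops and termini. A predicted model is
trustworthy for structural analysis when its deviation from the crystal
structures is no larger than the deviation the crystal structures show among
themselves. `structval` operationalizes that comparison with two
complementary dissimilarities, an ensemble clustering test, and supporting
statistics.

## The two metrics

**Superposition RMSD.** For paired coordinate sets the Kabsch algorithm
finds the proper rotation and translation minimizing the root-mean-square
deviation. We solve it by SVD of the 3×3 cross-covariance matrix with the
usual determinant correction, so reflections are never returned (the
determinant of the rotation is +1 to 1e-9). Comparisons run at three atom
levels: Cα only, main chain (N, Cα, C, O), and all heavy atoms common by
name between the paired residues — hydrogens are absent from most crystal
models, so they never enter. Residue-wise deviation profiles use a *single
global* superposition followed by per-residue RMSD over the mapped atoms;
no sliding-window refitting, so large local excursions are visible against
a stable frame.

**IRDM metric.** The inter-residue distance map (IRDM) of a structure with
$n$ residues is the $n\times n$ matrix $D$ of Cα–Cα Euclidean distances.
Each residue is thereby re-indexed by its distances to all residues. For two
aligned structures, residue $i$ carries the row distance
$e_i = \sqrt{\sum_j (D_1[i,j]-D_2[i,j])^2}$ and the overall metric is

$$\mathrm{IRDM}(D_1,D_2) \;=\; \sqrt{\tfrac1n \sum_i e_i^2}
  \;=\; \frac{\lVert D_1 - D_2\rVert_F}{\sqrt n}.$$

The two natural phrasings of this quantity — a root mean of summed squared
row differences, and a root-mean-square of the per-residue Euclidean
distances $e_i$ — describe the same number, and the package implements that
single definition; a test asserts the Frobenius identity to 1e-12. Because
distance maps are invariant under rigid motion *and reflection*, the metric
needs no superposition but cannot distinguish a structure from its mirror
image; a dedicated test documents that a chiral four-point set and its
mirror have IRDM 0 while Kabsch RMSD is 0.5 Å.

For ensembles, all IRDM (and RMSD) comparisons are restricted by default to
the ensemble-wide common residue set, so every pairwise value shares one $n$
and the dissimilarity matrix is coherent for clustering; a pairwise-common
mode is available through `common = "pairwise"`.

## Residue correspondence

Residues are matched by author numbering `(chain, seqnum, insertion-code)`,
not by sequence alignment: AlphaFold DB models use UniProt numbering, which
coincides with PDB author numbering for the proteins this workflow targets.
A `chain_map` argument covers renamed chains. Residue-name mismatches
(engineered mutations in crystal constructs) are kept but flagged, and
all-atom comparisons use only atom names present in both residues, so a
mutated side chain contributes its common atoms only. Alternate locations
are resolved at read time to the highest-occupancy conformer (ties go to
file order); hydrogens, waters and hetero groups are dropped unconditionally
since no metric here uses them.

## Ensemble clustering and the outlier null

`hcluster()` performs agglomerative clustering on the dissimilarity matrix.
Average linkage (UPGMA) is the default — no linkage is canonical for this
task, and the choice is exposed (`complete`, `single`) because cluster
composition near a cut height can depend on it. Heights are in the metric's
units (Å). The validation design phrases the null hypothesis as: *the
predicted model is an outlier group, separate from the crystal structures.*
`outlier_test()` cuts the tree at a height and reports whether the model
sits alone; rejecting singleton status at a height comparable to the
crystal-vs-crystal spread is the evidence of interest. `group_comparison()`
supports the companion boxplot-style summary: the $m$ model-vs-crystal
values against the $m(m-1)/2$ crystal-vs-crystal values, tested by Welch's
*t*. That split is the only consistent reading of a single designated
member against the rest, and it is recomputed directly from the matrix.

## Confidence statistics

pLDDT is taken from the B-factor column of predicted models (the AlphaFold
DB convention); `extract_profile()` validates the 0–100 range. The
confidence–flexibility link uses the Spearman rank correlation (monotone,
not linear, association is the claim), with the *p*-value from the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation on $n-2$ df; mid-ranks
handle ties. PAE matrices (both public JSON dialects) are reduced to one
value per residue before correlating with B-factors; the reduction is the
row mean by default and configurable (`row`, `col`, `sym`) because no
canonical reduction exists — rows and columns of a PAE matrix are not
symmetric in meaning. All tests are two-sided. Confidence categories use
the three-band thresholds high ≥ 98.5, medium ≥ 96.0, low < 96.0.

## SASA and buried interface area

Solvent accessibility uses the Shrake–Rupley construction: each atom's van
der Waals sphere (Bondi-style element radii; C 1.70, N 1.55, O 1.52, S 1.80
Å, …) is inflated by the probe radius (default 1.4 Å, water) and covered
with a deterministic golden-spiral point set (default 960 points), counting
points outside every neighbour's inflated sphere. The golden spiral makes
results reproducible bit-for-bit with no random state. Single isolated
atoms recover the closed form $4\pi(r+p)^2$ exactly at any point count; a
two-sphere configuration matches the analytic spherical-cap value within
0.5% at 960 points. Buried interface area between residue groups A and B is
SASA(A) + SASA(B) − SASA(A∪B), computed by default on the two groups alone
(the pairwise interface); `context = TRUE` keeps the remaining atoms present
in all three terms instead. Convergence is monotone: totals move < 0.5% per
doubling of the point count from 960 up.

## Motif scanning and enrichment

The PROSITE subset supported: residue letters, `x`, `[..]` alternatives,
`{..}` exclusions, `(n)`/`(n,m)` repetitions, and the `<`/`>` anchors.
Every start position is tested independently, so overlapping matches are
all counted — `P-x-L-x-P` on `PALAPALAP` hits at 1 and 5, and note that
`PALAPNLRP` contains the motif twice (`PALAP`, then `PNLRP` from the
second P). Enrichment is the ratio of matches per query protein to expected
random matches per background sequence; the shipped defaults (10 318
expected matches in ~100 000 sequences) describe the public background for
`P-x-L-x-P`. Since no per-motif test is canonical for this ratio, we use a
Poisson count model — under the null the query-list match total is Poisson
with mean $\lambda = n_\text{proteins} \times \text{background rate}$ —
with the upper-tail $P(X \ge k)$, and Benjamini–Hochberg FDR across motifs
tested together. Background counts are interpreted as match counts, not
sequences-with-a-match.

## The synthetic generator and what it does (not) show

`make_ensemble()` emulates ensemble variability by adding iid Gaussian
displacements (per-residue, per-coordinate s.d. $\sigma_i$) to an ideal
Cα geometry (helix with 1.5 Å rise, 100°/residue, 2.3 Å radius; or a seeded
coil), optionally followed by random rigid motions. Ground truth follows
the crystallographic relations $B_i = 8\pi^2\sigma_i^2$ and a monotone
decreasing pLDDT map $100 - 40\,\sigma_i/\sigma_{max}$ clipped to
[50, 100] — any monotone map suffices for sign-recovery tests. Under iid
noise $E[\mathrm{RMSD}^2] = 3\sigma^2$ against the base and
$3(\sigma_i^2+\sigma_j^2)$ between members, which the tests check within
10%. Planted clusters are made by a hinge-like offset of the second half of
the chain (a whole-body offset would vanish under superposition), giving
groups whose separation is an order of magnitude above the within-group
spread.

The generator is deliberately idealized: no physical backbone (φ/ψ), no
correlated domain motions, no lattice contacts, no missing loops beyond
what the caller deletes. Passing tests therefore demonstrate the *metrics
and statistics* are computed correctly under known truth — they do not
certify behaviour on pathologies of real crystallographic data (disordered
regions modelled differently by different depositors, alternate
conformations beyond the altloc policy, non-isotropic displacement).

## Problem sizes and numerical choices

The test suite and the reproduction script run on ensembles of up to 300
residues and 6 members, 960–10 000 SASA points, and 150-residue confidence
profiles — sizes at which every expectation used has comfortably converged.
Collinear point sets in superposition warn rather than fail (tiny fixtures
are legitimate); ties in hierarchical clustering follow `stats::hclust`'s
deterministic order; the IRDM metric is exactly zero on identical maps and
the triangle inequality is property-tested on random Euclidean matrices.
Known limitations: residue matching never falls back to sequence alignment
(renumbered models need an explicit chain/numbering fix upstream), NMR
multi-model files use model 1 only, and analyses of real ensembles require
the corresponding public coordinate sets as inputs — the package ships
none.
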