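# structval

Tools for deciding whether a predicted protein structure (an AlphaFold model,
say) can stand in for experimental structures: is the model's deviation from
the crystal structures any larger than the deviations the crystal structures
show among themselves?

`structval` is aimed at structural biologists validating predicted models
against an ensemble of crystal structures of the same (or a homologous)
protein. It provides:

- **IRDM dissimilarity** — the inter-residue distance map of a structure with
  *n* residues is the *n* × *n* matrix *D* of Cα–Cα Euclidean distances.
  For two aligned structures the per-residue difference is the row norm
  *e*ᵢ = √Σⱼ (D₁\[i,j\] − D₂\[i,j\])², and the overall dissimilarity is

      IRDM metric = sqrt( (1/n) Σᵢ eᵢ² )  =  ‖D₁ − D₂‖_F / √n   (Å)

  Distance maps are translation- and rotation-invariant, so this metric needs
  no superposition (and, unlike RMSD, is blind to chirality).
- **Kabsch superposition RMSD** at Cα, main-chain (N, Cα, C, O) and all-atom
  levels, with residue-wise deviation profiles after one global fit.
- **Ensemble analysis** — pairwise dissimilarity matrices, hierarchical
  clustering (UPGMA default) with Newick export, an outlier test (is the
  predicted model a singleton cluster at a given cut height?), group
  comparison by Welch's *t*-test, and resolution–deviation correlation.
- **Confidence statistics** — Spearman correlation of per-residue pLDDT
  against crystallographic B-factors, Pearson correlation of predicted
  aligned error (PAE) against B-factors, and the high/medium/low confidence
  banding (≥98.5 / ≥96.0 / <96.0).
- **Shrake–Rupley SASA** and buried interface area between two residue
  groups: SASA(A) + SASA(B) − SASA(A∪B).
- **PROSITE-style motif scanning** (e.g. `P-x-L-x-P`) with a Poisson
  fold-enrichment test against a sequence background and Benjamini–Hochberg
  FDR across motifs.
- **A synthetic-structure generator** with known ground truth (per-residue
  noise σᵢ, B = 8π²σᵢ², monotone pLDDT), so every stage is testable without
  downloading anything.

Structures are tibbles of atoms; results come back as tibbles or small S3
objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(structval)

# a synthetic ensemble: 6 members, 0.1 A noise, two planted conformations
ens <- make_ensemble(n_residues = 100, n_members = 6, sigma = 0.1,
                     group_offset = c(0, 0, 0, 6, 6, 6), seed = 103)
d <- pairwise_dissimilarity(ens$structures, "rmsd")
round(d$values[1:3, 4:6], 2)
#>      m4   m5   m6
#> m1 1.52 1.54 1.51
#> m2 1.52 1.54 1.51
#> m3 1.52 1.54 1.51

tree <- hcluster(d)                       # UPGMA on the RMSD matrix
cut_clusters(tree, 1.0)
#> # A tibble: 6 x 2
#>   label cluster
#> 1 m1          1
#> 2 m2          1
#> 3 m3          1
#> 4 m4          2
#> 5 m5          2
#> 6 m6          2

outlier_test(tree, "m1", 1.0)$is_singleton
#> [1] FALSE                               # m1 clusters with m2, m3

# motif enrichment: 13 PXLXP matches in 19 proteins vs the public background
motif_enrichment(13, 19, background_matches = 10318, background_size = 1e5)
#> # A tibble: 1 x 11
#>   n_hits observed_rate background_rate  fold   p.value
#> 1     13         0.684           0.103  6.63   1.7e-07
```

The two planted conformational groups separate at ~1.5 Å against ~0.24 Å
within-group spread, so the cut at 1.0 Å recovers them exactly; the
enrichment row reads as "0.684 matches per query protein against 0.103
expected per background sequence, a 6.6-fold enrichment".

A command-line front-end with `rmsd`, `profile`, `irdm`, `cluster`,
`confcorr`, `sasa-interface`, `motif-enrich` and `simulate` subcommands is
installed at `inst/cli/structval`.

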