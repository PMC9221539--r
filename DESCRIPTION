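Package: structval
Title: Validation of Predicted Protein Structures Against Crystal-Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well predicted protein structures (such as
    AlphaFold models) agree with ensembles of crystal structures. Implements a
    superposition-free inter-residue distance-map (IRDM) dissimilarity metric,
    Kabsch least-squares superposition with RMSD at C-alpha, main-chain and
    all-atom levels, hierarchical clustering of structure ensembles with an
    outlier test, confidence-score versus B-factor correlation analysis,
    Shrake-Rupley solvent-accessible surface area and buried interface area,
    PROSITE-style motif scanning with fold-enrichment statistics, and a
    synthetic-structure ensemble generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
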