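Package: DisorderCensus
Title: Proteome-Wide Census of Protein Intrinsic Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteome-scale surveys of intrinsically disordered
    proteins and regions. Provides per-residue disorder scoring from amino
    acid propensity scales, import of externally computed per-residue
    scores, proteome-level disorder content measures (fraction of
    disordered residues, fraction of proteins with long disordered regions,
    fraction of wholly disordered proteins), whole-protein binary
    classification by cumulative-distribution-function (CDF) curves and
    charge-hydropathy (CH) plots with joint CH-CDF quadrant calls, amino
    acid composition profiling with symmetrized Kullback-Leibler
    divergence, habitat-factor correlation analysis, phylogenetic tree
    annotation by disorder content, and a synthetic proteome generator
    with known ground-truth disorder architecture for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
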