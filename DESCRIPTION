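Package: dinoResolve
Title: Ortholog Curation, Multigene-rDNA Congruence and Species Delimitation for Dinoflagellates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether ribosomal DNA phylogenies delimit
    dinoflagellate species as well as multigene phylogenies do. Implements
    reciprocal-best-hit screening of transcriptome contig libraries against
    reference gene panels, paralog pruning and gene quality control
    (mean-distance outlier elimination, paralog-group partitioning and
    selection, tree-diameter and reciprocal-monophyly rejection,
    identity-gap filtering, longest-sequence duplicate resolution), supermatrix
    concatenation, a self-contained GTR(+Gamma) tree engine (distances,
    neighbor joining, Felsenstein pruning likelihood, branch-length
    optimization, nonparametric bootstrap, sequence simulation), a
    parametric-bootstrap congruence test of per-gene signal against a
    concatenated tree, the Y/YP/YA/N/NA species-resolution classifier with its
    three-category survey summary and region-agreement statistic, a
    species-description decision tree, and seeded synthetic-data generators
    (species trees, gene families with paralogs, contig libraries, rDNA allele
    arrays under concerted evolution with pseudogenes, survey tables) with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
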