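Package: taarminer
Title: Mining Trace Amine-Associated Receptor Repertoires from Fragmented Genome Assemblies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering trace amine-associated receptor (TAAR) gene
    repertoires from fragmented genome assemblies: bait-based translated
    homology search over six-frame translations (Smith-Waterman with
    Karlin-Altschul E-values), splice-aware reconstruction of one- and
    two-exon gene models with canonical GT-AG phase-0 introns, classification
    of loci as complete genes, pseudogenes, edge genes or fragments,
    percent-identity family and subfamily clustering, ortholog detection,
    pairwise dN/dS by the Nei-Gojobori method with Zhang's
    transition/transversion weighting, structural annotation (transmembrane
    segments, N-glycosylation sequons, conserved motifs, splice-site logos),
    and a synthetic-genome simulator that plants receptor repertoires with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
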