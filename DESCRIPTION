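Package: hdnaTracts
Title: Strand-Level Simulation and Analysis of Meiotic Heteroduplex DNA Tracts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling and analyzing heteroduplex DNA (hDNA) in
    meiotic recombination products. Provides a strand-level simulator of
    double-strand-break repair under competing mechanistic models
    (synthesis-dependent strand annealing, double Holliday junction
    resolution and dissolution, two-end engagement, and double-strand gap
    repair), overlays of canonical nick-directed long-patch mismatch repair
    and nucleotide-excision-repair-dependent short-patch mismatch repair,
    a purine-selection observation model for rosy-locus recombinants, and
    an analysis layer that reconstructs hDNA and gene-conversion tracts
    from per-strand marker genotypes, classifies crossovers and cis/trans
    tract architecture, computes co-repair statistics for adjacent marker
    pairs, and estimates tract lengths by a truncated-exponential model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
biocViews: Genetics, Recombination, Software, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'segments.R'
    'AllGenerics.R'
    'AllClasses.R'
    'hdnaTracts-package.R'
    'markerMap.R'
    'mmr.R'
    'pipeline.R'
    'recombSim.R'
    'selection.R'
    'statsTests.R'
    'tractAnalysis.R'
    'tractLength.R'
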