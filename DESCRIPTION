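Package: haplorigin
Title: Trio-Free Parental Ancestry Assignment in Phased Hybrid Genome Assemblies
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assigns parental (lineage) origin along the chromosomes of a
    phased interspecific-hybrid genome assembly without parental sequencing
    data (no trio binning). Tandem-repeat annotations are canonicalized into
    rotation- and strand-invariant representative units and clustered into
    satellite families; families with opposite phase specificity seed a rough
    parental partition of the assembly, from which lineage-enriched high-copy
    k-mer marker libraries are selected by frequency and log2-fold-change
    filters. Exact marker matches are binned per chromosome into a log2
    a1/a2 ratio track (with the extended-real special cases and a display
    transform for infinite bins) and segmented into parental-origin blocks at
    tag-filtered zero crossings. Companion tools genotype an introgression in
    a mapping population with region-diagnostic 31-mers and test 1:2:1
    segregation, verify chromosome origin from windowed read-depth contrasts,
    and evaluate inter-phase identity, LTR insertion age and phasing switch
    error with the corresponding closed-form expressions. A deterministic
    synthetic-data generator provides diverged parental genomes with planted
    satellite families, hybrid mosaics with ground truth, and offspring read
    sets for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'haplorigin-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'repeat-catalog.R'
    'repeat-clustering.R'
    'kmer-markers.R'
    'ancestry-painting.R'
    'introgression.R'
    'coverage.R'
    'divergence.R'
    'synthetic-data.R'
    'pipeline.R'
    'cli.R'
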