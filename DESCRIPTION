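Package: OmicsBridge
Title: Integration of Human Transcriptomic, Proteomic and Metabolomic
    Tables via Correlation Networks and Enrichment Analyses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale integration of human multi-omics measurement
    tables (transcript, protein and metabolite abundances across
    experimental conditions or time points). Builds Pearson-correlation
    networks within and across omics layers, bridges a missing third
    layer through curated transcript-protein-metabolite relations,
    ranks network clusters, draws hierarchically clustered coexpression
    heatmaps, performs hypergeometric pathway enrichment over metabolite
    sets, Fisher/EASE Gene Ontology over-representation with
    Benjamini-Hochberg false discovery rates, and OMIM-style phenotype
    mapping. All reference annotation is served from local flat files;
    a seeded fixture generator and a synthetic omics simulator make
    every analysis reproducible offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Network, Pathways, GeneSetEnrichment, GO, Metabolomics,
    Proteomics, Transcriptomics, Visualization
RoxygenNote: 7.3.3
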