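Package: serpentome
Title: Postprandial Expression Trends and Gastric Secretome Analysis for
    Snake Multi-Organ RNA-Seq and Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-organ transcriptome time courses and
    gastric-juice proteomes of infrequently feeding snakes. Implements
    gene-level FPKM quantification under a longest-transcript gene model,
    a seven-class postprandial expression-trend classifier with KEGG-style
    colour export, strict heat-map DEG selection, PCA and Spearman/average
    linkage clustering of expression profiles, Fisher's exact GO
    over-representation with Benjamini-Hochberg FDR and most-specific-term
    reduction, a subtractive secretome workflow (peptide-evidence filter,
    plasma and prey-homolog subtraction, keyword categorisation) with emPAI
    semi-quantitation, read quality trimming, in-silico tryptic digestion,
    and Tajima-Nei nucleotide distances. Seeded generators produce every
    input with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
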