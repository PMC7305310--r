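Package: ProteoCombine
Title: Multi-Engine Proteomics Aggregation with Strict FDR Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Aggregates peptide-spectrum matches from multiple database
    search engines and datasets into strictly FDR-controlled peptide and
    protein identifications, and runs the downstream interpretation steps
    used in deep-coverage prokaryotic proteome surveys: combined posterior
    error probabilities from engine overlap, length-grouped peptide
    q-values, simplistic protein inference, picked protein FDR,
    physicochemical annotation, localization categorization from supplied
    predictions, signal-peptide cleavage-site validation from
    semi-enzymatic peptides, cross-dataset overlap profiles, arCOG class
    enrichment, and sliding-window detection of genomic regions with low
    identification rates on circular replicons. A ground-truthed synthetic
    data generator makes every stage testable without raw mass spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
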