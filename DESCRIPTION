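Package: mitotail
Title: Mapping 3' Transcript Ends in Circular Mitochondrial Genomes from
    Poly(A)-Enriched RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates mature 3' ends of mitochondrial mRNAs from
    poly(A)-enriched RNA-Seq. Reads are aligned to the circular
    mitochondrial genome with a soft-clip-aware local aligner under
    length-fraction and similarity-fraction acceptance thresholds;
    non-template adenine runs at read ends are aggregated into
    strand-aware polyadenylation sites; sites are then turned into
    biological verdicts: stop codons completed post-transcriptionally
    by polyadenylation, 3' untranslated regions, bicistronic
    transcripts with overlapping reading frames, conformance to the
    tRNA punctuation processing model, and stem-loop candidacy of
    intergenic spacers. A seeded synthetic mitochondrial transcriptome
    generator provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
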