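Package: itvus
Title: Information-Theory Based Prioritization of Variants of Uncertain
    Significance in Hereditary Cancer Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified information-theory framework for flagging and
    prioritizing coding and non-coding variants in hereditary breast/ovarian
    cancer gene panels. Builds individual-information weight matrices for
    protein-binding sites (splice sites, splicing regulatory factors,
    transcription factors, RNA-binding proteins), scores variants by their
    change in information content (delta-Ri, in bits), predicts pseudoexon
    activation and splice-isoform shifts via exon-definition analysis, ranks
    UTR variants by predicted mRNA secondary-structure disruption, triages
    protein-truncating variants, and detects candidate hemizygous deletions
    from cohort genotypes. Ships a synthetic-fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
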