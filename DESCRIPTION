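Package: ebwtax
Title: Alignment-Free Metagenomic Read Classification via the Extended
    Burrows-Wheeler Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-free and alignment-free taxonomic classification of
    sequencing reads against a reference genome collection. Builds the
    extended Burrows-Wheeler transform (eBWT), LCP array and document array
    of a read+genome collection, detects alpha-clusters (maximal blocks of
    eBWT symbols whose suffixes share a context of length at least alpha and
    that mix read and genome colors), derives two cluster-based read-genome
    similarity measures (symbol-matching with IUPAC ambiguity-code support,
    and color-count based), and assigns each read or read pair to a taxon by
    a three-phase procedure over the normalized similarity matrices, with
    optional lineage fallback to higher ranks. Includes a paired-end read
    simulator with substitution errors, shuffled negative controls, toy
    taxonomies, evaluation metrics (sensitivity, precision, F1, specificity)
    and classifier concordance statistics, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
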