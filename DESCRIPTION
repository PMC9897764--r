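Package: trnacurate
Title: Curation of Predicted Prokaryotic tRNA Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes predicted prokaryotic tRNA gene sets (tRNAscan-SE
    tabular output or GtRNAdb-style listings) to distinguish canonical tRNA
    genes from tRNA gene fragments left behind by mobile genetic element
    integration (attR remnants) or CRISPR-Cas spacer acquisition, to rescue
    isotype misassignments caused by ambiguous (N) bases in the input genome,
    and to report deviations from a standard archaeal tRNA gene set. Includes
    a rule-based cloverleaf structure annotator, genomic-context screens
    (direct-repeat attR pairs, CRISPR repeat-spacer arrays, N-ambiguity,
    tmRNA tracks), isotype-score triage bands, gene-set comparison matrices,
    and a seeded synthetic-genome fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
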