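Package: seednet
Title: Comparative Seed-Network Extraction and Candidate Gene Discovery
    from Developmental Expression Time Courses
Version: 0.1.0
Authors@R:
    person("seednet", "maintainers", email = "maintainers@seednet.dev",
           role = c("aut", "cre"))
Description: Projects a literature-curated Drosophila retinal-determination
    seed network onto mouse homologs, extracts a correlation-supported seed
    network from multiple expression time-course datasets using tie-aware
    Spearman rank correlation with an absolute threshold, queries the
    datasets for genes correlated with three or more seed genes
    (guilt-by-association candidate prioritization), and tests candidate
    lists for annotation over-representation with an exact hypergeometric
    upper-tail test. Includes a synthetic time-course study generator with
    planted signed co-expression structure and a ground-truth manifest so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
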