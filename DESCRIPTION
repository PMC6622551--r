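Package: equinet
Title: Longitudinal Horse Movement Contact Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn monthly horse-movement questionnaire diaries into
    directed monthly contact networks between locations, and to characterise
    those networks for infectious-disease epidemiology. Implements ingestion
    and inclusion filtering of movement records, table-driven location
    standardisation with gazetteer lookup, great-circle distance and
    within/between-region flow summaries, monthly network construction,
    static network measures (size, reciprocity, degree and nominal
    assortativity, giant strong component, degree summaries), temporal
    stability statistics (node loyalty and top-node similarity via the
    Jaccard index), questionnaire data-completeness sensitivity scenarios,
    and a synthetic movement-diary generator so the whole pipeline can be
    exercised and validated without access to confidential study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
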