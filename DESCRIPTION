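Package: litmapr
Title: Assisted Topic-Based Exploration of Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assisted analysis of biomedical literature: boolean
    alias-group search construction for PubMed, parsing of Entrez efetch XML
    into publication records with MeSH, chemical and keyword metadata,
    cluster-based topic modelling (embed, reduce, density-cluster) with
    centroid cosine ranking and topic-word extraction, per-topic
    meta-information profiles, label-driven semantic relation graphs, and
    evaluation statistics including user-agreed relevance, reference-rank
    analysis and C_v topic coherence. A synthetic PubMed-like corpus
    generator with planted topic structure makes the whole pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
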