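# Hand-written efetch-dialect fixture: one full article, one article
# without keyword list, built in code so tests stay text-only.
fixture_article_xml <- function() {
  paste0(
    '<?xml version="1.0" ?>\n<PubmedArticleSet>\n',
    "<PubmedArticle><MedlineCitation><PMID>123456</PMID>",
    "<Article><Journal><JournalIssue><PubDate><Year>2020</Year>",
    "</PubDate></JournalIssue></Journal>",
    "<ArticleTitle>Analgesic outcomes after surgery</ArticleTitle>",
    "<Abstract><AbstractText>Background text.</AbstractText>",
    "<AbstractText>Conclusion text.</AbstractText></Abstract></Article>",
    "<MeshHeadingList>",
    "<MeshHeading><DescriptorName>Pain</DescriptorName></MeshHeading>",
    "<MeshHeading><DescriptorName>Analgesics</DescriptorName></MeshHeading>",
    "</MeshHeadingList>",
    "<ChemicalList><Chemical><NameOfSubstance>Propofol</NameOfSubstance>",
    "</Chemical></ChemicalList>",
    "<KeywordList><Keyword>postoperative</Keyword></KeywordList>",
    "</MedlineCitation></PubmedArticle>\n",
    "<PubmedArticle><MedlineCitation><PMID>123457</PMID>",
    "<Article><Journal><JournalIssue><PubDate>",
    "<MedlineDate>1998 Nov-Dec</MedlineDate>",
    "</PubDate></JournalIssue></Journal>",
    "<ArticleTitle>Second article</ArticleTitle>",
    "<Abstract><AbstractText>Only abstract.</AbstractText></Abstract>",
    "</Article></MedlineCitation></PubmedArticle>\n",
    "</PubmedArticleSet>\n")
}

toy_records <- function(n = 4) {
  publication_records(
    pub_id = paste0("p", seq_len(n)),
    title = paste("title", seq_len(n)),
    body_text = paste("body text", seq_len(n)),
    year = rep(c(2019L, NA_integer_), length.out = n),
    mesh_terms = rep(list(c("Pain")), n),
    chemicals = rep(list(character(0)), n),
    keywords = rep(list(c("kw1", "kw2")), n))
}

# small planted corpus used by several modules
planted_corpus <- function(seed = 7, overlap = 0.1) {
  generate_corpus(corpus_spec(n_topics = 2, docs_per_topic = 30,
                              topic_vocab_overlap = overlap, seed = seed))
}

fit_planted <- function(gen, embed_seed = 3, min_cluster = 10) {
  dv <- embed_corpus(parse_pubmed_xml(gen$xml),
                     hash_embedder(dim = 256, seed = embed_seed))
  list(doc_vectors = dv,
       model = fit_topic_model(
         dv, clusterer = density_clusterer(min_cluster_size = min_cluster),
         seed = 1))
}

# brute-force cosine for oracle checks
cos_loop <- function(u, v) {
  s <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    s <- s + u[i] * v[i]; nu <- nu + u[i]^2; nv <- nv + v[i]^2
  }
  s / sqrt(nu * nv)
}
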