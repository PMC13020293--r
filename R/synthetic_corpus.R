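#' Specification of a synthetic PubMed-like corpus
#'
#' Defines a corpus with planted topic structure: each topic owns an
#' exclusive slice of the vocabulary, a fraction of the vocabulary is
#' shared between all topics, and every document samples its tokens from
#' its topic's Zipf-shaped unigram distribution. Per-topic pools of MeSH
#' descriptors, chemical names and author keywords emulate PubMed
#' metadata. A fixed seed reproduces the corpus byte-for-byte.
#'
#' @param n_topics number of planted topics.
#' @param docs_per_topic documents generated per topic.
#' @param vocab_size total content vocabulary size.
#' @param topic_vocab_overlap fraction of the vocabulary shared across all
#'   topics, in \[0, 1).
#' @param mesh_pool_size,chemical_pool_size,keyword_pool_size per-topic
#'   metadata pool sizes.
#' @param year_range integer vector `c(first, last)` publication years.
#' @param zipf_exponent within-topic Zipf exponent (default 1.1).
#' @param doc_length_range token count range per abstract (default 80-200).
#' @param seed RNG seed.
#' @return a `corpus_spec` list.
#' @export
corpus_spec <- function(n_topics = 2L, docs_per_topic = 30L,
                        vocab_size = 400L, topic_vocab_overlap = 0.1,
                        mesh_pool_size = 5L, chemical_pool_size = 4L,
                        keyword_pool_size = 5L,
                        year_range = c(2005L, 2024L),
                        zipf_exponent = 1.1,
                        doc_length_range = c(80L, 200L),
                        seed = 1L) {
  stopifnot(n_topics >= 1, docs_per_topic >= 1, vocab_size >= 1,
            topic_vocab_overlap >= 0, topic_vocab_overlap < 1,
            length(year_range) == 2, year_range[1] <= year_range[2])
  n_shared <- round(topic_vocab_overlap * vocab_size)
  n_excl <- floor((vocab_size - n_shared) / n_topics)
  if (n_excl < 10) {
    stop("vocab_size too small for the requested overlap: each topic ",
         "needs at least 10 exclusive terms, got ", n_excl, call. = FALSE)
  }
  structure(list(n_topics = as.integer(n_topics),
                 docs_per_topic = as.integer(docs_per_topic),
                 vocab_size = as.integer(vocab_size),
                 topic_vocab_overlap = topic_vocab_overlap,
                 n_shared = as.integer(n_shared),
                 n_exclusive = as.integer(n_excl),
                 mesh_pool_size = as.integer(mesh_pool_size),
                 chemical_pool_size = as.integer(chemical_pool_size),
                 keyword_pool_size = as.integer(keyword_pool_size),
                 year_range = as.integer(year_range),
                 zipf_exponent = zipf_exponent,
                 doc_length_range = as.integer(doc_length_range),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

#' Generate a synthetic PubMed-like corpus with planted topics
#'
#' Produces an efetch-dialect XML article set plus a ground-truth manifest
#' recording, for every generated publication, its planted topic and all
#' planted metadata. Titles and abstracts are sampled from the topic's
#' Zipf-shaped unigram distribution; MeSH descriptors, chemicals, keywords
#' and the publication year are drawn from per-topic pools. The XML parses
#' through [parse_pubmed_xml()] with zero loss, field-for-field equal to
#' the manifest.
#'
#' @param spec a [corpus_spec()].
#' @return list with `xml` (a single XML string) and `manifest` (a
#'   `publication_records` data frame with an extra `topic` column, plus
#'   the spec as attribute `spec`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_rng(spec$seed, {
    shared <- if (spec$n_shared > 0) {
      sprintf("shared%04d", seq_len(spec$n_shared))
    } else character(0)
    topics <- lapply(seq_len(spec$n_topics), function(t) {
      excl <- sprintf("topic%02dterm%04d", t, seq_len(spec$n_exclusive))
      vocab <- c(excl, shared)
      # Zipf weights over a topic-specific random ordering of its vocabulary
      ranks <- sample(seq_along(vocab))
      probs <- (1 / ranks^spec$zipf_exponent)
      list(vocab = vocab, probs = probs / sum(probs),
           mesh = sprintf("Descriptor T%02d-%02d", t,
                          seq_len(spec$mesh_pool_size)),
           chem = sprintf("Compound T%02d-%02d", t,
                          seq_len(spec$chemical_pool_size)),
           kw = sprintf("keyword-t%02d-%02d", t,
                        seq_len(spec$keyword_pool_size)))
    })
    n_docs <- spec$n_topics * spec$docs_per_topic
    pub_id <- sprintf("%07d", 1000000L + seq_len(n_docs))
    topic_of <- rep(seq_len(spec$n_topics), each = spec$docs_per_topic)
    title <- character(n_docs)
    abstract <- character(n_docs)
    year <- integer(n_docs)
    mesh <- vector("list", n_docs)
    chem <- vector("list", n_docs)
    kw <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      tp <- topics[[topic_of[i]]]
      len <- sample(spec$doc_length_range[1]:spec$doc_length_range[2], 1)
      tokens <- sample(tp$vocab, len, replace = TRUE, prob = tp$probs)
      n_title <- sample(6:12, 1)
      title[i] <- paste(tokens[seq_len(n_title)], collapse = " ")
      abstract[i] <- paste(tokens[-seq_len(n_title)], collapse = " ")
      year[i] <- sample(spec$year_range[1]:spec$year_range[2], 1)
      mesh[[i]] <- sort(sample(tp$mesh, sample(1:3, 1)))
      chem[[i]] <- sort(sample(tp$chem, sample(1:2, 1)))
      kw[[i]] <- sort(sample(tp$kw, sample(1:3, 1)))
    }
    manifest <- publication_records(pub_id, title, abstract, year,
                                    mesh_terms = mesh, chemicals = chem,
                                    keywords = kw)
    manifest$topic <- topic_of
    attr(manifest, "spec") <- spec
    article <- vapply(seq_len(n_docs), function(i) {
      mesh_xml <- paste(sprintf(
        "<MeshHeading><DescriptorName MajorTopicYN=\"N\">%s</DescriptorName></MeshHeading>",
        xml_escape(mesh[[i]])), collapse = "")
      chem_xml <- paste(sprintf(
        "<Chemical><NameOfSubstance>%s</NameOfSubstance></Chemical>",
        xml_escape(chem[[i]])), collapse = "")
      kw_xml <- paste(sprintf("<Keyword>%s</Keyword>",
                              xml_escape(kw[[i]])), collapse = "")
      paste0(
        "<PubmedArticle><MedlineCitation><PMID>", pub_id[i], "</PMID>",
        "<Article><Journal><JournalIssue><PubDate><Year>", year[i],
        "</Year></PubDate></JournalIssue></Journal>",
        "<ArticleTitle>", xml_escape(title[i]), "</ArticleTitle>",
        "<Abstract><AbstractText>", xml_escape(abstract[i]),
        "</AbstractText></Abstract></Article>",
        "<MeshHeadingList>", mesh_xml, "</MeshHeadingList>",
        "<ChemicalList>", chem_xml, "</ChemicalList>",
        "<KeywordList>", kw_xml, "</KeywordList>",
        "</MedlineCitation></PubmedArticle>")
    }, character(1))
    xml <- paste0("<?xml version=\"1.0\" ?>\n<PubmedArticleSet>\n",
                  paste(article, collapse = "\n"),
                  "\n</PubmedArticleSet>\n")
    list(xml = xml, manifest = manifest)
  })
}

#' Generate a synthetic reference ranking
#'
#' Builds an ordered publication-id list emulating a recorded best-match
#' result ranking with a known answer: the documents of `relevant_topic`
#' occupy a contiguous block of ranks ending at `round(depth * N)` (so
#' `depth = 1` forces them all into the tail), every other document fills
#' the remaining ranks in seeded random order, and with probability `noise`
#' each relevant document is instead relocated to a uniformly random rank.
#' With `noise = 0` the mean rank of the relevant documents is exactly
#' `round(depth * N) - (R - 1) / 2` for `R` relevant documents, which is
#' the closed-form oracle for [reference_rank_stats()].
#'
#' @param manifest manifest from [generate_corpus()].
#' @param relevant_topic planted topic id whose documents are "relevant".
#' @param noise relocation probability in \[0, 1\].
#' @param depth tail position of the relevant block, in (0, 1\].
#' @param seed RNG seed.
#' @return character vector of publication ids, best rank first.
#' @export
generate_reference_ranking <- function(manifest, relevant_topic,
                                       noise = 0, depth = 1, seed = 1L) {
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    stop("noise must lie in [0, 1]", call. = FALSE)
  }
  if (!relevant_topic %in% manifest$topic) {
    stop("relevant_topic ", relevant_topic, " not present in manifest",
         call. = FALSE)
  }
  n <- nrow(manifest)
  rel <- manifest$pub_id[manifest$topic == relevant_topic]
  oth <- manifest$pub_id[manifest$topic != relevant_topic]
  d0 <- round(depth * n)
  if (d0 < length(rel) || d0 > n) {
    stop("depth places the relevant block outside the ranking", call. = FALSE)
  }
  with_rng(seed, {
    ranking <- character(n)
    block <- (d0 - length(rel) + 1L):d0
    ranking[block] <- rel
    ranking[-block] <- sample(oth)
    if (noise > 0 && length(rel) > 0) {
      move <- stats::runif(length(rel)) < noise
      for (id in rel[move]) {
        from <- which(ranking == id)
        to <- sample.int(n, 1)
        tmp <- ranking[to]
        ranking[to] <- id
        ranking[from] <- tmp
      }
    }
    ranking
  })
}
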