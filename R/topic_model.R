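#' Topic id used for noise documents
#' @export
NOISE_TOPIC <- 0L

#' PCA reducer factory
#'
#' Deterministic linear dimensionality reduction used before clustering.
#' Nonlinear manifold reducers (UMAP semantics) can be injected through the
#' same `function(doc_vectors, seed) -> reduced matrix` contract; the PCA
#' default keeps the whole pipeline bit-reproducible.
#'
#' @param n_components output dimensionality (default 5, the conventional
#'   pre-clustering target).
#' @return a reducer function.
#' @export
pca_reducer <- function(n_components = 5L) {
  n_components <- as.integer(n_components)
  function(doc_vectors, seed = 1L) {
    k <- min(n_components, ncol(doc_vectors), nrow(doc_vectors))
    p <- stats::prcomp(doc_vectors, center = TRUE, scale. = FALSE)
    red <- p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
    rownames(red) <- rownames(doc_vectors)
    red
  }
}

#' Fit a cluster-based topic model
#'
#' Consolidates a corpus into topics: document vectors are reduced to a
#' low-dimensional space, clustered by hierarchical density clustering
#' (which discovers the number of topics from the data — the caller never
#' supplies it), and each topic's centroid is the arithmetic mean of its
#' member document vectors in the ORIGINAL embedding space. The reduced
#' space is used only for clustering. Documents in low-density regions are
#' labelled noise ([NOISE_TOPIC]); if everything is noise the model reports
#' "no topics found" rather than raising an error.
#'
#' @param doc_vectors numeric matrix of document embeddings, rownames =
#'   publication ids (e.g. from [embed_corpus()]).
#' @param reducer `function(doc_vectors, seed)` -> reduced matrix; default
#'   [pca_reducer()].
#' @param clusterer `function(reduced)` -> integer labels, 0 = noise;
#'   default [density_clusterer()].
#' @param seed integer seed forwarded to the reducer.
#' @return an object of class `topic_model` with elements `assignments`
#'   (named integer vector, 0 = noise), `centroids` (topics x d matrix),
#'   `topic_sizes`, `reduced`, `n_topics`.
#' @export
fit_topic_model <- function(doc_vectors,
                            reducer = pca_reducer(),
                            clusterer = density_clusterer(),
                            seed = 1L) {
  doc_vectors <- as.matrix(doc_vectors)
  if (nrow(doc_vectors) < 1) stop("empty corpus", call. = FALSE)
  if (is.null(rownames(doc_vectors))) {
    rownames(doc_vectors) <- as.character(seq_len(nrow(doc_vectors)))
  }
  reduced <- with_rng(seed, reducer(doc_vectors, seed))
  labels <- clusterer(reduced)
  stopifnot(length(labels) == nrow(doc_vectors))
  ids <- sort(setdiff(unique(labels), 0L))
  # renumber topics by decreasing size, ties by first member index
  if (length(ids) > 0) {
    size <- vapply(ids, function(t) sum(labels == t), integer(1))
    first <- vapply(ids, function(t) which(labels == t)[1], integer(1))
    ord <- ids[order(-size, first)]
    relab <- integer(max(ord))
    relab[ord] <- seq_along(ord)
    labels <- ifelse(labels == 0L, 0L, relab[labels])
  }
  assignments <- stats::setNames(as.integer(labels), rownames(doc_vectors))
  n_topics <- length(ids)
  centroids <- NULL
  topic_sizes <- integer(0)
  if (n_topics > 0) {
    centroids <- t(vapply(seq_len(n_topics), function(t) {
      colMeans(doc_vectors[assignments == t, , drop = FALSE])
    }, numeric(ncol(doc_vectors))))
    rownames(centroids) <- as.character(seq_len(n_topics))
    topic_sizes <- stats::setNames(
      vapply(seq_len(n_topics), function(t) sum(assignments == t),
             integer(1)),
      as.character(seq_len(n_topics)))
  }
  structure(list(assignments = assignments, centroids = centroids,
                 topic_sizes = topic_sizes, reduced = reduced,
                 n_topics = n_topics),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  if (x$n_topics == 0) {
    cat("Topic model: no topics found (all", length(x$assignments),
        "documents classed as noise)\n")
  } else {
    cat("Topic model:", x$n_topics, "topic(s) over",
        length(x$assignments), "documents;",
        sum(x$assignments == NOISE_TOPIC), "noise\n")
    print(x$topic_sizes)
  }
  invisible(x)
}

#' Rank a topic's publications by closeness to the topic centroid
#'
#' Relevance of a publication within its topic is the cosine similarity of
#' its document vector to the topic centroid; by default the ten most
#' relevant publications are returned. Ties are broken by publication id
#' ascending.
#'
#' @param model a `topic_model`.
#' @param doc_vectors the document-vector matrix the model was fitted on.
#' @param topic_id existing topic id.
#' @param n number of publications to return (default 10); a smaller topic
#'   returns all its members.
#' @return data frame with columns `pub_id`, `similarity`, descending.
#' @export
rank_topic_documents <- function(model, doc_vectors, topic_id, n = 10L) {
  stopifnot(inherits(model, "topic_model"))
  topic_id <- as.integer(topic_id)
  if (model$n_topics == 0 || !topic_id %in% seq_len(model$n_topics)) {
    stop("unknown topic id: ", topic_id, call. = FALSE)
  }
  member_ids <- names(model$assignments)[model$assignments == topic_id]
  centroid <- model$centroids[as.character(topic_id), ]
  sims <- vapply(member_ids, function(id) {
    cosine_similarity(doc_vectors[id, ], centroid)
  }, numeric(1))
  ord <- order(-sims, member_ids)
  take <- seq_len(min(as.integer(n), length(member_ids)))
  data.frame(pub_id = member_ids[ord][take],
             similarity = unname(sims[ord][take]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Topic words by nearest word vectors
#'
#' In a joint document-word embedding space, the words nearest a topic's
#' centroid describe the topic. Returns the `k` vocabulary terms with the
#' highest cosine similarity to the centroid, ties broken lexicographically.
#'
#' @param centroid topic centroid vector (original embedding space).
#' @param word_vectors matrix of word vectors, one row per vocabulary term.
#' @param vocabulary character vector aligned with `word_vectors` rows;
#'   defaults to its rownames.
#' @param k number of terms; if the vocabulary is smaller, all terms are
#'   returned with a message.
#' @return data frame with columns `term`, `similarity`, descending.
#' @export
topic_words_nearest <- function(centroid, word_vectors,
                                vocabulary = rownames(word_vectors),
                                k = 10L) {
  k <- as.integer(k)
  if (k <= 0L) {
    return(data.frame(term = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(nrow(word_vectors) == length(vocabulary))
  if (length(vocabulary) < k) {
    message("vocabulary has only ", length(vocabulary),
            " terms; returning all")
    k <- length(vocabulary)
  }
  sims <- vapply(seq_len(nrow(word_vectors)), function(i) {
    cosine_similarity(word_vectors[i, ], centroid)
  }, numeric(1))
  ord <- order(-sims, vocabulary)
  data.frame(term = vocabulary[ord][seq_len(k)],
             similarity = sims[ord][seq_len(k)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Topic words by class-based term weighting
#'
#' Aggregates each topic's documents into a single pseudo-document and
#' scores each term `t` in topic `c` as
#' `tf(t, c) * log(1 + A / f(t))`, where `tf` is the term's frequency in the
#' pseudo-document, `A` is the mean pseudo-document token count and `f(t)`
#' the term's total corpus frequency. The inverse class weighting demotes
#' terms common to all topics, so no stopword filtering is needed.
#'
#' @param texts_by_topic named list: topic id -> character vector of the
#'   topic's document texts.
#' @param k terms to keep per topic.
#' @param tokenizer tokenising function; default [tokenize_text()].
#' @return named list of data frames (`term`, `score`), score descending,
#'   ties lexicographic. A topic whose pseudo-document tokenises to nothing
#'   yields an empty data frame.
#' @export
topic_words_ctfidf <- function(texts_by_topic, k = 10L,
                               tokenizer = tokenize_text) {
  stopifnot(is.list(texts_by_topic), length(texts_by_topic) >= 1)
  k <- as.integer(k)
  pseudo <- lapply(texts_by_topic, function(texts) {
    unlist(tokenizer(paste(texts, collapse = " ")))
  })
  a_mean <- mean(lengths(pseudo))
  corpus_freq <- table(unlist(pseudo))
  lapply(pseudo, function(tokens) {
    if (length(tokens) == 0) {
      return(data.frame(term = character(0), score = numeric(0),
                        stringsAsFactors = FALSE))
    }
    tf <- table(tokens)
    terms <- names(tf)
    score <- as.numeric(tf) *
      log(1 + a_mean / as.numeric(corpus_freq[terms]))
    ord <- order(-score, terms)
    take <- seq_len(min(k, length(terms)))
    data.frame(term = terms[ord][take], score = score[ord][take],
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Persist a fitted topic model as plain-text tables
#'
#' Writes `assignments.tsv` (pub_id, topic_id), `centroids.tsv` (one row per
#' topic) and, when supplied, per-topic word tables, into a directory.
#'
#' @param model a `topic_model`.
#' @param dir output directory (created if needed).
#' @param topic_words optional list from [topic_words_ctfidf()] or built
#'   from [topic_words_nearest()].
#' @return `dir`, invisibly.
#' @export
write_topic_model <- function(model, dir, topic_words = NULL) {
  stopifnot(inherits(model, "topic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(pub_id = names(model$assignments),
               topic_id = unname(model$assignments)),
    file.path(dir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(model$centroids)) {
    utils::write.table(model$centroids, file.path(dir, "centroids.tsv"),
                       sep = "\t", quote = FALSE, col.names = FALSE)
  }
  if (!is.null(topic_words)) {
    for (t in names(topic_words)) {
      utils::write.table(topic_words[[t]],
                         file.path(dir, paste0("topic_words_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
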