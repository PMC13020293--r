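#' Create validated relevance-label assignments
#'
#' One row per labelled publication: the binary relevance judgement and,
#' for relevant publications, the free-text topic name the user assigned.
#'
#' @param pub_id character publication ids, unique.
#' @param relevant logical relevance judgements.
#' @param user_label character topic names; must be non-empty wherever
#'   `relevant` is `TRUE` (may be `NA` otherwise).
#' @return a `label_assignments` data frame.
#' @export
label_assignments <- function(pub_id, relevant, user_label = NA_character_) {
  pub_id <- as.character(pub_id)
  if (anyDuplicated(pub_id)) {
    stop("at most one assignment per publication", call. = FALSE)
  }
  relevant <- as.logical(relevant)
  user_label <- rep_len(as.character(user_label), length(pub_id))
  bad <- relevant & (is.na(user_label) | !nzchar(trimws(user_label)))
  if (any(bad)) {
    stop("relevant publications need a non-empty user label: ",
         paste(pub_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(pub_id = pub_id, relevant = relevant,
                    user_label = user_label, stringsAsFactors = FALSE)
  class(out) <- c("label_assignments", "data.frame")
  out
}

#' Read label assignments from TSV
#'
#' Expects columns `pub_id`, `relevant` (TRUE/FALSE or 1/0), `user_label`.
#'
#' @param path TSV file path.
#' @return a `label_assignments` data frame.
#' @export
read_label_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  label_assignments(df$pub_id,
                    df$relevant %in% c("TRUE", "true", "1"),
                    df$user_label)
}

#' Aggregate labelled publications into user-topic vectors
#'
#' For each user-assigned topic label, the topic vector is the arithmetic
#' mean of the member publications' document vectors, L2-normalised
#' (mean-then-normalise, keeping cosine comparisons consistent).
#' Non-relevant assignments are ignored.
#'
#' @param assignments a `label_assignments` data frame with at least one
#'   relevant row.
#' @param doc_vectors document-vector matrix with `pub_id` rownames; every
#'   relevant publication must have a row.
#' @return matrix of topic vectors, one row per user label.
#' @export
aggregate_label_topics <- function(assignments, doc_vectors) {
  rel <- assignments[assignments$relevant, , drop = FALSE]
  if (nrow(rel) == 0) {
    stop("no relevant assignments to aggregate", call. = FALSE)
  }
  missing <- setdiff(rel$pub_id, rownames(doc_vectors))
  if (length(missing) > 0) {
    stop("no document vector for relevant publication(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- sort(unique(rel$user_label))
  out <- t(vapply(labels, function(lab) {
    ids <- rel$pub_id[rel$user_label == lab]
    v <- colMeans(doc_vectors[ids, , drop = FALSE])
    n <- sqrt(sum(v * v))
    if (n == 0) stop("zero aggregate vector for label ", lab, call. = FALSE)
    v / n
  }, numeric(ncol(doc_vectors))))
  rownames(out) <- labels
  out
}

#' Build the semantic relation graph of user topics and search terms
#'
#' Nodes are the user-labelled topics (role `user_topic`, drawn red) plus
#' every search phrase from the first alias group (`group1_term`, green) and
#' second alias group (`group2_term`, blue), each embedded with the same
#' embedder as the publications. Cosine similarity is computed between all
#' node pairs; each topic node contributes undirected edges to its `k` most
#' similar other nodes (default 3). Term nodes receive edges but do not
#' initiate them unless `terms_initiate = TRUE`. Duplicate edges are merged;
#' an edge's weight is the pairwise cosine similarity.
#'
#' @param topic_vectors matrix from [aggregate_label_topics()] (may have
#'   zero rows if only terms are compared, but at least two nodes must
#'   exist in total).
#' @param search_spec a [search_spec()] supplying the term nodes, or `NULL`
#'   for a topics-only graph.
#' @param embedder embedder used for the publications.
#' @param k connections per initiating node (>= 1); ties at the k-th
#'   similarity broken by node id ascending.
#' @param terms_initiate if `TRUE`, term nodes also initiate their top-k
#'   edges.
#' @return an object of class `relation_graph` with `nodes` (id, role,
#'   colour), `edges` (from, to, weight) and the node vector matrix.
#' @export
build_relation_graph <- function(topic_vectors, search_spec = NULL,
                                 embedder = NULL, k = 3L,
                                 terms_initiate = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  roles <- rep("user_topic", nrow(topic_vectors))
  ids <- rownames(topic_vectors)
  vecs <- topic_vectors
  if (!is.null(search_spec)) {
    stopifnot(inherits(search_spec, "search_spec"), !is.null(embedder))
    add_terms <- function(phrases, role) {
      for (ph in phrases) {
        vecs <<- rbind(vecs, embed_phrase(embedder, ph))
        ids <<- c(ids, ph)
        roles <<- c(roles, role)
      }
    }
    add_terms(search_spec$group1$phrases, "group1_term")
    if (!is.null(search_spec$group2)) {
      add_terms(search_spec$group2$phrases, "group2_term")
    }
  }
  n <- length(ids)
  if (n < 2) stop("a relation graph needs at least two nodes", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  rownames(vecs) <- ids
  sim <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) sim[i, j] <- cosine_similarity(vecs[i, ], vecs[j, ])
    }
  }
  initiators <- which(roles == "user_topic" | terms_initiate)
  edges <- list()
  for (i in initiators) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-sim[i, others], ids[others])]
    for (j in utils::head(ord, k)) {
      key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
      if (is.null(edges[[key]])) {
        a <- sort(c(ids[i], ids[j]))
        edges[[key]] <- data.frame(from = a[1], to = a[2],
                                   weight = sim[i, j],
                                   stringsAsFactors = FALSE)
      }
    }
  }
  edge_df <- if (length(edges) == 0) {
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, edges)
    rownames(df) <- NULL
    df[order(df$from, df$to), , drop = FALSE]
  }
  colour_map <- c(user_topic = "red", group1_term = "green",
                  group2_term = "blue")
  nodes <- data.frame(id = ids, role = roles,
                      colour = unname(colour_map[roles]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edge_df, vectors = vecs, k = k),
            class = "relation_graph")
}

#' @export
print.relation_graph <- function(x, ...) {
  cat("Relation graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "user_topic"), "user topics ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a relation graph to igraph
#'
#' Node attributes `role` and `colour` and edge attribute `weight` are
#' carried over, ready for GraphML export.
#'
#' @param graph a `relation_graph`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "relation_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

#' Export a relation graph
#'
#' @param graph a `relation_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, links = graph$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
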