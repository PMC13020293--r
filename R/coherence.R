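#' Coherence configuration
#'
#' Parameters of the C_v topic-coherence measure: the number of top words
#' scored per topic, the boolean sliding-window size in tokens, and the
#' smoothing epsilon used inside the NPMI terms. Defaults are the canonical
#' values of the measure (top 10 words, window 110, epsilon 1e-12).
#'
#' @param top_n_words words scored per topic (>= 2).
#' @param window_size sliding-window length in tokens (>= 2).
#' @param epsilon smoothing constant (> 0).
#' @return a `coherence_config` list.
#' @export
coherence_config <- function(top_n_words = 10L, window_size = 110L,
                             epsilon = 1e-12) {
  top_n_words <- as.integer(top_n_words)
  window_size <- as.integer(window_size)
  if (is.na(top_n_words) || top_n_words < 2L) {
    stop("top_n_words must be >= 2", call. = FALSE)
  }
  if (is.na(window_size) || window_size < 2L) {
    stop("window_size must be >= 2", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be > 0", call. = FALSE)
  }
  structure(list(top_n_words = top_n_words, window_size = window_size,
                 epsilon = epsilon), class = "coherence_config")
}

#' C_v topic coherence
#'
#' Scores each topic's word set against the corpus using the C_v measure:
#' a boolean sliding window of `window_size` tokens over every document
#' yields virtual documents (a document shorter than the window contributes
#' one window); word and word-pair occurrence probabilities over these
#' windows feed epsilon-smoothed NPMI context vectors; each word's score is
#' the cosine of its NPMI vector (against all N topic words) with the
#' vector summed over all N words; a topic's score is the mean over its
#' words, and the corpus score the mean over topics.
#'
#' A word absent from the corpus has its probabilities replaced by epsilon;
#' a topic none of whose words occur is reported as `NaN`.
#'
#' @param topic_word_sets list of character vectors, each with >= 2 words
#'   (only the first `top_n_words` of each set are scored).
#' @param tokenised_corpus list of token vectors, one per document (e.g.
#'   from [tokenize_text()]).
#' @param config a [coherence_config()].
#' @return list with `per_topic` numeric scores and their `mean`
#'   (over defined topic scores).
#' @export
cv_coherence <- function(topic_word_sets, tokenised_corpus,
                         config = coherence_config()) {
  stopifnot(inherits(config, "coherence_config"))
  if (length(tokenised_corpus) == 0) {
    stop("corpus must be non-empty", call. = FALSE)
  }
  if (any(lengths(topic_word_sets) < 2)) {
    stop("every topic word set needs at least 2 words", call. = FALSE)
  }
  topic_word_sets <- lapply(topic_word_sets, function(w) {
    utils::head(w, config$top_n_words)
  })
  vocab <- unique(unlist(topic_word_sets))
  counts <- count_window_occurrences(tokenised_corpus, vocab,
                                     config$window_size)
  b_windows <- counts$n_windows
  eps <- config$epsilon
  p_single <- counts$single / b_windows
  p_pair <- counts$pair / b_windows

  npmi <- function(wi, wj) {
    pi <- p_single[[wi]]
    pj <- p_single[[wj]]
    if (pi == 0) pi <- eps
    if (pj == 0) pj <- eps
    pij <- p_pair[wi, wj]
    log((pij + eps) / (pi * pj)) / (-log(pij + eps))
  }
  per_topic <- vapply(topic_word_sets, function(words) {
    if (all(p_single[words] == 0)) return(NaN)
    ctx <- t(vapply(words, function(wi) {
      vapply(words, function(wj) npmi(wi, wj), numeric(1))
    }, numeric(length(words))))
    total <- colSums(ctx)
    mean(vapply(seq_along(words), function(i) {
      cosine_similarity(ctx[i, ], total)
    }, numeric(1)))
  }, numeric(1))
  defined <- per_topic[!is.nan(per_topic)]
  list(per_topic = per_topic,
       mean = if (length(defined)) mean(defined) else NaN)
}

# Boolean sliding-window occurrence counts for `vocab` over the corpus.
# Returns the number of windows, per-word window counts, and the pairwise
# co-occurrence count matrix.
count_window_occurrences <- function(tokenised_corpus, vocab, window_size) {
  nv <- length(vocab)
  single <- stats::setNames(numeric(nv), vocab)
  pair <- matrix(0, nv, nv, dimnames = list(vocab, vocab))
  n_windows <- 0L
  for (tokens in tokenised_corpus) {
    len <- length(tokens)
    if (len == 0) next
    starts <- if (len <= window_size) 1L else seq_len(len - window_size + 1L)
    for (s in starts) {
      win <- tokens[s:min(s + window_size - 1L, len)]
      present <- vocab[vocab %in% win]
      n_windows <- n_windows + 1L
      if (length(present) > 0) {
        single[present] <- single[present] + 1
        pair[present, present] <- pair[present, present] + 1
      }
    }
  }
  diag(pair) <- single
  list(n_windows = n_windows, single = single, pair = pair)
}
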