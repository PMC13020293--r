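#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return similarity in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must share a dimension", call. = FALSE)
  }
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

# Deterministic string hash: polynomial rolling hash over Unicode code
# points, modulo a prime < 2^26 so all intermediates stay exact in doubles.
# `salt` decouples the bucket hash from the sign hash.
.hash_string <- function(s, seed, salt) {
  p <- 67108859 # prime < 2^26
  h <- (seed * 2654435 + salt * 97) %% p
  for (cp in utf8ToInt(s)) {
    h <- (h * 31 + cp) %% p
  }
  h
}

#' Deterministic feature-hashing embedder
#'
#' A seeded bag-of-tokens embedder providing a genuine joint document-word
#' space for offline testing: each token hashes to one of `dim` signed
#' buckets; a document's vector is the L2-normalised signed term-frequency
#' vector, and a word's vector is its signed one-hot bucket vector. Tokens
#' shared between texts therefore raise their cosine similarity by
#' construction, and a topic word scores highly against documents that use
#' it. Fixed `seed` + fixed text gives a bit-identical vector.
#'
#' Production deployments would plug in a pretrained sentence encoder behind
#' the same three-function contract (`embed_documents`, `embed_terms`,
#' `embed_phrase`); no particular model is assumed here.
#'
#' @param dim embedding dimension (>= 2).
#' @param seed integer hashing seed.
#' @return an object of class `hash_embedder`.
#' @export
hash_embedder <- function(dim = 256L, seed = 1L) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 2L) stop("dim must be >= 2", call. = FALSE)
  structure(list(dim = dim, seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = "hash_embedder")
}

# bucket index (1..dim) and sign (+/-1) for one token, memoised per embedder
.token_slot <- function(embedder, token) {
  hit <- embedder$cache[[token]]
  if (!is.null(hit)) return(hit)
  b <- (.hash_string(token, embedder$seed, salt = 1) %% embedder$dim) + 1L
  s <- if ((.hash_string(token, embedder$seed, salt = 2) %% 2) == 0) 1 else -1
  slot <- c(bucket = b, sign = s)
  embedder$cache[[token]] <- slot
  slot
}

.hash_embed_tokens <- function(embedder, tokens) {
  v <- numeric(embedder$dim)
  for (tok in tokens) {
    slot <- .token_slot(embedder, tok)
    v[slot[["bucket"]]] <- v[slot[["bucket"]]] + slot[["sign"]]
  }
  n <- sqrt(sum(v * v))
  if (n > 0) v <- v / n
  v
}

#' Embed a single phrase or text
#'
#' @param embedder an embedder object.
#' @param text one character string.
#' @return numeric vector of length `embedder$dim`.
#' @export
embed_phrase <- function(embedder, text) UseMethod("embed_phrase")

#' @export
embed_phrase.hash_embedder <- function(embedder, text) {
  stopifnot(is.character(text), length(text) == 1)
  .hash_embed_tokens(embedder, tokenize_text(text)[[1]])
}

#' Embed several texts into document vectors
#'
#' @param embedder an embedder object.
#' @param texts character vector.
#' @return matrix with one row per text.
#' @export
embed_documents <- function(embedder, texts) UseMethod("embed_documents")

#' @export
embed_documents.hash_embedder <- function(embedder, texts) {
  stopifnot(is.character(texts))
  toks <- tokenize_text(texts)
  t(vapply(toks, function(tk) .hash_embed_tokens(embedder, tk),
           numeric(embedder$dim)))
}

#' Embed vocabulary terms into the same space as documents
#'
#' @param embedder an embedder object.
#' @param vocabulary character vector of terms.
#' @return matrix with one row per term, rownames = vocabulary.
#' @export
embed_terms <- function(embedder, vocabulary) UseMethod("embed_terms")

#' @export
embed_terms.hash_embedder <- function(embedder, vocabulary) {
  stopifnot(is.character(vocabulary))
  m <- t(vapply(vocabulary, function(term) embed_phrase(embedder, term),
                numeric(embedder$dim)))
  rownames(m) <- vocabulary
  m
}

#' Embed a publication corpus
#'
#' The embedded text of each publication is its title and body text joined
#' by a single space; row `i` of the returned matrix corresponds to record
#' `i`, with `pub_id` rownames.
#'
#' @param records a publication record data frame (see [parse_pubmed_xml()]).
#' @param embedder an embedder object.
#' @return matrix of document vectors, rownames = `pub_id`.
#' @export
embed_corpus <- function(records, embedder) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("embed_corpus requires a non-empty record set", call. = FALSE)
  }
  texts <- paste(records$title, records$body_text)
  m <- embed_documents(embedder, texts)
  rownames(m) <- records$pub_id
  m
}
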