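# fully enumerated reference implementation: materialises every window and
# every NPMI term with plain loops
cv_bruteforce <- function(word_sets, corpus_tokens, window, eps) {
  windows <- list()
  for (doc in corpus_tokens) {
    len <- length(doc)
    if (len == 0) next
    if (len <= window) {
      windows[[length(windows) + 1]] <- doc
    } else {
      for (s in 1:(len - window + 1)) {
        windows[[length(windows) + 1]] <- doc[s:(s + window - 1)]
      }
    }
  }
  B <- length(windows)
  p1 <- function(w) sum(vapply(windows, function(win) w %in% win,
                               logical(1))) / B
  p2 <- function(a, b) sum(vapply(windows, function(win) {
    (a %in% win) && (b %in% win)
  }, logical(1))) / B
  npmi <- function(a, b) {
    pa <- p1(a); pb <- p1(b)
    if (pa == 0) pa <- eps
    if (pb == 0) pb <- eps
    pij <- p2(a, b)
    log((pij + eps) / (pa * pb)) / (-log(pij + eps))
  }
  scores <- numeric(0)
  for (words in word_sets) {
    nw <- length(words)
    ctx <- matrix(0, nw, nw)
    for (i in 1:nw) for (j in 1:nw) ctx[i, j] <- npmi(words[i], words[j])
    total <- colSums(ctx)
    wscore <- numeric(nw)
    for (i in 1:nw) {
      wscore[i] <- sum(ctx[i, ] * total) /
        (sqrt(sum(ctx[i, ]^2)) * sqrt(sum(total^2)))
    }
    scores <- c(scores, mean(wscore))
  }
  scores
}

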