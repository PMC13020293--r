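test_that("well-separated planted topics are recovered exactly", {
  gen <- planted_corpus(seed = 7)
  fit <- fit_planted(gen)
  expect_equal(fit$model$n_topics, 2)
  ari <- mclust::adjustedRandIndex(fit$model$assignments,
                                   gen$manifest$topic)
  expect_equal(ari, 1.0)
})

test_that("topic sizes plus noise conserve the corpus size", {
  gen <- planted_corpus(seed = 5)
  fit <- fit_planted(gen)
  m <- fit$model
  expect_equal(sum(m$topic_sizes) + sum(m$assignments == NOISE_TOPIC),
               length(m$assignments))
})

test_that("an all-identical corpus yields one topic whose centroid is the shared vector", {
  dv <- matrix(rep(c(0.2, 0.5, 0.1, 0.7), each = 25), nrow = 25)
  rownames(dv) <- sprintf("p%02d", 1:25)
  m <- fit_topic_model(dv, clusterer = density_clusterer(min_cluster_size = 5))
  expect_equal(m$n_topics, 1)
  expect_equal(unname(m$topic_sizes), 25L)
  expect_equal(unname(m$centroids[1, ]), c(0.2, 0.5, 0.1, 0.7),
               tolerance = 1e-12)
})

test_that("all-noise data gives a no-topics-found model, not an exception", {
  set.seed(4)
  dv <- matrix(rnorm(10 * 3), nrow = 10)
  rownames(dv) <- paste0("p", 1:10)
  m <- fit_topic_model(dv,
                       clusterer = density_clusterer(min_cluster_size = 50))
  expect_equal(m$n_topics, 0)
  expect_true(all(m$assignments == NOISE_TOPIC))
  expect_output(print(m), "no topics found")
})

test_that("centroids equal the brute-force mean of member vectors", {
  gen <- planted_corpus(seed = 9)
  fit <- fit_planted(gen)
  for (t in seq_len(fit$model$n_topics)) {
    members <- names(fit$model$assignments)[fit$model$assignments == t]
    manual <- colSums(fit$doc_vectors[members, , drop = FALSE]) /
      length(members)
    expect_equal(unname(fit$model$centroids[as.character(t), ]),
                 unname(manual), tolerance = 1e-12)
  }
})

test_that("fitting is bit-reproducible with the PCA reducer and fixed seed", {
  gen <- planted_corpus(seed = 13)
  f1 <- fit_planted(gen)
  f2 <- fit_planted(gen)
  expect_identical(f1$model$assignments, f2$model$assignments)
  expect_identical(f1$model$centroids, f2$model$centroids)
})

test_that("document ranking returns the top-10 by centroid cosine with ties by id", {
  gen <- planted_corpus(seed = 7)
  fit <- fit_planted(gen)
  r <- rank_topic_documents(fit$model, fit$doc_vectors, 1)
  expect_equal(nrow(r), 10) # default subset size
  expect_true(all(diff(r$similarity) <= 1e-15))
  # full-sort oracle over all members
  members <- names(fit$model$assignments)[fit$model$assignments == 1]
  sims <- vapply(members, function(id) {
    cos_loop(fit$doc_vectors[id, ], fit$model$centroids["1", ])
  }, numeric(1))
  oracle <- members[order(-sims, members)][1:10]
  expect_identical(r$pub_id, oracle)
  expect_error(rank_topic_documents(fit$model, fit$doc_vectors, 99),
               "unknown topic")
})

test_that("ranking truncates to the topic size for small topics", {
  dv <- rbind(diag(3) + 1, diag(3) + 1.01)
  rownames(dv) <- paste0("p", 1:6)
  m <- fit_topic_model(dv, clusterer = density_clusterer(min_cluster_size = 3))
  expect_equal(m$n_topics, 1)
  r <- rank_topic_documents(m, dv, 1, n = 10)
  expect_equal(nrow(r), 6)
})

test_that("nearest-word topic words match an exhaustive scan", {
  emb <- hash_embedder(dim = 64, seed = 2)
  vocab <- c("pain", "propofol", "catheter", "microbiome", "ammonia")
  wv <- embed_terms(emb, vocab)
  # centroid equal to one word's vector puts that word first at similarity 1
  tw <- topic_words_nearest(wv["catheter", ], wv, vocab, k = 3)
  expect_identical(tw$term[1], "catheter")
  expect_equal(tw$similarity[1], 1.0, tolerance = 1e-12)
  # exhaustive oracle on a random centroid
  set.seed(8)
  centroid <- rnorm(64)
  tw <- topic_words_nearest(centroid, wv, vocab, k = 5)
  sims <- vapply(vocab, function(w) cos_loop(wv[w, ], centroid), numeric(1))
  expect_identical(tw$term, vocab[order(-sims, vocab)])
  expect_equal(tw$similarity, unname(sims[order(-sims, vocab)]),
               tolerance = 1e-12)
  # k = 0 and oversized k
  expect_equal(nrow(topic_words_nearest(centroid, wv, vocab, k = 0)), 0)
  expect_message(all_t <- topic_words_nearest(centroid, wv, vocab, k = 10),
                 "returning all")
  expect_equal(nrow(all_t), 5)
})

test_that("class-based topic words follow the tf x log(1 + A/f) formula", {
  # single-topic frequency ordering
  one <- topic_words_ctfidf(list(`1` = "aa aa bb"), k = 5)
  expect_identical(one[["1"]]$term, c("aa", "bb"))
  # a ubiquitous term scores below an equally frequent exclusive term
  by_topic <- list(`1` = "common exclusive exclusive common",
                   `2` = "common other other common")
  tw <- topic_words_ctfidf(by_topic, k = 5)
  s1 <- tw[["1"]]
  expect_gt(s1$score[s1$term == "exclusive"], s1$score[s1$term == "common"])
  # three-topic loop oracle of the exact formula
  texts <- list(`1` = c("alpha alpha beta shared"),
                `2` = c("gamma gamma shared delta"),
                `3` = c("epsilon shared shared beta"))
  tw <- topic_words_ctfidf(texts, k = 10)
  toks <- lapply(texts, function(t) unlist(tokenize_text(t)))
  a_mean <- mean(lengths(toks))
  corpus_f <- table(unlist(toks))
  for (topic in names(texts)) {
    tf <- table(toks[[topic]])
    for (term in names(tf)) {
      expected <- as.numeric(tf[term]) *
        log(1 + a_mean / as.numeric(corpus_f[term]))
      got <- tw[[topic]]$score[tw[[topic]]$term == term]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # empty pseudo-document yields an empty table
  expect_equal(nrow(topic_words_ctfidf(list(`1` = "a !", `2` = "xx"))[["1"]]),
               0)
})

test_that("model persistence writes readable plain-text tables", {
  gen <- planted_corpus(seed = 7)
  fit <- fit_planted(gen)
  dir <- withr::local_tempdir()
  write_topic_model(fit$model, dir)
  asg <- read.delim(file.path(dir, "assignments.tsv"),
                    colClasses = c("character", "integer"))
  expect_equal(nrow(asg), 60)
  expect_identical(asg$pub_id, names(fit$model$assignments))
})
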