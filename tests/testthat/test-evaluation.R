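table4_pcts <- c(16.6, 40, 65, 15, 65, 35, 33.3, 43.3, 25, 56.6,
                 80, 40, 56.6, 50, 100, 90, 100, 30)

test_that("user-agreed relevance counts only topics with a relevant label", {
  sugg <- list(`1` = paste0("p", 1:10))
  asg <- label_assignments(paste0("p", 1:3), TRUE, "T")
  expect_equal(user_agreed_relevance(asg, sugg), 30.0)
  # a second, unlabelled topic is excluded from the denominator
  sugg2 <- list(`1` = paste0("p", 1:10), `2` = paste0("q", 1:10))
  asg2 <- label_assignments(paste0("p", 1:4), TRUE, "T")
  expect_equal(user_agreed_relevance(asg2, sugg2), 40.0)
  # no relevant topic at all
  none <- user_agreed_relevance(
    label_assignments("p1", FALSE, NA), sugg)
  expect_true(is.na(none))
  expect_identical(attr(none, "reason"), "no relevant topics")
  expect_error(user_agreed_relevance(asg, list()), "non-empty")
})

test_that("user-agreed relevance matches a brute-force recount on random labels", {
  set.seed(12)
  for (i in 1:25) {
    topics <- paste0("t", 1:3)
    sugg <- setNames(lapply(topics, function(t) {
      paste0(t, "_p", seq_len(sample(3:10, 1)))
    }), topics)
    all_ids <- unlist(sugg)
    rel <- sample(c(TRUE, FALSE), length(all_ids), replace = TRUE)
    asg <- label_assignments(all_ids, rel,
                             ifelse(rel, "label", NA))
    got <- user_agreed_relevance(asg, sugg)
    # loop oracle
    rel_ids <- all_ids[rel]
    num <- den <- 0
    for (t in topics) {
      hits <- sum(sugg[[t]] %in% rel_ids)
      if (hits > 0) {
        num <- num + hits
        den <- den + length(sugg[[t]])
      }
    }
    if (den == 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, 100 * num / den, tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 100)
    }
  }
})

test_that("adding a relevant label never decreases user-agreed relevance", {
  sugg <- list(`1` = paste0("p", 1:10), `2` = paste0("q", 1:10))
  base_ids <- c("p1", "q1")
  prev <- user_agreed_relevance(
    label_assignments(base_ids, TRUE, "T"), sugg)
  for (extra in c("p2", "q2", "p3")) {
    base_ids <- c(base_ids, extra)
    cur <- user_agreed_relevance(
      label_assignments(base_ids, TRUE, "T"), sugg)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("relevance summary reproduces the published per-search table", {
  s <- relevance_summary(table4_pcts, threshold = 50)
  expect_equal(s$mean, 52.3)
  expect_equal(s$minimum, 15)
  expect_equal(s$n_at_or_above, 9)
  # singleton and error behaviour
  one <- relevance_summary(40)
  expect_equal(one$mean, 40.0)
  expect_equal(one$minimum, 40.0)
  expect_equal(one$n_at_or_above, 0)
  expect_error(relevance_summary(numeric(0)), "no relevance")
})

test_that("relevance summary matches a loop oracle on random inputs", {
  set.seed(99)
  for (i in 1:100) {
    pcts <- round(runif(sample(1:20, 1), 0, 100), 1)
    thr <- runif(1, 0, 100)
    s <- relevance_summary(pcts, thr)
    m <- 0; mn <- Inf; cnt <- 0
    for (p in pcts) {
      m <- m + p
      if (p < mn) mn <- p
      if (p >= thr) cnt <- cnt + 1
    }
    # reported mean is the loop mean up to one-decimal rounding
    expect_lte(abs(s$mean - m / length(pcts)), 0.05 + 1e-9)
    expect_equal(s$minimum, mn)
    expect_equal(s$n_at_or_above, cnt)
    expect_gte(s$mean, min(pcts) - 0.05)
    expect_lte(s$mean, max(pcts) + 0.05)
  }
})

test_that("reference rank positions are 1-based with absent ids dropped", {
  ranking <- paste0("r", 1:10)
  st <- reference_rank_stats(c("r1", "r3"), ranking)
  expect_equal(st$mean, 2.0)
  expect_equal(st$median, 2.0)
  expect_equal(st$dropped, 0)
  st2 <- reference_rank_stats(c("r1", "zz"), ranking)
  expect_equal(st2$dropped, 1)
  expect_equal(st2$positions, 1)
  empty <- reference_rank_stats(character(0), ranking)
  expect_equal(length(empty$positions), 0)
  expect_true(is.na(empty$mean))
})

test_that("rank stats over a large synthetic ranking match an index-scan oracle", {
  set.seed(5)
  ranking <- sample(sprintf("id%04d", 1:500))
  relevant <- sample(ranking, 25)
  st <- reference_rank_stats(relevant, ranking, bin_width = 50)
  pos <- integer(0)
  for (id in relevant) {
    for (i in seq_along(ranking)) {
      if (ranking[i] == id) { pos <- c(pos, i); break }
    }
  }
  expect_equal(sort(st$positions), sort(pos))
  expect_equal(st$mean, mean(pos))
  expect_equal(st$median, median(pos))
  expect_equal(sum(st$histogram$count), 25)
  for (b in seq_len(nrow(st$histogram))) {
    expect_equal(st$histogram$count[b],
                 sum(pos >= st$histogram$bin_start[b] &
                       pos <= st$histogram$bin_end[b]))
  }
})

test_that("relevance correlates report Spearman rho for volume and specificity", {
  # perfectly monotone decreasing relevance vs count
  df <- data.frame(result_count = c(10, 100, 1000, 5000),
                   specificity = c(20, 15, 10, 5),
                   relevance_pct = c(90, 60, 30, 10))
  rc <- relevance_correlates(df)
  expect_equal(rc$rho_volume, -1.0)
  expect_equal(rc$rho_specificity, 1.0)
  # shuffled independent series stay near zero
  set.seed(6)
  big <- data.frame(result_count = sample(200),
                    specificity = sample(200),
                    relevance_pct = sample(200))
  rc2 <- relevance_correlates(big)
  expect_lt(abs(rc2$rho_volume), 0.2)
  expect_lt(abs(rc2$rho_specificity), 0.2)
  # constant series -> undefined
  const <- data.frame(result_count = c(5, 5, 5), specificity = 1:3,
                      relevance_pct = c(10, 20, 30))
  expect_true(is.na(relevance_correlates(const)$rho_volume))
  expect_error(relevance_correlates(df[1:2, ]), "at least 3")
})

test_that("tie-heavy Spearman matches an average-rank brute force", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    df <- data.frame(result_count = x, specificity = seq_len(30),
                     relevance_pct = y)
    rho <- relevance_correlates(df)$rho_volume
    # Pearson on average ranks
    rx <- rank(x); ry <- rank(y)
    manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(rho, manual, tolerance = 1e-12)
  }
})
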