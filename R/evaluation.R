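#' User-agreed relevance of suggested publications
#'
#' The percentage of suggested publications the user marked relevant,
#' counting only topics that received at least one relevant label: the
#' denominator is the total number of publications suggested within those
#' topics, the numerator the relevant labels among them. Topics the user
#' never marked relevant are excluded entirely.
#'
#' @param assignments a `label_assignments` data frame.
#' @param suggestions named list: topic id -> character vector of suggested
#'   publication ids (e.g. the top-10 per topic).
#' @return percentage in \[0, 100\] (unrounded), or `NA` with attribute
#'   `reason = "no relevant topics"` when no topic received a relevant
#'   label.
#' @export
user_agreed_relevance <- function(assignments, suggestions) {
  if (length(suggestions) == 0) {
    stop("suggestions must be non-empty", call. = FALSE)
  }
  relevant_ids <- assignments$pub_id[assignments$relevant]
  counted <- vapply(suggestions, function(ids) {
    any(ids %in% relevant_ids)
  }, logical(1))
  if (!any(counted)) {
    return(structure(NA_real_, reason = "no relevant topics"))
  }
  kept <- suggestions[counted]
  n_suggested <- sum(lengths(kept))
  n_relevant <- sum(vapply(kept, function(ids) {
    sum(ids %in% relevant_ids)
  }, integer(1)))
  100 * n_relevant / n_suggested
}

#' Summarise per-search relevance percentages
#'
#' @param per_search_pcts numeric vector of per-search user-agreed
#'   relevance percentages, one per search.
#' @param threshold percentage threshold for the count (default 50).
#' @return list with `mean` (rounded to one decimal, matching reporting
#'   style), `minimum`, and `n_at_or_above` the threshold.
#' @export
relevance_summary <- function(per_search_pcts, threshold = 50) {
  if (length(per_search_pcts) == 0) {
    stop("no relevance percentages supplied", call. = FALSE)
  }
  list(mean = round(mean(per_search_pcts), 1),
       minimum = min(per_search_pcts),
       n_at_or_above = sum(per_search_pcts >= threshold))
}

#' Positions of relevant publications within a reference ranking
#'
#' Locates each relevant publication in an ordered reference ranking (for
#' instance a recorded best-match result list) and summarises the 1-based
#' rank positions. Ids absent from the ranking are dropped and counted
#' separately.
#'
#' @param relevant_ids character ids of relevant publications.
#' @param reference_ranking character vector of ids, best rank first.
#' @param bin_width histogram bin width in ranks (default 50).
#' @return list with `positions` (found ranks, in input order), `mean`,
#'   `median`, `dropped` (count of ids not in the ranking), and `histogram`
#'   (data frame `bin_start`, `bin_end`, `count` over
#'   \[1, bin_width\], (bin_width, 2 bin_width\], ...).
#' @export
reference_rank_stats <- function(relevant_ids, reference_ranking,
                                 bin_width = 50L) {
  if (length(reference_ranking) == 0) {
    stop("reference ranking must be non-empty", call. = FALSE)
  }
  bin_width <- as.integer(bin_width)
  if (length(relevant_ids) == 0) {
    return(list(positions = integer(0), mean = NA_real_, median = NA_real_,
                dropped = 0L,
                histogram = data.frame(bin_start = integer(0),
                                       bin_end = integer(0),
                                       count = integer(0))))
  }
  pos <- match(relevant_ids, reference_ranking)
  dropped <- sum(is.na(pos))
  found <- pos[!is.na(pos)]
  n_bins <- ceiling(length(reference_ranking) / bin_width)
  starts <- (seq_len(n_bins) - 1L) * bin_width + 1L
  ends <- starts + bin_width - 1L
  counts <- vapply(seq_len(n_bins), function(b) {
    sum(found >= starts[b] & found <= ends[b])
  }, integer(1))
  list(positions = found,
       mean = if (length(found)) mean(found) else NA_real_,
       median = if (length(found)) stats::median(found) else NA_real_,
       dropped = dropped,
       histogram = data.frame(bin_start = starts, bin_end = ends,
                              count = counts))
}

#' Relationship of relevance to result volume and keyword specificity
#'
#' Pairs each search's user-agreed relevance with (a) the number of results
#' its query retrieved and (b) its keyword specificity (mean phrase length
#' in characters), and reports Spearman rank correlations for both
#' pairings. A constant series makes the correlation undefined and is
#' reported as `NA`.
#'
#' @param searches data frame with columns `result_count`, `specificity`,
#'   `relevance_pct`; at least 3 rows.
#' @return list with `volume_pairs`, `specificity_pairs` (data frames) and
#'   `rho_volume`, `rho_specificity` (Spearman coefficients or `NA`).
#' @export
relevance_correlates <- function(searches) {
  stopifnot(is.data.frame(searches),
            all(c("result_count", "specificity", "relevance_pct")
                %in% names(searches)))
  if (nrow(searches) < 3) {
    stop("at least 3 searches are required", call. = FALSE)
  }
  spearman <- function(x, y) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  list(volume_pairs = searches[, c("result_count", "relevance_pct")],
       specificity_pairs = searches[, c("specificity", "relevance_pct")],
       rho_volume = spearman(searches$result_count, searches$relevance_pct),
       rho_specificity = spearman(searches$specificity,
                                  searches$relevance_pct))
}
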