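#' Create a keyword alias group
#'
#' A keyword group is a keyword together with its synonyms ("aliases"), e.g.
#' "Maternal Pain" and "Pain during pregnancy". Within a group the phrases
#' are OR-ed in the final boolean query; distinct groups are AND-ed.
#'
#' @param phrases character vector of at least one non-empty phrase. Leading
#'   and trailing whitespace is stripped; phrase order is preserved.
#' @return an object of class `keyword_group`.
#' @export
#' @examples
#' keyword_group(c("Maternal Pain", "Pain during pregnancy"))
keyword_group <- function(phrases) {
  if (!is.character(phrases) || length(phrases) == 0) {
    stop("a keyword group needs at least one phrase", call. = FALSE)
  }
  phrases <- trimws(phrases)
  if (any(!nzchar(phrases))) {
    stop("keyword group phrases must be non-empty", call. = FALSE)
  }
  structure(list(phrases = phrases), class = "keyword_group")
}

#' Create a search specification
#'
#' A search is defined by one or two alias groups (the design limits a search
#' to two groups; requests for more are rejected rather than truncated) and
#' the maximum number of records to retrieve.
#'
#' @param group1 a [keyword_group()] (or character vector coerced to one).
#' @param group2 optional second [keyword_group()]; `NULL` when the search
#'   uses a single group.
#' @param max_results positive integer retrieval cap.
#' @param ... must be empty; passing further groups is an error because the
#'   design supports at most two alias groups.
#' @return an object of class `search_spec`.
#' @export
#' @examples
#' search_spec(keyword_group(c("POCD", "Postoperative cognitive disorder")))
search_spec <- function(group1, group2 = NULL, max_results = 100L, ...) {
  extra <- list(...)
  if (inherits(max_results, "keyword_group") || length(extra) > 0) {
    stop("at most two keyword groups are supported ",
         "(the search design limits a query to two alias groups)",
         call. = FALSE)
  }
  if (is.character(group1)) group1 <- keyword_group(group1)
  if (is.character(group2)) group2 <- keyword_group(group2)
  if (!inherits(group1, "keyword_group")) {
    stop("group1 must be a keyword_group", call. = FALSE)
  }
  if (!is.null(group2) && !inherits(group2, "keyword_group")) {
    stop("group2 must be a keyword_group or NULL", call. = FALSE)
  }
  max_results <- as.integer(max_results)
  if (is.na(max_results) || max_results < 1L) {
    stop("max_results must be a positive integer", call. = FALSE)
  }
  structure(list(group1 = group1, group2 = group2,
                 max_results = max_results),
            class = "search_spec")
}

#' Build the boolean PubMed query for a search
#'
#' Phrases within a group are joined with `" OR "`, each group is wrapped in
#' parentheses, and two groups are joined with `" AND "`. Phrases are emitted
#' bare (no quoting, no field tags) and in the order given.
#'
#' @param spec a [search_spec()].
#' @return a single query string.
#' @export
#' @examples
#' build_boolean_query(search_spec(
#'   keyword_group(c("Maternal Pain", "Pain during pregnancy")),
#'   keyword_group(c("Postpartum depression", "Postnatal depression"))))
build_boolean_query <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  clause <- function(g) paste0("(", paste(g$phrases, collapse = " OR "), ")")
  q <- clause(spec$group1)
  if (!is.null(spec$group2)) {
    q <- paste(q, "AND", clause(spec$group2))
  }
  q
}

#' Keyword specificity of a search
#'
#' Specificity is estimated as the average length of the keywords used in a
#' search, in characters: the arithmetic mean of the character counts of all
#' phrases across both groups, in a single averaging step. Internal spaces
#' count; surrounding whitespace does not (phrases are stored trimmed).
#' Counting is Unicode code-point based.
#'
#' @param spec a [search_spec()].
#' @return non-negative numeric, mean characters per phrase.
#' @export
#' @examples
#' keyword_specificity(search_spec(keyword_group("POCD")))  # 4
keyword_specificity <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  phrases <- c(spec$group1$phrases,
               if (!is.null(spec$group2)) spec$group2$phrases)
  mean(nchar(phrases, type = "chars"))
}

#' @export
print.search_spec <- function(x, ...) {
  cat("Search specification\n")
  cat("  group 1:", paste(x$group1$phrases, collapse = " | "), "\n")
  if (!is.null(x$group2)) {
    cat("  group 2:", paste(x$group2$phrases, collapse = " | "), "\n")
  }
  cat("  max results:", x$max_results, "\n")
  cat("  query:", build_boolean_query(x), "\n")
  invisible(x)
}
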