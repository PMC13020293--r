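#' Build the meta-information profile of a topic
#'
#' Computes the five summaries shown for each topic: the ranked topic words
#' plus frequency tables of MeSH descriptors, chemicals/medicines, author
#' keywords, and publication years across the topic's records. A descriptor
#' listed twice in one record counts once (per-record deduplication);
#' records with unknown year are omitted from the year histogram. Tables
#' are sorted count-descending, then name ascending.
#'
#' @param records_in_topic `publication_records` rows belonging to a topic.
#' @param topic_words optional ranked topic-word data frame (passed through
#'   from the topic model).
#' @return an object of class `topic_profile` with elements `topic_words`,
#'   `mesh_freq`, `chemical_freq`, `keyword_freq`, `year_hist`.
#' @export
build_topic_profile <- function(records_in_topic, topic_words = NULL) {
  if (!is.data.frame(records_in_topic) || nrow(records_in_topic) < 1) {
    stop("a topic profile needs at least one record", call. = FALSE)
  }
  dedup_counts <- function(col) {
    sorted_count_df(unlist(lapply(records_in_topic[[col]], unique)))
  }
  years <- records_in_topic$year
  years <- years[!is.na(years)]
  year_hist <- if (length(years) == 0) {
    data.frame(year = integer(0), count = integer(0))
  } else {
    tab <- table(years)
    data.frame(year = as.integer(names(tab)), count = as.integer(tab),
               row.names = NULL)
  }
  structure(list(topic_words = topic_words,
                 mesh_freq = dedup_counts("mesh_terms"),
                 chemical_freq = dedup_counts("chemicals"),
                 keyword_freq = dedup_counts("keywords"),
                 year_hist = year_hist,
                 n_records = nrow(records_in_topic)),
            class = "topic_profile")
}

#' @export
print.topic_profile <- function(x, ...) {
  cat("Topic profile over", x$n_records, "publication(s)\n")
  if (!is.null(x$topic_words) && nrow(x$topic_words) > 0) {
    cat("  topic words:", paste(utils::head(x$topic_words$term, 10),
                                collapse = ", "), "\n")
  }
  cat("  MeSH descriptors:", nrow(x$mesh_freq),
      "| chemicals:", nrow(x$chemical_freq),
      "| keywords:", nrow(x$keyword_freq),
      "| years:", nrow(x$year_hist), "\n")
  invisible(x)
}

#' Write a topic profile as JSON
#'
#' @param profile a `topic_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topic_profile <- function(profile, path) {
  stopifnot(inherits(profile, "topic_profile"))
  jsonlite::write_json(
    list(n_records = profile$n_records,
         topic_words = profile$topic_words,
         mesh_freq = profile$mesh_freq,
         chemical_freq = profile$chemical_freq,
         keyword_freq = profile$keyword_freq,
         year_hist = profile$year_hist),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
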