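#' Construct a publication record set
#'
#' Internal constructor/validator for the corpus container: a data frame
#' with one row per publication and list-columns for metadata.
#'
#' @param pub_id character PMIDs, non-empty and unique.
#' @param title character titles, non-empty.
#' @param body_text abstract (and any further text) per record.
#' @param year integer publication year or `NA` when unknown.
#' @param mesh_terms,chemicals,keywords lists of character vectors.
#' @return a `publication_records` data frame.
#' @export
publication_records <- function(pub_id, title, body_text,
                                year = NA_integer_,
                                mesh_terms = NULL, chemicals = NULL,
                                keywords = NULL) {
  n <- length(pub_id)
  empty_lists <- function(x) {
    if (is.null(x)) rep(list(character(0)), n) else x
  }
  pub_id <- as.character(pub_id)
  if (any(!nzchar(pub_id)) || anyDuplicated(pub_id)) {
    stop("pub_id values must be non-empty and unique within a corpus",
         call. = FALSE)
  }
  if (any(!nzchar(title))) {
    stop("titles must be non-empty", call. = FALSE)
  }
  year <- as.integer(year)
  if (length(year) == 1) year <- rep(year, n)
  bad_year <- !is.na(year) & (year < 1800 | year > 2100)
  if (any(bad_year)) {
    stop("years must lie in [1800, 2100] when present", call. = FALSE)
  }
  out <- data.frame(pub_id = pub_id, title = as.character(title),
                    body_text = as.character(body_text), year = year,
                    stringsAsFactors = FALSE)
  out$mesh_terms <- empty_lists(mesh_terms)
  out$chemicals <- empty_lists(chemicals)
  out$keywords <- empty_lists(keywords)
  class(out) <- c("publication_records", "data.frame")
  out
}

#' Parse PubMed efetch XML into publication records
#'
#' Accepts the `PubmedArticleSet` dialect returned by the Entrez efetch
#' endpoint. One record is produced per `PubmedArticle`, preserving the
#' article order of the XML (which is the retrieval ranking). Body text is
#' all `AbstractText` sections joined with newlines. Year extraction
#' prefers `PubDate/Year`, then the first four-digit year in a
#' `MedlineDate`, then `ArticleDate/Year`, else unknown. MeSH terms are
#' descriptor names only (qualifiers ignored). Articles lacking both title
#' and abstract are dropped with a warning.
#'
#' @param xml an `xml_document`, a file path, or a length-1 XML string.
#' @return a `publication_records` data frame (zero rows for an empty set).
#' @export
parse_pubmed_xml <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else {
    tryCatch(xml2::read_xml(xml),
             error = function(e) {
               stop("malformed PubMed XML: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  articles <- xml2::xml_find_all(doc, "//PubmedArticle")
  if (length(articles) == 0) {
    return(publication_records(character(0), character(0), character(0),
                               integer(0)))
  }
  first_text <- function(node, xpath) {
    hit <- xml2::xml_find_first(node, xpath)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  all_text <- function(node, xpath) {
    xml2::xml_text(xml2::xml_find_all(node, xpath))
  }
  parse_one <- function(art) {
    title <- first_text(art, ".//Article/ArticleTitle")
    abstract <- paste(all_text(art, ".//Article/Abstract/AbstractText"),
                      collapse = "\n")
    year <- first_text(art, ".//Journal/JournalIssue/PubDate/Year")
    if (is.na(year)) {
      medline <- first_text(art, ".//Journal/JournalIssue/PubDate/MedlineDate")
      if (!is.na(medline)) {
        m <- regmatches(medline, regexpr("[0-9]{4}", medline))
        if (length(m) == 1) year <- m
      }
    }
    if (is.na(year)) year <- first_text(art, ".//Article/ArticleDate/Year")
    list(pub_id = first_text(art, ".//MedlineCitation/PMID"),
         title = title,
         body_text = abstract,
         year = suppressWarnings(as.integer(year)),
         mesh = all_text(art, ".//MeshHeadingList/MeshHeading/DescriptorName"),
         chem = all_text(art, ".//ChemicalList/Chemical/NameOfSubstance"),
         kw = all_text(art, ".//KeywordList/Keyword"))
  }
  parsed <- lapply(articles, parse_one)
  usable <- vapply(parsed, function(p) {
    (!is.na(p$title) && nzchar(p$title)) || nzchar(p$body_text)
  }, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " article(s) lacking both title and abstract ",
            "were dropped", call. = FALSE)
    parsed <- parsed[usable]
  }
  if (length(parsed) == 0) {
    return(publication_records(character(0), character(0), character(0),
                               integer(0)))
  }
  publication_records(
    pub_id = vapply(parsed, `[[`, character(1), "pub_id"),
    title = vapply(parsed, function(p) {
      if (is.na(p$title) || !nzchar(p$title)) "[no title]" else p$title
    }, character(1)),
    body_text = vapply(parsed, `[[`, character(1), "body_text"),
    year = vapply(parsed, function(p) {
      if (is.null(p$year) || length(p$year) == 0) NA_integer_ else p$year
    }, integer(1)),
    mesh_terms = lapply(parsed, `[[`, "mesh"),
    chemicals = lapply(parsed, `[[`, "chem"),
    keywords = lapply(parsed, `[[`, "kw"))
}

#' Write a corpus cache as JSONL
#'
#' One UTF-8 JSON object per line, field names matching the record columns.
#' The round trip through [read_corpus_jsonl()] is lossless.
#'
#' @param records a `publication_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(list(
      pub_id = jsonlite::unbox(records$pub_id[i]),
      title = jsonlite::unbox(records$title[i]),
      body_text = jsonlite::unbox(records$body_text[i]),
      year = jsonlite::unbox(records$year[i]),
      mesh_terms = records$mesh_terms[[i]],
      chemicals = records$chemicals[[i]],
      keywords = records$keywords[[i]]), null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL corpus cache
#'
#' @param path path written by [write_corpus_jsonl()].
#' @return a `publication_records` data frame in file order.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  as_chr <- function(x) if (length(x) == 0) character(0) else as.character(x)
  publication_records(
    pub_id = vapply(objs, function(o) as.character(o$pub_id), character(1)),
    title = vapply(objs, function(o) as.character(o$title), character(1)),
    body_text = vapply(objs, function(o) as.character(o$body_text),
                       character(1)),
    year = vapply(objs, function(o) {
      if (is.null(o$year)) NA_integer_ else as.integer(o$year)
    }, integer(1)),
    mesh_terms = lapply(objs, function(o) as_chr(o$mesh_terms)),
    chemicals = lapply(objs, function(o) as_chr(o$chemicals)),
    keywords = lapply(objs, function(o) as_chr(o$keywords)))
}

#' Fetch publications from PubMed (Entrez E-utilities)
#'
#' Runs an `esearch` for the boolean query followed by an `efetch` of the
#' matching PMIDs, returning the article-set XML text. The best-match result
#' order returned by PubMed is preserved in the XML and is the reference
#' ranking used by [reference_rank_stats()]. The HTTP layer is injectable so
#' the contract can be exercised offline against recorded responses.
#'
#' @param query non-empty boolean query string, e.g. from
#'   [build_boolean_query()].
#' @param max_results positive integer retrieval cap.
#' @param transport function(url) -> character response body. Defaults to a
#'   plain HTTP GET; tests substitute a fixture transport.
#' @param email contact identity sent to NCBI, as their usage policy asks.
#' @return the efetch XML as a single string.
#' @export
fetch_publications <- function(query, max_results = 100L,
                               transport = default_transport,
                               email = getOption("litmapr.email", "")) {
  if (!is.character(query) || length(query) != 1 || !nzchar(query)) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  max_results <- as.integer(max_results)
  if (is.na(max_results) || max_results < 1L) {
    stop("max_results must be a positive integer", call. = FALSE)
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  esearch <- paste0(base, "/esearch.fcgi?db=pubmed&sort=relevance&term=",
                    utils::URLencode(query, reserved = TRUE),
                    "&retmax=", max_results,
                    if (nzchar(email)) paste0("&email=", email))
  search_xml <- xml2::read_xml(transport(esearch))
  ids <- xml2::xml_text(xml2::xml_find_all(search_xml, "//IdList/Id"))
  if (length(ids) == 0) {
    return("<?xml version=\"1.0\" ?>\n<PubmedArticleSet></PubmedArticleSet>")
  }
  efetch <- paste0(base, "/efetch.fcgi?db=pubmed&retmode=xml&id=",
                   paste(ids, collapse = ","),
                   if (nzchar(email)) paste0("&email=", email))
  transport(efetch)
}

#' @rdname fetch_publications
#' @param url request URL.
#' @export
default_transport <- function(url) {
  paste(readLines(url, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

#' Read / write a reference ranking file
#'
#' A reference ranking (e.g. a recorded best-match result order) is stored
#' as plain text, one publication id per line, best rank first.
#'
#' @param path file path.
#' @return character vector of ids in rank order.
#' @export
read_reference_ranking <- function(path) {
  ids <- readLines(path, encoding = "UTF-8")
  ids[nzchar(trimws(ids))]
}

#' @rdname read_reference_ranking
#' @param ids character vector of publication ids, best rank first.
#' @export
write_reference_ranking <- function(ids, path) {
  writeLines(as.character(ids), path, useBytes = TRUE)
  invisible(path)
}
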