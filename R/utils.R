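#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# session RNG.
with_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Tokenise free text
#'
#' Lowercases, splits on runs of non-alphanumeric characters and drops tokens
#' shorter than two characters. This is the tokeniser used for class-based
#' topic-word extraction and for coherence scoring; no stopword list is
#' applied (inverse class weighting demotes ubiquitous terms).
#'
#' @param text character vector of texts.
#' @return a list with one character vector of tokens per input text.
#' @export
#' @examples
#' tokenize_text("Maternal pain, and postpartum depression!")
tokenize_text <- function(text) {
  lapply(strsplit(tolower(text), "[^a-z0-9]+"), function(tok) {
    tok[nchar(tok) >= 2]
  })
}

# Sort a named count table: count descending, then name ascending.
sorted_count_df <- function(x, value_col = "term") {
  if (length(x) == 0) {
    out <- data.frame(term = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
    names(out)[1] <- value_col
    return(out)
  }
  tab <- table(x)
  nm <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, nm)
  out <- data.frame(term = nm[ord], count = cnt[ord], stringsAsFactors = FALSE)
  names(out)[1] <- value_col
  rownames(out) <- NULL
  out
}
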