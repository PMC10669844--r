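#' Activity classes recognised by the screen
#'
#' The four pharmacological activity classes the screen targets:
#' anti-oxidant (`AOX`), anti-inflammatory (`AINF`), anti-aging (`AAG`) and
#' anti-senescence (`ASEN`).
#'
#' @format Character vector of length four.
#' @export
ACTIVITY_CLASSES <- c("AOX", "AINF", "AAG", "ASEN")

#' Load the activity vocabulary table
#'
#' Maps free-text activity labels (as found in curated plant tables, e.g.
#' `"anti-oxidant"`, `"senolytic"`) onto the four canonical classes.  The
#' shipped table can be extended with user rows; matching is case-insensitive
#' and ignores hyphens, underscores and whitespace.
#'
#' @param extra Optional data frame with columns `token` and `class` appended
#'   to the shipped vocabulary.
#' @return Tibble with columns `token` (canonicalised) and `class`.
#' @export
activity_vocab <- function(extra = NULL) {
  path <- system.file("extdata", "activity_vocab.tsv", package = "phytoscreen")
  vocab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("token", "class") %in% names(extra)))
    vocab <- rbind(vocab[, c("token", "class")],
                   as.data.frame(extra)[, c("token", "class")])
  }
  bad <- setdiff(vocab$class, ACTIVITY_CLASSES)
  if (length(bad) > 0) {
    stop("unknown activity class in vocabulary: ", paste(bad, collapse = ", "))
  }
  vocab$token <- canonical_token(vocab$token)
  tibble::as_tibble(vocab[!duplicated(vocab$token), ])
}

canonical_token <- function(x) {
  gsub("[-_[:space:]]", "", tolower(trimws(x)))
}

#' Normalise free-text activity tokens
#'
#' @param tokens Character vector of raw labels.
#' @param vocab Vocabulary table from [activity_vocab()].
#' @return List with `activities` (subset of [ACTIVITY_CLASSES], unique,
#'   canonical order) and `unknown` (tokens not in the vocabulary, verbatim).
#' @export
normalize_activities <- function(tokens, vocab = activity_vocab()) {
  tokens <- tokens[!is.na(tokens) & nzchar(trimws(tokens))]
  if (length(tokens) == 0) {
    return(list(activities = character(0), unknown = character(0)))
  }
  idx <- match(canonical_token(tokens), vocab$token)
  acts <- unique(vocab$class[idx[!is.na(idx)]])
  list(
    activities = ACTIVITY_CLASSES[ACTIVITY_CLASSES %in% acts],
    unknown = tokens[is.na(idx)]
  )
}
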