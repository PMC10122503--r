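#' Normalize clinical free text
#'
#' Lower-cases the text and removes every character that is not a letter
#' (including the Finnish letters \enc{å}{a}, \enc{ä}{a}, \enc{ö}{o}), a
#' digit, or a space; runs of whitespace collapse to single spaces and
#' leading/trailing whitespace is trimmed. The transformation is idempotent,
#' so already-normalized text passes through unchanged. An empty result is
#' allowed (the caller decides whether to drop such sentences).
#'
#' @param text character vector of raw sentences.
#' @return character vector of normalized sentences.
#' @examples
#' normalize_text("Tupakointi: 10 ask./v!!")
#' @export
normalize_text <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z0-9åäö ]+", " ", x, perl = TRUE)
  x <- gsub(" +", " ", x, perl = TRUE)
  trimws(x)
}

#' Keep sentences containing a smoking-related word stem
#'
#' Retains exactly those sentences whose token sequence contains a token
#' beginning with one of the stems `tupak` (tobacco/smoking), `aski`
#' (pack), or `smok`. Sentences are expected to be normalized first
#' ([normalize_text()]), which makes the match effectively
#' case-insensitive.
#'
#' @param sentences a character vector of normalized sentences, or a
#'   data frame with a `text` column (rows are filtered).
#' @return object of the same shape as the input, restricted to candidate
#'   sentences.
#' @export
extract_candidate_sentences <- function(sentences) {
  txt <- if (is.data.frame(sentences)) sentences$text else sentences
  keep <- grepl("(^| )(tupak|aski|smok)", txt, perl = TRUE)
  if (is.data.frame(sentences)) sentences[keep, , drop = FALSE]
  else sentences[keep]
}
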