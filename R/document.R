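#' Construct an input document
#'
#' The recommender accepts two input types: free text, and comma-delimited
#' keywords. For keyword input the raw text is split on commas and each
#' keyword keeps its character span into the raw text; annotations that do
#' not cover a whole keyword are later discarded by
#' [filter_keyword_annotations()].
#'
#' @param text A single string: the raw input.
#' @param type `"text"` (default) or `"keywords"`.
#' @return An object of class `input_document` with fields `raw_text`,
#'   `input_type`, and (for keywords) a tibble `keywords` with columns
#'   `keyword`, `start`, `end` (1-based inclusive character spans).
#' @export
#' @examples
#' input_document("melanoma, skin, eye", type = "keywords")
input_document <- function(text, type = c("text", "keywords")) {
  if (!is_scalar_string(text)) abort_config("`text` must be a single string")
  type <- match.arg(type)
  keywords <- NULL
  if (type == "keywords") {
    pieces <- strsplit(text, ",", fixed = TRUE)[[1]]
    if (length(pieces) == 0) pieces <- ""
    ends <- cumsum(nchar(pieces) + 1L) - 1L # spans of the raw segments
    starts <- c(1L, utils::head(ends, -1) + 2L)
    # trim surrounding whitespace, keeping spans into raw_text
    lead <- nchar(pieces) - nchar(sub("^\\s+", "", pieces))
    trail <- nchar(pieces) - nchar(sub("\\s+$", "", pieces))
    keywords <- tibble::tibble(
      keyword = trimws(pieces),
      start = starts + lead,
      end = ends - trail
    )
    keywords <- keywords[nzchar(keywords$keyword), ]
    if (nrow(keywords) == 0) {
      abort_config("keyword input contains no keywords")
    }
  }
  structure(list(raw_text = text, input_type = type, keywords = keywords),
            class = "input_document")
}

#' @export
print.input_document <- function(x, ...) {
  cat(sprintf("<input_document> type=%s, %d characters\n",
              x$input_type, nchar(x$raw_text)))
  if (!is.null(x$keywords)) print(x$keywords)
  invisible(x)
}

as_input_document <- function(x, type = "text") {
  if (inherits(x, "input_document")) return(x)
  input_document(x, type = type)
}
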