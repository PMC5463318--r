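#' Round half away from zero
#'
#' Base `round()` rounds half to even, which turns 0.125 into 0.12. Score
#' display follows the convention that halves round up (0.125 -> 0.13).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# split "a|b|c" -> c("a","b","c"); accepts list-columns already split
split_pipes <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(v) as.character(v[nzchar(v)])))
  }
  lapply(strsplit(ifelse(is.na(x), "", as.character(x)), "|", fixed = TRUE),
         function(v) v[nzchar(v)])
}

join_pipes <- function(x) {
  vapply(x, paste, character(1), collapse = "|")
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

abort_config <- function(msg) stop(msg, call. = FALSE)
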