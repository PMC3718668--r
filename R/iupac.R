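#' IUPAC nucleotide ambiguity codes
#'
#' Base sets for the IUPAC degenerate nucleotide alphabet. Note that the
#' letter \code{N} in a *genome* is unsequenced, not ambiguous: it matches no
#' pattern code, including pattern \code{N} (see [pattern_matches()]).
#'
#' @format Named list mapping each IUPAC symbol to its set of concrete bases.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Expand an IUPAC symbol to its set of concrete bases
#'
#' @param code Single IUPAC symbol, e.g. `"R"`.
#' @return Character vector of concrete bases, e.g. `c("A","G")`.
#' @examples
#' iupac_expand("R")  # A, G
#' @export
iupac_expand <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop("'code' must be a single IUPAC symbol")
  set <- IUPAC_CODES[[toupper(code)]]
  if (is.null(set)) stop("unknown IUPAC symbol: '", code, "'")
  set
}

#' Test a nucleotide window against a degenerate pattern
#'
#' Position-wise comparison of a concrete window with an IUPAC pattern of the
#' same length. A genome `N` in the window never matches (unsequenced bases
#' are not callable).
#'
#' @param window Nucleotide string over `{A,C,G,T,N}`.
#' @param pattern IUPAC degenerate pattern of the same length.
#' @return `TRUE` iff every window base is in the corresponding code's set.
#' @examples
#' pattern_matches("CGTA", "CNNR")  # TRUE
#' pattern_matches("CGTT", "CNNR")  # FALSE (T is not a purine)
#' @export
pattern_matches <- function(window, pattern) {
  if (nchar(window) != nchar(pattern))
    stop("window and pattern lengths differ (", nchar(window), " vs ",
         nchar(pattern), ")")
  wb <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  pb <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  for (i in seq_along(wb)) {
    set <- IUPAC_CODES[[pb[i]]]
    if (is.null(set)) stop("unknown IUPAC symbol: '", pb[i], "'")
    if (!(wb[i] %in% set)) return(FALSE)  # genome N is in no set
  }
  TRUE
}

# complement of an IUPAC string (kept as character; vectorized via chartr)
iupac_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
}

#' Reverse complement of a nucleotide or IUPAC string
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented sequences, same length.
#' @export
revcomp <- function(x) {
  vapply(iupac_complement(x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
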