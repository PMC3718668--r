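#' Load a genome from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file, uppercases
#' soft-masked bases and validates the alphabet. The in-memory genome
#' representation used throughout the package is a named character vector of
#' uppercase chromosome sequences over `{A,C,G,T,N}`; all coordinates are
#' 0-based, half-open, with minus-strand features reported in forward
#' coordinates.
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector of class `mspji_genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  as_genome(g)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return Validated genome (named uppercase character vector,
#'   class `mspji_genome`).
#' @export
as_genome <- function(seqs) {
  if (inherits(seqs, "mspji_genome")) return(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) ||
      anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique non-empty names")
  g <- toupper(unlist(seqs))
  bad <- grepl("[^ACGTN]", g)
  if (any(bad))
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(g)[bad], collapse = ", "))
  structure(g, class = "mspji_genome")
}

#' @export
print.mspji_genome <- function(x, ...) {
  cat("MspJI genome:", length(x), "chromosome(s),",
      format(sum(nchar(x)), big.mark = ","), "bp\n")
  for (nm in utils::head(names(x), 10L))
    cat("  ", nm, ": ", format(nchar(x[[nm]]), big.mark = ","), " bp\n",
        sep = "")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome Genome as accepted by [as_genome()].
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_genome <- function(genome, path, width = 70L) {
  g <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# lengths helper
genome_lengths <- function(genome) nchar(unclass(as_genome(genome)))
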