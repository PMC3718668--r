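#' Quality-control policy for sequenced reads
#'
#' Thresholds follow the strict-inequality reading of the filtering rule:
#' a read is dropped when *more than* 30% of its bases are N, or when
#' *over* 10% of its bases have Phred quality below 20.
#'
#' @param max_n_frac Maximum tolerated N fraction (exclusive bound).
#' @param max_lowq_frac Maximum tolerated low-quality fraction (exclusive).
#' @param lowq_threshold Phred score below which a base counts as
#'   low-quality.
#' @param adapter 3' sequencing adapter to trim (Illumina TruSeq read-1
#'   adapter by default).
#' @param min_overlap Minimum adapter/read overlap for trimming.
#' @return list of class `mspji_qc_policy`.
#' @export
qc_policy <- function(max_n_frac = 0.30, max_lowq_frac = 0.10,
                      lowq_threshold = 20L,
                      adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                      min_overlap = 5L) {
  stopifnot(max_n_frac >= 0, max_n_frac <= 1,
            max_lowq_frac >= 0, max_lowq_frac <= 1)
  structure(list(max_n_frac = max_n_frac, max_lowq_frac = max_lowq_frac,
                 lowq_threshold = as.integer(lowq_threshold),
                 adapter = toupper(adapter),
                 min_overlap = as.integer(min_overlap)),
            class = "mspji_qc_policy")
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip-transparent). Phred+33 qualities assumed.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# Phred scores from a Phred+33 quality string
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Filter reads on N content and base quality
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param policy [qc_policy()].
#' @return `reads` with added logical `keep` and character `reason`
#'   (`""`, `"empty"`, `"n_frac"` or `"lowq_frac"`).
#' @export
filter_reads <- function(reads, policy = qc_policy()) {
  n <- nrow(reads)
  len <- nchar(reads$seq)
  n_frac <- ifelse(len > 0,
                   (len - nchar(gsub("N", "", reads$seq, fixed = TRUE))) /
                     len, 0)
  lowq_frac <- vapply(seq_len(n), function(i) {
    if (len[i] == 0L) return(0)
    mean(phred_scores(reads$qual[i]) < policy$lowq_threshold)
  }, numeric(1L))
  reason <- rep("", n)
  reason[lowq_frac > policy$max_lowq_frac] <- "lowq_frac"
  reason[n_frac > policy$max_n_frac] <- "n_frac"
  reason[len == 0L] <- "empty"
  reads$keep <- reason == ""
  reads$reason <- reason
  reads
}

#' Trim the 3' sequencing adapter from reads
#'
#' Removes the longest exact prefix of the adapter that is anchored at the
#' read's 3' end (minimum overlap `policy$min_overlap`). Reads without a
#' match are returned unchanged and flagged. Trimming never lengthens a
#' read and is idempotent on trimmed output (an insert does not end in the
#' adapter prefix again, except by sequence coincidence).
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param policy [qc_policy()] carrying the adapter.
#' @return `reads` with `seq`/`qual` trimmed and added logical
#'   `adapter_found`.
#' @export
trim_adapter <- function(reads, policy = qc_policy()) {
  adapter <- policy$adapter
  if (!nzchar(adapter)) stop("no adapter configured")
  alen <- nchar(adapter)
  trim_len <- vapply(reads$seq, function(s) {
    L <- nchar(s)
    kmax <- min(L, alen)
    if (kmax < policy$min_overlap) return(0L)
    for (k in seq(kmax, policy$min_overlap)) {
      if (substr(s, L - k + 1L, L) == substr(adapter, 1L, k)) return(k)
    }
    0L
  }, integer(1L), USE.NAMES = FALSE)
  found <- trim_len > 0L
  L <- nchar(reads$seq)
  reads$seq <- substr(reads$seq, 1L, L - trim_len)
  reads$qual <- substr(reads$qual, 1L, L - trim_len)
  reads$adapter_found <- found
  reads
}
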