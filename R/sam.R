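#' Read alignments from SAM or BAM
#'
#' SAM text is parsed directly; BAM goes through Rsamtools. Mapping
#' multiplicity is taken from the `NH` auxiliary tag when present,
#' otherwise from the number of records sharing a read name (both dialects
#' of multi-mapper reporting are supported).
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`, `multiplicity`,
#'   `mapped`, `strand`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read BAM files")
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
      tag = "NH")
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    aln <- data.frame(qname = b$qname, flag = b$flag,
                      chrom = as.character(b$rname), pos = b$pos,
                      mapq = b$mapq, cigar = b$cigar,
                      seq = as.character(b$seq),
                      nh = if (is.null(b$tag$NH)) NA_integer_ else b$tag$NH,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines)) {
      f <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(f)
      if (any(nf < 11L))
        stop("malformed SAM record at line ", which(nf < 11L)[1L],
             " (fewer than 11 fields)")
      get <- function(i) vapply(f, `[[`, character(1L), i)
      nh <- vapply(f, function(x) {
        tag <- grep("^NH:i:", x[-(1:11)], value = TRUE)
        if (length(tag)) as.integer(sub("^NH:i:", "", tag[1L]))
        else NA_integer_
      }, integer(1L))
      aln <- data.frame(qname = get(1L), flag = as.integer(get(2L)),
                        chrom = get(3L), pos = as.integer(get(4L)),
                        mapq = as.integer(get(5L)), cigar = get(6L),
                        seq = get(10L), nh = nh, stringsAsFactors = FALSE)
    } else {
      aln <- data.frame(qname = character(), flag = integer(),
                        chrom = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character(), nh = integer(),
                        stringsAsFactors = FALSE)
    }
  }
  aln$mapped <- bitwAnd(aln$flag, 4L) == 0L
  aln$strand <- ifelse(bitwAnd(aln$flag, 16L) == 16L, "-", "+")
  per_name <- table(aln$qname[aln$mapped])
  fallback <- as.integer(per_name[aln$qname])
  aln$multiplicity <- ifelse(is.na(aln$nh), fallback, aln$nh)
  aln$multiplicity[!aln$mapped] <- 0L
  aln$nh <- NULL
  aln
}

#' Infer insert fragments from alignments
#'
#' Each mapped record of an adapter-trimmed read becomes one candidate
#' insert fragment spanning the aligned reference interval. Unmapped reads
#' are skipped and counted; mapping and unique-mapping rates (mapped /
#' clean and multiplicity-1 / clean reads) are attached as attributes.
#'
#' @param aln Alignments from [read_alignments()].
#' @param genome Reference genome; chromosome names must cover the
#'   alignments.
#' @return data.frame of class-free fragments: `qname`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `length`, `multiplicity`, with
#'   attributes `n_reads`, `n_mapped`, `mapping_rate`, `unique_rate`.
#' @export
infer_fragments <- function(aln, genome) {
  g <- as_genome(genome)
  if (is.null(aln$mapped)) aln$mapped <- bitwAnd(aln$flag, 4L) == 0L
  if (is.null(aln$strand))
    aln$strand <- ifelse(bitwAnd(aln$flag, 16L) == 16L, "-", "+")
  if (is.null(aln$multiplicity)) aln$multiplicity <- 1L
  m <- aln[aln$mapped, , drop = FALSE]
  bad <- setdiff(unique(m$chrom), names(g))
  if (length(bad))
    stop("alignment chromosome(s) absent from reference: ",
         paste(bad, collapse = ", "))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(m$cigar)
  out <- data.frame(qname = m$qname, chrom = m$chrom,
                    start = m$pos - 1L, end = m$pos - 1L + width,
                    strand = m$strand, length = width,
                    multiplicity = m$multiplicity,
                    stringsAsFactors = FALSE)
  n_reads <- length(unique(aln$qname))
  n_mapped <- length(unique(m$qname))
  n_unique <- length(unique(m$qname[m$multiplicity == 1L]))
  attr(out, "n_reads") <- n_reads
  attr(out, "n_mapped") <- n_mapped
  attr(out, "mapping_rate") <- if (n_reads) n_mapped / n_reads else NA_real_
  attr(out, "unique_rate") <- if (n_reads) n_unique / n_reads else NA_real_
  out
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM writer used for simulator truth alignments.
#'
#' @param aln data.frame with `qname`, `flag`, `chrom`, `pos` (1-based),
#'   `cigar`, `seq`; optional `mapq`, `qual`, `multiplicity`.
#' @param genome Genome for the header `@SQ` lines.
#' @param path Output file.
#' @export
write_sam <- function(aln, genome, path) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(g), lens))
  mapq <- if (is.null(aln$mapq)) rep(60L, nrow(aln)) else aln$mapq
  qual <- if (is.null(aln$qual)) rep("*", nrow(aln)) else aln$qual
  mult <- if (is.null(aln$multiplicity)) rep(1L, nrow(aln))
    else aln$multiplicity
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
                 aln$qname, aln$flag, aln$chrom, aln$pos, mapq, aln$cigar,
                 aln$seq, qual, mult)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
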