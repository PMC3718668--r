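#' The seven symmetric two-way cleavage categories
#'
#' Degenerate strings describing the site classes whose paired methylated
#' cytosines release a defined two-way fragment. For each pattern:
#' `c_index` is the 0-based offset of the plus-strand C inside the pattern,
#' `d` the signed offset from that C to the partner C on the minus strand
#' (forward coordinates), and `length` the end-repaired two-way fragment
#' length, which obeys `length == 33 - d`.
#'
#' @format data.frame with columns pattern, c_index, d, length, context.
#' @export
TABLE1_CATEGORIES <- data.frame(
  pattern = c("YNCGNR", "YCHGR", "CHHG", "CYHAG", "CHYAHG",
              "TDDGCHHA", "TDDGNCHHA"),
  c_index = c(2L, 1L, 0L, 0L, 0L, 4L, 5L),
  d       = c(1L, 2L, 3L, 4L, 5L, -1L, -2L),
  length  = c(32L, 31L, 30L, 29L, 28L, 34L, 35L),
  context = c("CG", "CHG", "CHH", "CHH", "CHH", "CHH", "CHH"),
  stringsAsFactors = FALSE
)

# precedence when one locus window satisfies several category strings:
# longest pattern first, then the fixed order below; first match wins.
CATEGORY_PRECEDENCE <- c("TDDGNCHHA", "TDDGCHHA", "CHYAHG", "CYHAG",
                         "YNCGNR", "YCHGR", "CHHG")

#' Scan a genome for a degenerate pattern
#'
#' Finds all (overlapping) matches of an IUPAC pattern. Minus-strand matches
#' are evaluated on the reverse complement and reported by the leftmost
#' forward coordinate of the matched window, so `pos` is always a BED-style
#' 0-based window start. Windows containing genome `N` never match.
#'
#' @param genome Genome ([as_genome()]).
#' @param pattern IUPAC degenerate pattern string.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame with columns `chrom`, `pos` (0-based window start),
#'   `strand`.
#' @export
scan_sites <- function(genome, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  g <- as_genome(genome)
  pat <- Biostrings::DNAString(pattern)
  k <- length(pat)
  out <- vector("list", 2L * length(g))
  j <- 0L
  for (chrom in names(g)) {
    subj <- Biostrings::DNAString(g[[chrom]])
    L <- length(subj)
    starts0 <- .match_starts(pat, subj, g[[chrom]], k)
    j <- j + 1L
    out[[j]] <- if (length(starts0))
      data.frame(chrom = chrom, pos = starts0, strand = "+",
                 stringsAsFactors = FALSE) else NULL
    if (strands == "both") {
      rc <- Biostrings::reverseComplement(subj)
      rcs <- as.character(rc)
      s_rc <- .match_starts(pat, rc, rcs, k)
      j <- j + 1L
      out[[j]] <- if (length(s_rc))
        data.frame(chrom = chrom, pos = L - s_rc - k, strand = "-",
                   stringsAsFactors = FALSE) else NULL
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# 0-based match starts of `pat` in `subj`, excluding windows that touch an N.
# fixed="subject" lets IUPAC codes in the pattern act as base sets while the
# subject stays literal, but pattern N would still match subject N, so
# N-containing windows are filtered out explicitly.
.match_starts <- function(pat, subj, subj_chr, k) {
  m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
  s <- BiocGenerics::start(m) - 1L
  if (!length(s)) return(integer())
  npos <- gregexpr("N", subj_chr, fixed = TRUE)[[1L]]
  if (npos[1L] != -1L) {
    npos0 <- as.integer(npos) - 1L
    hasN <- vapply(s, function(x) any(npos0 >= x & npos0 < x + k),
                   logical(1L))
    s <- s[!hasN]
  }
  s
}

#' Classify the methylation context of a cytosine
#'
#' Plant-standard three-way classification by the two bases 3' of the C on
#' its own strand: CG if the next base is G, else CHG if the base after next
#' is G, else CHH. An `N` (or a chromosome end) among the downstream bases
#' makes the context undefined; it is reported as CHH with
#' `context_flagged = TRUE`.
#'
#' @param genome Genome.
#' @param chrom Chromosome name.
#' @param pos 0-based position of the cytosine (forward coordinates).
#' @param strand `"+"` or `"-"`.
#' @return list with `context` (`"CG"|"CHG"|"CHH"`) and `context_flagged`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  g <- as_genome(genome)
  seq <- g[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  base_at <- function(p) if (p < 0L || p >= nchar(seq)) "N"
    else substr(seq, p + 1L, p + 1L)
  this <- base_at(pos)
  this <- if (strand == "+") this else chartr("ACGTN", "TGCAN", this)
  if (this != "C") stop("base at (", pos, ",", strand, ") is ", this,
                        ", not C")
  step <- if (strand == "+") 1L else -1L
  b1 <- base_at(pos + step)
  b2 <- base_at(pos + 2L * step)
  if (strand == "-") {
    b1 <- chartr("ACGTN", "TGCAN", b1)
    b2 <- chartr("ACGTN", "TGCAN", b2)
  }
  if (b1 == "N" || (b1 != "G" && b2 == "N"))
    return(list(context = "CHH", context_flagged = TRUE))
  if (b1 == "G") list(context = "CG", context_flagged = FALSE)
  else if (b2 == "G") list(context = "CHG", context_flagged = FALSE)
  else list(context = "CHH", context_flagged = FALSE)
}

#' Classify the symmetric two-way category of a CNNR locus
#'
#' Tests the seven category strings anchored so the locus C occupies the
#' category's C position (for a minus-strand locus, the partner-C position of
#' the forward-strand representation). Precedence is longest-pattern-first
#' with a fixed tie order; no match (or a window running past a chromosome
#' end) classifies the locus as `"asymmetric"`.
#'
#' @inheritParams classify_context
#' @return list with `category` (pattern string or `"asymmetric"`) and
#'   `partner_offset_d` (signed; `NA` for asymmetric). For a plus-strand
#'   locus `d = partner C position - this C position` in forward
#'   coordinates; the partner locus classifies to the same category with
#'   `d` of opposite sign.
#' @export
classify_symmetric_category <- function(genome, chrom, pos, strand) {
  g <- as_genome(genome)
  seq <- g[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  L <- nchar(seq)
  for (patname in CATEGORY_PRECEDENCE) {
    row <- TABLE1_CATEGORIES[TABLE1_CATEGORIES$pattern == patname, ]
    anchor <- if (strand == "+") row$c_index else row$c_index + row$d
    start <- pos - anchor
    k <- nchar(patname)
    if (start < 0L || start + k > L) next  # insufficient flank
    win <- substr(seq, start + 1L, start + k)
    if (pattern_matches(win, patname))
      return(list(category = patname,
                  partner_offset_d = if (strand == "+") row$d else -row$d))
  }
  list(category = "asymmetric", partner_offset_d = NA_integer_)
}

#' Scan all CNNR loci of a genome
#'
#' Finds every CNNR occurrence on the requested strand(s) and annotates the
#' position of the C, its methylation context and its symmetric two-way
#' category (with signed partner offset d).
#'
#' @param genome Genome.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame with columns `chrom`, `pos` (0-based C position),
#'   `strand`, `context`, `context_flagged`, `category`,
#'   `partner_offset_d`.
#' @export
scan_cnnr_loci <- function(genome, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  g <- as_genome(genome)
  hits <- scan_sites(g, "CNNR", strands)
  # window start -> C position: plus C at start; minus C at start + 3
  hits$pos <- ifelse(hits$strand == "+", hits$pos, hits$pos + 3L)
  n <- nrow(hits)
  ctx <- character(n); flag <- logical(n)
  cat_ <- character(n); d <- integer(n)
  # per-chromosome vectorized context classification
  for (chrom in unique(hits$chrom)) {
    idx <- which(hits$chrom == chrom)
    seq <- g[[chrom]]
    L <- nchar(seq)
    p <- hits$pos[idx]
    plus <- hits$strand[idx] == "+"
    b1 <- b2 <- rep("N", length(idx))
    q1 <- ifelse(plus, p + 1L, p - 1L); q2 <- ifelse(plus, p + 2L, p - 2L)
    ok1 <- q1 >= 0L & q1 < L; ok2 <- q2 >= 0L & q2 < L
    b1[ok1] <- substring(seq, q1[ok1] + 1L, q1[ok1] + 1L)
    b2[ok2] <- substring(seq, q2[ok2] + 1L, q2[ok2] + 1L)
    b1[!plus] <- chartr("ACGTN", "TGCAN", b1[!plus])
    b2[!plus] <- chartr("ACGTN", "TGCAN", b2[!plus])
    cg <- b1 == "G"
    chg <- !cg & b2 == "G"
    ctx[idx] <- ifelse(cg, "CG", ifelse(chg, "CHG", "CHH"))
    flag[idx] <- b1 == "N" | (!cg & b2 == "N")
  }
  # category maps from forward scans of the seven patterns, precedence order
  cat_[] <- "asymmetric"; d[] <- NA_integer_
  key <- paste(hits$chrom, hits$pos, hits$strand)
  assigned <- logical(n)
  for (patname in CATEGORY_PRECEDENCE) {
    row <- TABLE1_CATEGORIES[TABLE1_CATEGORIES$pattern == patname, ]
    m <- scan_sites(g, patname, "forward")
    if (!nrow(m)) next
    kplus <- paste(m$chrom, m$pos + row$c_index, "+")
    kminus <- paste(m$chrom, m$pos + row$c_index + row$d, "-")
    hit_p <- match(key, kplus)
    sel <- !assigned & !is.na(hit_p)
    cat_[sel] <- patname; d[sel] <- row$d; assigned[sel] <- TRUE
    hit_m <- match(key, kminus)
    sel <- !assigned & !is.na(hit_m)
    cat_[sel] <- patname; d[sel] <- -row$d; assigned[sel] <- TRUE
  }
  out <- data.frame(chrom = hits$chrom, pos = hits$pos,
                    strand = hits$strand, context = ctx,
                    context_flagged = flag, category = cat_,
                    partner_offset_d = d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
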