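# Independent oracles and small fixtures, kept deliberately naive and
# separate from the package's implementation paths.

# 40-bp toy genome with a single symmetric CG site (plus C at 18)
toy_cg_genome <- function() {
  as_genome(c(chr1 = paste0(strrep("A", 16), "TACGTA", strrep("A", 18))))
}

# random genome as plain named character vector
random_genome <- function(len, gc = 0.36, n_chrom = 1L, seed = 1L) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  stats::setNames(vapply(seq_len(n_chrom), function(i)
    paste(sample(names(probs), len, TRUE, probs), collapse = ""),
    character(1L)), paste0("chr", seq_len(n_chrom)))
}

# --- brute-force IUPAC window scanner (own code map, regex-free loop) ----
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), N = c("A", "C", "G", "T"))

oracle_window_match <- function(win, pat) {
  wb <- strsplit(win, "")[[1]]
  pb <- strsplit(pat, "")[[1]]
  if (length(wb) != length(pb)) return(FALSE)
  all(mapply(function(w, p) w %in% oracle_iupac[[p]], wb, pb))
}

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s)
  paste(rev(oracle_comp[strsplit(s, "")[[1]]]), collapse = "")

# forward + reverse matches; minus matches reported by forward window start
oracle_scan <- function(seqs, pat, strands = "both") {
  k <- nchar(pat)
  out <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    if (L < k) next
    for (i in 0:(L - k)) {
      win <- substr(s, i + 1, i + k)
      if (oracle_window_match(win, pat))
        out[[length(out) + 1]] <- data.frame(chrom = chrom, pos = i,
                                             strand = "+")
      if (strands == "both" && oracle_window_match(oracle_revcomp(win),
                                                   pat))
        out[[length(out) + 1]] <- data.frame(chrom = chrom, pos = i,
                                             strand = "-")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$strand), ]
}

# --- brute-force digestion oracle -----------------------------------------
# Model: a two-way fragment is released for every opposite-strand pair of
# methylated loci with geometry E (1 <= d <= 15) or F (d <= -1), spanning
# [minus C - 16, plus C + 17), unless any cut of a third methylated locus
# falls strictly inside that span. Enumerates ALL pairs and scans the full
# cut list (no sweep, no adjacency): an independent route to the same model.
oracle_two_way <- function(seqs, loci) {
  out <- list()
  for (chrom in names(seqs)) {
    L <- nchar(seqs[[chrom]])
    lc <- loci[loci$chrom == chrom, , drop = FALSE]
    plus <- lc$pos[lc$strand == "+"]
    minus <- lc$pos[lc$strand == "-"]
    valid_p <- plus[plus + 17 <= L & plus + 13 >= 0]
    valid_m <- minus[minus - 16 >= 0 & minus - 12 <= L]
    if (!length(valid_p) || !length(valid_m)) next
    cuts <- sort(c(valid_p + 13, valid_p + 17, valid_m - 12, valid_m - 16))
    pairs <- expand.grid(p = valid_p, q = valid_m)
    d <- pairs$q - pairs$p
    pairs <- pairs[d <= 15 & d != 0, , drop = FALSE]
    if (!nrow(pairs)) next
    start <- pairs$q - 16
    end <- pairs$p + 17
    inside <- findInterval(end - 1, cuts) - findInterval(start, cuts)
    # subtract the pair's own interior cuts (near cuts: q-12 and p+13)
    own <- (pairs$q - 12 > start & pairs$q - 12 < end) +
      (pairs$p + 13 > start & pairs$p + 13 < end)
    keep <- (inside - own) == 0
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = start[keep], end = end[keep],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# engine two-way fragments in comparable form
engine_two_way <- function(dig) {
  fr <- dig$fragments
  fr <- fr[fr$scenario %in% c("E", "F"), c("chrom", "start", "end")]
  fr <- fr[order(fr$chrom, fr$start, fr$end), , drop = FALSE]
  rownames(fr) <- NULL
  fr
}

# minimal SAM text for caller tests
make_sam <- function(genome, records) {
  lens <- nchar(unclass(genome))
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), lens),
    records)
}

# concrete instantiations of the seven symmetric categories, chosen so the
# T-flanked core contains exactly the two partner CNNR loci
category_cores <- c(
  YNCGNR = "TACGTA", YCHGR = "TCTGA", CHHG = "CTTG", CYHAG = "CTTAG",
  CHYAHG = "CTTATG", TDDGCHHA = "TTTGCTTA", TDDGNCHHA = "TTTGTCTTA")

embed_core <- function(core, flank = 20L) {
  as_genome(c(chr1 = paste0(strrep("T", flank), core,
                            strrep("T", flank))))
}
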