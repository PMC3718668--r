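#' Notarize CNNR loci inside insert fragments by cut-model geometry
#'
#' Inverts the two-way cleavage geometry: a fragment released by two
#' opposite-strand breaks carries its plus-strand methylated C 17 bases
#' left of the right outer cut (`end - 17`) and its minus-strand methylated
#' C 16 bases right of the left outer cut (`start + 16`). Each candidate is
#' accepted only if the reference carries a CNNR site on that strand at
#' that position (the surrounding reference sequence is consulted, so loci
#' near fragment ends are still classified). With `wobble = 1`, positions
#' one base either side are also tried when the exact offset fails,
#' accommodating the enzyme's occasional one-base cut wobble.
#'
#' @param fragments Fragments from [infer_fragments()] (or the digest
#'   engine's fragment table).
#' @param genome Reference genome.
#' @param wobble `0` (default) or `1`.
#' @return data.frame with one row per accepted locus: `frag_row` (row
#'   index into `fragments`), `chrom`, `pos`, `strand`, `context`,
#'   `category`, `partner_offset_d`, `wobbled`.
#' @export
notarize_cnnr <- function(fragments, genome, wobble = 0L) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  n <- nrow(fragments)
  if (n == 0L)
    return(data.frame(frag_row = integer(), chrom = character(),
                      pos = integer(), strand = character(),
                      context = character(), category = character(),
                      partner_offset_d = integer(), wobbled = logical(),
                      stringsAsFactors = FALSE))
  if (any(fragments$start < 0L) ||
      any(fragments$end > lens[fragments$chrom]))
    stop("fragment outside reference bounds")
  offs <- if (wobble >= 1L) c(0L, -1L, 1L) else 0L
  # candidate (fragment, strand, offset) grid; first accepted offset wins
  cand <- function(strand) {
    base <- if (strand == "+") fragments$end - 17L else fragments$start + 16L
    found <- rep(FALSE, n); pos <- rep(NA_integer_, n)
    wob <- rep(FALSE, n)
    for (o in offs) {
      p <- base + o
      ok <- !found & .is_cnnr(g, fragments$chrom, p, strand)
      pos[ok] <- p[ok]; wob[ok] <- o != 0L; found[ok] <- TRUE
    }
    data.frame(frag_row = seq_len(n), chrom = fragments$chrom, pos = pos,
               strand = strand, wobbled = wob,
               stringsAsFactors = FALSE)[found, , drop = FALSE]
  }
  out <- rbind(cand("+"), cand("-"))
  if (!nrow(out)) {
    out$context <- character(); out$category <- character()
    out$partner_offset_d <- integer()
    return(out[, c("frag_row", "chrom", "pos", "strand", "context",
                   "category", "partner_offset_d", "wobbled")])
  }
  # annotate each distinct locus once, then join back
  key <- paste(out$chrom, out$pos, out$strand)
  u <- !duplicated(key)
  ann <- vapply(which(u), function(i) {
    ctx <- classify_context(g, out$chrom[i], out$pos[i], out$strand[i])
    cat_ <- classify_symmetric_category(g, out$chrom[i], out$pos[i],
                                        out$strand[i])
    c(ctx$context, cat_$category, as.character(cat_$partner_offset_d))
  }, character(3L))
  j <- match(key, key[u])
  out$context <- ann[1L, j]
  out$category <- ann[2L, j]
  out$partner_offset_d <- suppressWarnings(as.integer(ann[3L, j]))
  out <- out[order(out$frag_row, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("frag_row", "chrom", "pos", "strand", "context", "category",
          "partner_offset_d", "wobbled")]
}

# vectorized: is there a CNNR site (C on `strand` at pos, purine 3 bases 3')?
# a minus-strand CNNR at pos p reads YNNG on the forward window [p-3, p].
.is_cnnr <- function(g, chrom, pos, strand) {
  lens <- genome_lengths(g)
  n <- length(pos)
  plus <- rep_len(strand == "+", n)
  ok <- rep(FALSE, n)
  lo <- ifelse(plus, pos, pos - 3L)
  inb <- !is.na(pos) & lo >= 0L & lo + 4L <= lens[chrom]
  if (!any(inb)) return(ok)
  win <- rep(NA_character_, n)
  win[inb] <- substring(unclass(g)[chrom[inb]], lo[inb] + 1L, lo[inb] + 4L)
  pat <- ifelse(plus, "^C[ACGT][ACGT][AG]$", "^[CT][ACGT][ACGT]G$")
  ok[inb] <- mapply(grepl, pat[inb], win[inb], USE.NAMES = FALSE)
  ok
}

#' Call methylated sites from insert fragments
#'
#' Aggregates notarized loci over fragments; the depth (number of
#' supporting fragments) is the absolute methylation level of the
#' cytosine. A two-way fragment supports both of its loci. Duplicate
#' fragments are not removed: depth is the methylation signal.
#'
#' @param fragments Fragments from [infer_fragments()].
#' @param genome Reference genome.
#' @param unique_only Exclude fragments with multiplicity > 1 (default
#'   `TRUE`, matching the use of uniquely mapped reads downstream).
#' @param wobble Passed to [notarize_cnnr()].
#' @return data.frame with `chrom`, `pos`, `strand`, `context`,
#'   `category`, `partner_offset_d`, `depth`, `unique_only`.
#' @export
call_sites <- function(fragments, genome, unique_only = TRUE,
                       wobble = 0L) {
  fr <- fragments
  if (unique_only && nrow(fr) && !is.null(fr$multiplicity))
    fr <- fr[fr$multiplicity <= 1L, , drop = FALSE]
  loci <- notarize_cnnr(fr, genome, wobble = wobble)
  if (!nrow(loci))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      category = character(),
                      partner_offset_d = integer(), depth = integer(),
                      unique_only = logical(), stringsAsFactors = FALSE))
  key <- paste(loci$chrom, loci$pos, loci$strand)
  agg <- loci[!duplicated(key), c("chrom", "pos", "strand", "context",
                                  "category", "partner_offset_d")]
  agg$depth <- as.integer(table(key)[paste(agg$chrom, agg$pos,
                                           agg$strand)])
  agg$unique_only <- unique_only
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Resampled per-region read counts for multi-mapped reads
#'
#' Each multi-mapped read is assigned to one of its reported positions
#' uniformly at random; per-region counts are tallied and the mean over
#' `n_resample` draws is reported. A fragment is attributed to the first
#' listed region containing its midpoint; fragments in no region count as
#' `"unassigned"`, so the per-region means sum exactly to the number of
#' reads.
#'
#' @param fragments Fragments (possibly several rows per `qname` for
#'   multi-mappers).
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `name` (region class).
#' @param n_resample Number of resampling draws (1000 in the original
#'   procedure).
#' @param seed Optional RNG seed.
#' @return Named numeric vector of mean counts per region name plus
#'   `"unassigned"`.
#' @export
annotate_multimappers <- function(fragments, regions, n_resample = 1000L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(fragments) == 0L)
    return(stats::setNames(numeric(length(unique(regions$name)) + 1L),
                           c(unique(regions$name), "unassigned")))
  if (anyNA(fragments$qname) || any(!nzchar(fragments$qname)))
    stop("fragments must carry read names")
  # region label per fragment row (midpoint containment, first region wins)
  mid <- floor((fragments$start + fragments$end) / 2)
  gr_f <- GenomicRanges::GRanges(fragments$chrom,
                                 IRanges::IRanges(mid + 1L, mid + 1L))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  ov <- GenomicRanges::findOverlaps(gr_f, gr_r, select = "first")
  lab <- ifelse(is.na(ov), "unassigned", regions$name[ov])
  classes <- c(unique(regions$name), "unassigned")
  split_rows <- split(seq_len(nrow(fragments)), fragments$qname)
  if (any(lengths(split_rows) == 0L)) stop("empty position list")
  counts <- matrix(0, nrow = n_resample, ncol = length(classes),
                   dimnames = list(NULL, classes))
  uniq_rows <- unlist(split_rows[lengths(split_rows) == 1L],
                      use.names = FALSE)
  base_tab <- table(factor(lab[uniq_rows], levels = classes))
  multi <- split_rows[lengths(split_rows) > 1L]
  for (r in seq_len(n_resample)) {
    picked <- vapply(multi, function(rows)
      rows[sample.int(length(rows), 1L)], integer(1L))
    tab <- table(factor(lab[picked], levels = classes))
    counts[r, ] <- as.numeric(base_tab + tab)
  }
  colMeans(counts)
}

#' Per-region read density and methylated-site fraction
#'
#' Computes the two region-level ("relative") methylation measures: the
#' read density (total supporting-fragment depth of called loci in the
#' interval) and the mc_fraction (distinct called loci over distinct CNNR
#' loci in the interval). Intervals with no CNNR locus report
#' `mc_fraction = 0` with `zero_denominator = TRUE`.
#'
#' @param site_calls Calls from [call_sites()].
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); see [make_tiles()] for genome tilings.
#' @param genome Reference genome (for the CNNR denominator).
#' @param cnnr_loci Optional precomputed [scan_cnnr_loci()] table.
#' @return `intervals` with added `read_density`, `n_called`, `n_cnnr`,
#'   `mc_fraction`, `zero_denominator`.
#' @export
region_methylation <- function(site_calls, intervals, genome,
                               cnnr_loci = NULL) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  iv <- intervals
  clip <- iv$end > lens[iv$chrom] | iv$start < 0L
  if (any(clip)) {
    warning(sum(clip), " interval(s) beyond chromosome bounds were clipped")
    iv$start <- pmax(iv$start, 0L)
    iv$end <- pmin(iv$end, lens[iv$chrom])
  }
  if (is.null(cnnr_loci)) cnnr_loci <- scan_cnnr_loci(g, "both")
  iv$read_density <- 0; iv$n_called <- 0L; iv$n_cnnr <- 0L
  for (chrom in unique(iv$chrom)) {
    sel <- which(iv$chrom == chrom)
    cl <- site_calls[site_calls$chrom == chrom, , drop = FALSE]
    cl <- cl[order(cl$pos), , drop = FALSE]
    ap <- sort(cnnr_loci$pos[cnnr_loci$chrom == chrom])
    s <- iv$start[sel]; e <- iv$end[sel]
    iv$n_cnnr[sel] <- findInterval(e - 1L, ap) - findInterval(s - 1L, ap)
    if (nrow(cl)) {
      iv$n_called[sel] <- findInterval(e - 1L, cl$pos) -
        findInterval(s - 1L, cl$pos)
      cum <- c(0, cumsum(cl$depth))  # cum[i+1] = depth of first i loci
      iv$read_density[sel] <- cum[findInterval(e - 1L, cl$pos) + 1L] -
        cum[findInterval(s - 1L, cl$pos) + 1L]
    }
  }
  iv$zero_denominator <- iv$n_cnnr == 0L
  iv$mc_fraction <- ifelse(iv$zero_denominator, 0,
                           iv$n_called / pmax(iv$n_cnnr, 1L))
  iv
}

#' Tile a genome into fixed-width intervals
#'
#' @param genome Genome.
#' @param width Tile width in bp (e.g. 50 for fine-grained comparison,
#'   1e5 for chromosome-scale density tracks).
#' @return data.frame with `chrom`, `start`, `end` (last tile clipped).
#' @export
make_tiles <- function(genome, width) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  do.call(rbind, lapply(names(g), function(chrom) {
    s <- seq(0L, lens[[chrom]] - 1L, by = width)
    data.frame(chrom = chrom, start = s,
               end = pmin(s + width, lens[[chrom]]),
               stringsAsFactors = FALSE)
  }))
}

#' Insert-length spectrum
#'
#' @param fragments Fragment data.frame with `length`.
#' @param range Lengths reported individually (others binned as
#'   `"other"`); default `26:39`, the observed insert range.
#' @return Named integer vector of counts.
#' @export
fragment_length_spectrum <- function(fragments, range = 26:39) {
  counts <- stats::setNames(integer(length(range) + 1L),
                            c(as.character(range), "other"))
  if (!nrow(fragments)) return(counts)
  tab <- table(fragments$length)
  inr <- names(tab) %in% as.character(range)
  counts[names(tab)[inr]] <- as.integer(tab[inr])
  counts["other"] <- sum(as.integer(tab[!inr]))
  counts
}

#' Per-position base-frequency matrix of insert fragments
#'
#' Samples up to `n_sample` fragments of one length and tabulates A/C/G/T
#' frequencies per position of the reference plus-strand insert sequence
#' (the matrix behind a sequence logo; rendering is out of scope). For
#' two-way fragments of a symmetric CG site the signature is the central
#' CG dinucleotide (0-based positions 15-16 of a 32-mer).
#'
#' @param fragments Fragments of mixed lengths.
#' @param genome Reference genome.
#' @param length Insert length to profile.
#' @param n_sample Maximum fragments sampled (all used when fewer).
#' @param seed Optional RNG seed.
#' @return 4 x length numeric matrix, rows A, C, G, T.
#' @export
position_frequency_matrix <- function(fragments, genome, length,
                                      n_sample = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_genome(genome)
  fr <- fragments[fragments$length == length, , drop = FALSE]
  if (!nrow(fr)) stop("no fragments of length ", length)
  if (nrow(fr) > n_sample)
    fr <- fr[sample.int(nrow(fr), n_sample), , drop = FALSE]
  seqs <- substring(unclass(g)[fr$chrom], fr$start + 1L, fr$end)
  mat <- matrix(0, nrow = 4L, ncol = length,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (b in rownames(mat)) mat[b, ] <- colMeans(chars == b)
  mat
}
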