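#' MspJI cut pair for a methylated cytosine
#'
#' MspJI introduces a double-strand break at fixed distances 3' of the
#' methylated C: after the 12th nucleotide on the mC strand and after the
#' 16th on the opposite strand, leaving a four-base 5' overhang. Cut
#' coordinates are between-base forward coordinates in `[0, chrom_length]`.
#'
#' @param pos 0-based position of the methylated C (forward coordinates).
#' @param strand `"+"` or `"-"`.
#' @param chrom_length Chromosome length in bases.
#' @return list with `near_cut` (mC strand), `far_cut` (opposite strand),
#'   `overhang = 4` and `valid` (`FALSE` when a cut would fall outside the
#'   chromosome, in which case no break is made).
#' @export
cut_pair <- function(pos, strand, chrom_length) {
  if (strand == "+") {
    near <- pos + 13L; far <- pos + 17L
  } else {
    near <- pos - 12L; far <- pos - 16L
  }
  valid <- min(near, far) >= 0L && max(near, far) <= chrom_length
  list(near_cut = near, far_cut = far, overhang = 4L, valid = valid)
}

#' Cleavage scenario for two neighbouring methylated loci
#'
#' The six scenarios are determined by the strands of the two nearest
#' methylated CNNR loci and the distance between their C positions:
#' same strand at >= 12 bp gives two independent cleavages (A), closer
#' same-strand sites compete and leave only a cut terminus (B); opposite
#' strands cutting toward each other give a siteless middle fragment when
#' the minus-to-plus C offset d >= 29 (C), competing cleavage for
#' d in 16..28 (D) and a two-way fragment carrying both sites for
#' d in 1..15 (E); opposite strands cutting away from each other
#' (d <= -1) release a two-way fragment of >= 34 bp (F).
#'
#' @param posA,strandA,posB,strandB Positions (0-based C coordinates) and
#'   strands of the two loci (same chromosome).
#' @return Scenario letter `"A".."F"`.
#' @export
resolve_scenario <- function(posA, strandA, posB, strandB) {
  if (posA == posB && strandA == strandB)
    stop("the same locus was passed twice")
  if (strandA == strandB) {
    if (abs(posB - posA) >= 12L) "A" else "B"
  } else {
    plus <- if (strandA == "+") posA else posB
    minus <- if (strandA == "-") posA else posB
    d <- minus - plus
    if (d <= -1L) "F"
    else if (d <= 15L) "E"
    else if (d <= 28L) "D"
    else "C"
  }
}

#' Expected two-way fragment length from the partner offset
#'
#' For a symmetric pair with signed partner offset `d` (minus-strand C
#' position minus plus-strand C position), the end-repaired two-way fragment
#' spans from 16 bases left of the minus C to 17 bases right of the plus C,
#' hence `length = 33 - d`.
#'
#' @param d Signed partner offset, in `{-2,...,-1, 1,...,15}`.
#' @return Fragment length in bp.
#' @export
expected_fragment_length <- function(d) {
  if (any(d == 0L))
    stop("d = 0 is impossible: a C cannot base-pair with a C")
  if (any(d < -2L | d > 15L))
    stop("d must be in [-2, 15]")
  33L - as.integer(d)
}

#' Construct a methylation state
#'
#' @param mode `"all_cnnr"` (every CNNR cytosine methylated) or
#'   `"explicit"`.
#' @param loci For explicit mode, data.frame with `chrom`, `pos`, `strand`
#'   of methylated cytosines; each must be a CNNR locus.
#' @return list of class `mspji_state`.
#' @export
methylation_state <- function(mode = c("all_cnnr", "explicit"),
                              loci = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(loci)) loci <- data.frame(chrom = character(),
                                          pos = integer(),
                                          strand = character())
    stopifnot(all(c("chrom", "pos", "strand") %in% names(loci)))
  }
  structure(list(mode = mode, loci = loci), class = "mspji_state")
}

# methylated loci (annotated) for a genome + state; errors if an explicit
# position is not a CNNR locus (digestion requires recognition)
methylated_loci <- function(genome, state) {
  all_loci <- scan_cnnr_loci(genome, "both")
  if (state$mode == "all_cnnr") return(all_loci)
  key_all <- paste(all_loci$chrom, all_loci$pos, all_loci$strand)
  key_st <- paste(state$loci$chrom, state$loci$pos, state$loci$strand)
  hit <- match(key_st, key_all)
  if (anyNA(hit))
    stop(sum(is.na(hit)), " explicit methylated position(s) are not CNNR ",
         "loci, e.g. ", key_st[which(is.na(hit))[1L]])
  out <- all_loci[sort(unique(hit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a genome with MspJI under a methylation state
#'
#' Runs the cleavage-scenario engine: every methylated CNNR locus whose N12
#' and N16 cuts fall inside the chromosome makes a double-strand break
#' (DSB); breaks are sorted along the chromosome and each adjacent pair is
#' resolved to a scenario. Scenarios A, C, E and F emit the end-repaired
#' fragment between the two breaks (outer span, `[min cut of left DSB,
#' max cut of right DSB)`), unless a cut of a third methylated locus falls
#' strictly inside that span, in which case the product is destroyed and
#' suppressed. Competing pairs (B, D) emit no fragment, only a terminus
#' record. Pieces flanked by a chromosome end on one side are not enzyme
#' products of two cuts and are not reported.
#'
#' @param genome Genome.
#' @param state [methylation_state()] (default: all CNNR loci methylated).
#' @return list of class `mspji_digest` with `fragments` (chrom, start,
#'   end, length, scenario, category, the bounding loci, and the count of
#'   methylated loci inside), `termini` (competing-pair records) and
#'   `loci` (the methylated loci with a `cut_valid` flag).
#' @export
digest_genome <- function(genome, state = methylation_state("all_cnnr")) {
  g <- as_genome(genome)
  loci <- methylated_loci(g, state)
  lens <- genome_lengths(g)
  plus <- loci$strand == "+"
  near <- ifelse(plus, loci$pos + 13L, loci$pos - 12L)
  far <- ifelse(plus, loci$pos + 17L, loci$pos - 16L)
  cmin <- pmin(near, far); cmax <- pmax(near, far)
  L <- lens[loci$chrom]
  loci$cut_valid <- cmin >= 0L & cmax <= L

  frag_list <- list(); term_list <- list(); fi <- 0L; ti <- 0L
  for (chrom in names(g)) {
    idx <- which(loci$chrom == chrom & loci$cut_valid)
    if (length(idx) < 2L) next
    d <- data.frame(pos = loci$pos[idx], strand = loci$strand[idx],
                    category = loci$category[idx],
                    pd = loci$partner_offset_d[idx],
                    cmin = cmin[idx], cmax = cmax[idx],
                    stringsAsFactors = FALSE)
    d <- d[order(d$cmin, d$cmax, d$strand, d$pos), , drop = FALSE]
    n <- nrow(d)
    cuts <- sort(c(d$cmin, d$cmax))
    a <- seq_len(n - 1L); b <- a + 1L
    # vectorized scenario classification of adjacent DSB pairs
    same <- d$strand[a] == d$strand[b]
    ppos <- ifelse(d$strand[a] == "+", d$pos[a], d$pos[b])
    mpos <- ifelse(d$strand[a] == "-", d$pos[a], d$pos[b])
    dd <- mpos - ppos
    scen <- ifelse(same, ifelse(abs(d$pos[b] - d$pos[a]) >= 12L, "A", "B"),
                   ifelse(dd <= -1L, "F",
                          ifelse(dd <= 15L, "E",
                                 ifelse(dd <= 28L, "D", "C"))))
    start <- d$cmin[a]; end <- d$cmax[b]
    # suppress products with a foreign cut strictly inside (start, end)
    n_in <- findInterval(end - 1L, cuts) - findInterval(start, cuts)
    own <- (d$cmax[a] > start & d$cmax[a] < end) +
           (d$cmin[b] > start & d$cmin[b] < end)
    clean <- (n_in - own) == 0L
    emit <- scen %in% c("A", "C", "E", "F") & clean & (end - start) >= 1L
    # category carried only by a true symmetric partner pair
    partnered <- !same & !is.na(d$pd[a]) & !is.na(d$pd[b]) &
      d$category[a] == d$category[b] &
      d$pos[a] + d$pd[a] == d$pos[b] & d$pos[b] + d$pd[b] == d$pos[a]
    categ <- ifelse(scen %in% c("E", "F") & partnered,
                    d$category[a], NA_character_)
    if (any(emit)) {
      sp <- sort(loci$pos[loci$chrom == chrom])
      n_loci <- findInterval(end[emit] - 1L, sp) -
        findInterval(start[emit] - 1L, sp)
      fi <- fi + 1L
      frag_list[[fi]] <- data.frame(
        chrom = chrom, start = start[emit], end = end[emit],
        length = (end - start)[emit], scenario = scen[emit],
        category = categ[emit],
        locusA_pos = d$pos[a][emit], locusA_strand = d$strand[a][emit],
        locusB_pos = d$pos[b][emit], locusB_strand = d$strand[b][emit],
        n_loci_inside = n_loci, stringsAsFactors = FALSE)
    }
    comp <- scen %in% c("B", "D")
    if (any(comp)) {
      ti <- ti + 1L
      term_list[[ti]] <- data.frame(
        chrom = chrom, scenario = scen[comp],
        locusA_pos = d$pos[a][comp], locusA_strand = d$strand[a][comp],
        locusB_pos = d$pos[b][comp], locusB_strand = d$strand[b][comp],
        stringsAsFactors = FALSE)
    }
  }
  empty_f <- data.frame(chrom = character(), start = integer(),
                        end = integer(), length = integer(),
                        scenario = character(), category = character(),
                        locusA_pos = integer(), locusA_strand = character(),
                        locusB_pos = integer(), locusB_strand = character(),
                        n_loci_inside = integer(), stringsAsFactors = FALSE)
  empty_t <- data.frame(chrom = character(), scenario = character(),
                        locusA_pos = integer(), locusA_strand = character(),
                        locusB_pos = integer(), locusB_strand = character(),
                        stringsAsFactors = FALSE)
  fragments <- if (fi) do.call(rbind, frag_list) else empty_f
  termini <- if (ti) do.call(rbind, term_list) else empty_t
  rownames(fragments) <- NULL; rownames(termini) <- NULL
  structure(list(fragments = fragments, termini = termini, loci = loci),
            class = "mspji_digest")
}

#' @export
print.mspji_digest <- function(x, ...) {
  cat("MspJI in silico digest:", nrow(x$loci), "methylated loci,",
      nrow(x$fragments), "fragments,", nrow(x$termini),
      "competing-cleavage termini\n")
  if (nrow(x$fragments)) {
    tab <- table(x$fragments$scenario)
    cat("  scenarios:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Size-select fragments
#'
#' Keeps fragments whose length lies in the (inclusive) selection window,
#' emulating gel band excision.
#'
#' @param fragments Fragment data.frame (or an `mspji_digest`).
#' @param min_len,max_len Inclusive bounds; defaults 28 and 35 bp.
#' @return Filtered fragment data.frame.
#' @export
size_select <- function(fragments, min_len = 28L, max_len = 35L) {
  if (inherits(fragments, "mspji_digest")) fragments <- fragments$fragments
  stopifnot(min_len <= max_len)
  out <- fragments[fragments$length >= min_len &
                     fragments$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of recoverable cytosines under the all-methylated assumption
#'
#' Counts forward-strand matches of each of the seven symmetric two-way
#' category strings (each match is one symmetric locus carrying two
#' cytosines), the total genomic cytosines (C on either strand, i.e. C plus
#' G on the forward strand) and the generation rate: the fraction of all
#' cytosines recoverable in the size-selected two-way band if every CNNR
#' cytosine were methylated.
#'
#' @param genome Genome.
#' @return list of class `mspji_census`: `categories` (pattern, fragment
#'   length, d, count), `cytosines_in_sites`, `total_cytosines`,
#'   `generation_rate`.
#' @export
census <- function(genome) {
  g <- as_genome(genome)
  cats <- TABLE1_CATEGORIES
  cats$count <- vapply(cats$pattern, function(p)
    nrow(scan_sites(g, p, "forward")), integer(1L))
  seqs <- unclass(g)
  nC <- sum(vapply(seqs, function(s)
    nchar(s) - nchar(gsub("C", "", s, fixed = TRUE)), numeric(1L)))
  nG <- sum(vapply(seqs, function(s)
    nchar(s) - nchar(gsub("G", "", s, fixed = TRUE)), numeric(1L)))
  total <- nC + nG
  in_sites <- 2 * sum(cats$count)
  structure(list(categories = cats[, c("pattern", "length", "d", "count")],
                 cytosines_in_sites = in_sites,
                 total_cytosines = total,
                 generation_rate = if (total > 0) in_sites / total else 0),
            class = "mspji_census")
}

#' @export
print.mspji_census <- function(x, ...) {
  cat("MspJI two-way cleavage census\n")
  print(x$categories, row.names = FALSE)
  cat("cytosines in sites:", x$cytosines_in_sites,
      "of", x$total_cytosines, sprintf("(generation rate %.2f%%)\n",
                                       100 * x$generation_rate))
  invisible(x)
}

#' Fraction of cytosines in CNNR context
#'
#' Both-strand CNNR loci over both-strand cytosines. Under an i.i.d. base
#' model this is close to 1/2 (the probability that the base three
#' positions 3' of a C is a purine).
#'
#' @param genome Genome.
#' @return Numeric fraction in `[0, 1]`.
#' @export
cnnr_fraction <- function(genome) {
  g <- as_genome(genome)
  n_loci <- nrow(scan_sites(g, "CNNR", "both"))
  seqs <- unclass(g)
  total <- sum(vapply(seqs, function(s)
    2 * nchar(s) - nchar(gsub("C", "", s, fixed = TRUE)) -
      nchar(gsub("G", "", s, fixed = TRUE)), numeric(1L)))
  if (total == 0) {
    warning("genome contains no cytosines; reporting 0")
    return(0)
  }
  n_loci / total
}

#' Mappability of short fragments by exact occurrence counting
#'
#' Samples random substrings of each length and asks whether they map back
#' to the genome totally (the substring occurs; true by construction unless
#' it contains N, and N-containing draws are excluded from both numerator
#' and denominator) and uniquely (the set of genomic windows hit by the
#' substring or its reverse complement has size one). This approximates an
#' aligner-based re-mapping simulation with exact matching.
#'
#' @param genome Genome.
#' @param lengths Fragment lengths to sample; default `28:35`.
#' @param n Draws per length.
#' @param seed Optional RNG seed.
#' @return list with `per_length` data.frame (length, n_used, total_frac,
#'   unique_frac) and overall `total_fraction`, `unique_fraction`.
#' @export
simulate_fragment_mappability <- function(genome, lengths = 28:35,
                                          n = 1000L, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  subj <- Biostrings::DNAStringSet(unclass(g))
  rows <- list(); tot_used <- 0L; tot_total <- 0; tot_unique <- 0
  for (len in lengths) {
    avail <- pmax(lens - len + 1L, 0L)
    if (sum(avail) == 0L) {
      warning("length ", len, " exceeds every chromosome; skipped")
      next
    }
    chrom <- sample(names(g), n, replace = TRUE, prob = avail)
    start <- vapply(chrom, function(cn) sample.int(avail[[cn]], 1L),
                    integer(1L))
    s <- unname(substring(unclass(g)[chrom], start, start + len - 1L))
    s <- s[!grepl("N", s, fixed = TRUE)]
    if (!length(s)) next
    fwd <- Biostrings::DNAStringSet(s)
    rc <- Biostrings::reverseComplement(fwd)
    cf <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(fwd), subj))
    cr <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), subj))
    palin <- as.character(fwd) == as.character(rc)
    hits <- ifelse(palin, cf, cf + cr)  # distinct genomic windows
    rows[[length(rows) + 1L]] <- data.frame(
      length = len, n_used = length(s),
      total_frac = mean(hits >= 1L), unique_frac = mean(hits == 1L))
    tot_used <- tot_used + length(s)
    tot_total <- tot_total + sum(hits >= 1L)
    tot_unique <- tot_unique + sum(hits == 1L)
  }
  per_length <- if (length(rows)) do.call(rbind, rows) else
    data.frame(length = integer(), n_used = integer(),
               total_frac = numeric(), unique_frac = numeric())
  list(per_length = per_length,
       total_fraction = if (tot_used) tot_total / tot_used else NA_real_,
       unique_fraction = if (tot_used) tot_unique / tot_used else NA_real_)
}
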