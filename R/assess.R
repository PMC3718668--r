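#' Call methylated sites from bisulfite-style per-site counts
#'
#' For each covered site, a one-sided binomial test of the methylated read
#' count against the bisulfite non-conversion/sequencing error rate, with
#' Benjamini-Hochberg correction across tested sites (the Lister-style
#' procedure). `mode = "any_read"` instead calls every site covered by at
#' least one methylation-supporting read, the looser rule used when
#' comparing against enrichment data.
#'
#' @param records data.frame with `chrom`, `pos`, `strand`,
#'   `methylated_reads`, `total_reads`.
#' @param error_rate Null methylation probability per read (default 0.01).
#' @param fdr BH false-discovery threshold (default 0.05).
#' @param mode `"binomial"` or `"any_read"`.
#' @return `records` with added `p`, `padj`, `tested`, `called`.
#' @export
wgbs_call <- function(records, error_rate = 0.01, fdr = 0.05,
                      mode = c("binomial", "any_read")) {
  mode <- match.arg(mode)
  stopifnot(error_rate > 0, error_rate < 1,
            all(records$methylated_reads >= 0),
            all(records$methylated_reads <= records$total_reads))
  r <- records
  r$tested <- r$total_reads > 0L
  r$p <- NA_real_
  r$p[r$tested] <- stats::pbinom(r$methylated_reads[r$tested] - 1L,
                                 r$total_reads[r$tested], error_rate,
                                 lower.tail = FALSE)
  r$padj <- NA_real_
  r$padj[r$tested] <- stats::p.adjust(r$p[r$tested], method = "BH")
  if (mode == "binomial") {
    r$called <- r$tested & r$padj <= fdr & r$methylated_reads >= 1L
  } else {
    r$called <- r$tested & r$methylated_reads >= 1L
  }
  r$called[is.na(r$called)] <- FALSE
  r
}

#' Genome-wide uniqueness of the two-way insert around a symmetric CG locus
#'
#' Extracts the 32-bp end-repaired insert encompassing a symmetric CGNR
#' locus and reports whether the set of genomic windows matched by that
#' insert or its reverse complement has size one. Loci whose insert would
#' run past a chromosome end are flagged and reported non-unique.
#'
#' @param genome Genome.
#' @param loci data.frame with `chrom`, `pos`, `strand` of symmetric CG
#'   loci (plus-strand C at `pos` pairs with the minus-strand C at
#'   `pos + 1`).
#' @param length Insert length (default 32).
#' @return Logical vector: unique in the genome.
#' @export
fragment_uniqueness <- function(genome, loci, length = 32L) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  subj <- Biostrings::DNAStringSet(unclass(g))
  # plus-strand C at p: insert [p - 15, p + 17); minus-strand locus at m
  # shares the window of its partner at m - 1
  p <- ifelse(loci$strand == "+", loci$pos, loci$pos - 1L)
  lo <- p - 15L
  inb <- lo >= 0L & lo + length <= lens[loci$chrom]
  out <- rep(FALSE, nrow(loci))
  if (!any(inb)) return(out)
  s <- unname(substring(unclass(g)[loci$chrom[inb]], lo[inb] + 1L,
                        lo[inb] + length))
  okN <- !grepl("N", s, fixed = TRUE)
  idx <- which(inb)[okN]
  if (!length(idx)) return(out)
  fwd <- Biostrings::DNAStringSet(s[okN])
  rc <- Biostrings::reverseComplement(fwd)
  cf <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(fwd), subj))
  cr <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), subj))
  palin <- as.character(fwd) == as.character(rc)
  out[idx] <- ifelse(palin, cf, cf + cr) == 1L
  out
}

# restrict a call table (chrom,pos,strand) to peak intervals
.in_peaks <- function(calls, peaks) {
  if (!nrow(calls)) return(calls)
  gr_c <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L,
                                                  calls$pos + 1L))
  gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L,
                                                  peaks$end))
  hit <- IRanges::overlapsAny(gr_c, gr_p)
  calls[hit, , drop = FALSE]
}

#' Specificity and sensitivity of enrichment calls against bisulfite calls
#'
#' Both call sets are restricted to peak intervals and (optionally) to loci
#' whose 32-bp two-way insert is unique in the genome; then
#' `specificity = |shared| / |enrichment-called|` and
#' `sensitivity = |shared| / |bisulfite-called|`. Swapping the two call
#' sets exchanges the two numbers.
#'
#' @param mspji_calls,wgbs_calls data.frames with `chrom`, `pos`,
#'   `strand`.
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome Optional genome; when supplied, both sets are restricted
#'   to unique 32-bp loci.
#' @return list with `specificity`, `sensitivity`, `n_shared`, `n_mspji`,
#'   `n_wgbs`.
#' @export
specificity_sensitivity <- function(mspji_calls, wgbs_calls, peaks,
                                    genome = NULL) {
  a <- .in_peaks(mspji_calls, peaks)
  b <- .in_peaks(wgbs_calls, peaks)
  if (!is.null(genome)) {
    if (nrow(a)) a <- a[fragment_uniqueness(genome, a), , drop = FALSE]
    if (nrow(b)) b <- b[fragment_uniqueness(genome, b), , drop = FALSE]
  }
  ka <- paste(a$chrom, a$pos, a$strand)
  kb <- paste(b$chrom, b$pos, b$strand)
  shared <- length(intersect(ka, kb))
  spec <- if (length(ka)) shared / length(ka) else {
    warning("no enrichment calls in peaks; specificity undefined")
    NA_real_
  }
  sens <- if (length(kb)) shared / length(kb) else NA_real_
  list(specificity = spec, sensitivity = sens, n_shared = shared,
       n_mspji = length(ka), n_wgbs = length(kb))
}

#' Replicate agreement over peak regions
#'
#' Per peak, computes a per-replicate statistic (number of called loci, or
#' summed/mean depth of called loci) and returns the Pearson correlation
#' between replicates.
#'
#' @param calls_rep1,calls_rep2 Call tables from [call_sites()].
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param statistic `"site_count"`, `"depth_sum"` or `"depth_mean"`.
#' @return Pearson correlation coefficient (NA with a warning when a
#'   replicate has zero variance across peaks).
#' @export
replicate_correlation <- function(calls_rep1, calls_rep2, peaks,
                                  statistic = c("site_count", "depth_sum",
                                                "depth_mean")) {
  statistic <- match.arg(statistic)
  if (nrow(peaks) < 3L) stop("at least 3 peaks required")
  stat_fun <- function(calls) {
    vapply(seq_len(nrow(peaks)), function(i) {
      sel <- calls$chrom == peaks$chrom[i] &
        calls$pos >= peaks$start[i] & calls$pos < peaks$end[i]
      switch(statistic,
             site_count = sum(sel),
             depth_sum = sum(calls$depth[sel]),
             depth_mean = if (any(sel)) mean(calls$depth[sel]) else 0)
    }, numeric(1L))
  }
  x <- stat_fun(calls_rep1); y <- stat_fun(calls_rep2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance across peaks; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Metagene methylation profile
#'
#' Scales each region to 20 equal body bins (minus-strand regions reversed
#' so bin 1 is the 5' end) and adds 1-kb flanks in 100-bp bins; per-bin
#' relative methylation (called loci over CNNR loci, or read density) is
#' averaged across regions. Flank bins falling outside a chromosome are
#' dropped from the average for that region.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `strand`.
#' @param site_calls Calls from [call_sites()] (optionally pre-filtered to
#'   one context).
#' @param genome Genome.
#' @param what `"mc_fraction"` or `"read_density"`.
#' @param bins Number of body bins (20).
#' @param flank Flank width in bp (1000).
#' @param flank_bin Flank bin width in bp (100).
#' @param cnnr_loci Optional precomputed [scan_cnnr_loci()] table.
#' @return data.frame with `bin` (`u1..u10`, `b1..b20`, `d1..d10`),
#'   `position` (ordinal) and `value` (cross-region mean).
#' @export
metagene_profile <- function(regions, site_calls, genome,
                             what = c("mc_fraction", "read_density"),
                             bins = 20L, flank = 1000L, flank_bin = 100L,
                             cnnr_loci = NULL) {
  what <- match.arg(what)
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  if (is.null(cnnr_loci)) cnnr_loci <- scan_cnnr_loci(g, "both")
  nf <- as.integer(flank / flank_bin)
  short <- (regions$end - regions$start) < bins
  if (any(short)) {
    warning(sum(short), " region(s) shorter than ", bins, " bp skipped")
    regions <- regions[!short, , drop = FALSE]
  }
  total <- 2L * nf + bins
  acc <- matrix(NA_real_, nrow = nrow(regions), ncol = total)
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    s <- regions$start[i]; e <- regions$end[i]
    body <- round(seq(s, e, length.out = bins + 1L))
    up <- seq(s - flank, s, by = flank_bin)
    down <- seq(e, e + flank, by = flank_bin)
    starts <- c(utils::head(up, -1L), utils::head(body, -1L),
                utils::head(down, -1L))
    ends <- c(up[-1L], body[-1L], down[-1L])
    ok <- starts >= 0L & ends <= lens[[chrom]] & ends > starts
    iv <- data.frame(chrom = chrom, start = starts[ok], end = ends[ok],
                     stringsAsFactors = FALSE)
    rm_ <- region_methylation(site_calls, iv, g, cnnr_loci = cnnr_loci)
    vals <- rep(NA_real_, total)
    vals[ok] <- if (what == "mc_fraction") rm_$mc_fraction
      else rm_$read_density
    if (!is.null(regions$strand) && regions$strand[i] == "-")
      vals <- rev(vals)
    acc[i, ] <- vals
  }
  value <- colMeans(acc, na.rm = TRUE)
  data.frame(bin = c(paste0("u", seq_len(nf)),
                     paste0("b", seq_len(bins)),
                     paste0("d", seq_len(nf))),
             position = seq_len(total), value = value,
             stringsAsFactors = FALSE)
}

#' Normalized per-gene methylation of bodies and promoters
#'
#' Per-gene relative methylation (called loci over CNNR loci) divided by
#' the genome-wide mean relative methylation; promoters are the 1 kb
#' upstream of the TSS (strand-aware), clipped at chromosome ends.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `name`.
#' @param site_calls Calls from [call_sites()].
#' @param genome Genome.
#' @param promoter Promoter width upstream of the TSS (default 1000 bp).
#' @return `genes` with added `body_level`, `promoter_level` (normalized;
#'   1 = genome average).
#' @export
normalize_gene_methylation <- function(genes, site_calls, genome,
                                       promoter = 1000L) {
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  loci <- scan_cnnr_loci(g, "both")
  genome_mean <- if (nrow(loci)) nrow(site_calls) / nrow(loci) else 0
  if (genome_mean == 0) stop("genome-wide mean methylation is zero")
  body <- region_methylation(site_calls, genes[, c("chrom", "start",
                                                   "end")], g,
                             cnnr_loci = loci)
  prom_start <- ifelse(genes$strand == "-", genes$end,
                       genes$start - promoter)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(prom_start, 0L),
                     end = pmin(prom_start + promoter,
                                lens[genes$chrom]),
                     stringsAsFactors = FALSE)
  promv <- region_methylation(site_calls, prom, g, cnnr_loci = loci)
  genes$body_level <- body$mc_fraction / genome_mean
  genes$promoter_level <- promv$mc_fraction / genome_mean
  genes
}
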