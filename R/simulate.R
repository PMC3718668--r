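#' Configuration for the synthetic study emulator
#'
#' Defaults emulate the study design: a 100-kb genome at Arabidopsis-like
#' GC content, symmetric CG sites methylated at a high rate (so two-way CG
#' recovery is well exercised), lower CHG/CHH rates, 50-bp single-end reads
#' over a 28-35 bp size-selected insert band with the Illumina read-1
#' adapter, and a low substitution error rate.
#'
#' @param genome_length Bases per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param gc_content Genome GC fraction.
#' @param p_CG,p_CHG,p_CHH Per-context methylation probabilities (symmetric
#'   categories are planted jointly on both strands).
#' @param coverage Mean reads per selected fragment.
#' @param read_length Read length (bp).
#' @param adapter 3' adapter appended after the insert.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed (mandatory; stage k of the pipeline seeds with
#'   `seed + k` so stages are individually reproducible).
#' @param size_min,size_max Size-selection window.
#' @param repeat_block_length Length of a duplicated block planted to mimic
#'   a repeat (0 disables).
#' @param fixed_coverage If `TRUE`, exactly `coverage` reads per fragment;
#'   otherwise Poisson.
#' @return list of class `mspji_sim_config`.
#' @export
sim_config <- function(genome_length = 1e5, n_chromosomes = 1L,
                       gc_content = 0.36, p_CG = 0.8, p_CHG = 0.3,
                       p_CHH = 0.1, coverage = 10, read_length = 50L,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       error_rate = 0.001, seed = 1L, size_min = 28L,
                       size_max = 35L, repeat_block_length = 1000L,
                       fixed_coverage = FALSE) {
  stopifnot(p_CG >= 0, p_CG <= 1, p_CHG >= 0, p_CHG <= 1,
            p_CHH >= 0, p_CHH <= 1, gc_content >= 0, gc_content <= 1,
            !is.null(seed))
  structure(as.list(environment()), class = "mspji_sim_config")
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content; optionally a block is copied
#' to a second location to mimic a repeat (so uniqueness filters have
#' something to reject).
#'
#' @param config [sim_config()].
#' @return Genome ([as_genome()]).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- stats::setNames(vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(names(probs), config$genome_length, replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1L)), paste0("chr", seq_len(config$n_chromosomes)))
  rb <- config$repeat_block_length
  if (rb > 0 && config$genome_length >= 4 * rb) {
    # copy [src, src+rb) over [dst, dst+rb) on chromosome 1
    L <- config$genome_length
    src <- as.integer(L * 0.1); dst <- as.integer(L * 0.7)
    block <- substr(g[[1L]], src + 1L, src + rb)
    g[[1L]] <- paste0(substr(g[[1L]], 1L, dst),
                      block,
                      substr(g[[1L]], dst + rb + 1L, L))
  }
  as_genome(g)
}

#' Simulate gene models on a genome
#'
#' Non-overlapping stranded intervals for annotation and metagene tests.
#'
#' @param genome Genome.
#' @param n Number of genes.
#' @param min_len,max_len Gene length bounds.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `name`.
#' @export
simulate_gene_models <- function(genome, n = 20L, min_len = 1000L,
                                 max_len = 3000L, seed = 1L) {
  set.seed(seed)
  g <- as_genome(genome)
  lens <- genome_lengths(g)
  out <- list()
  for (chrom in names(g)) {
    L <- lens[[chrom]]
    k <- max(1L, round(n / length(g)))
    # lay genes on an even grid, jittered, to guarantee non-overlap
    slot <- L %/% k
    if (slot <= max_len + 200L) k <- max(1L, L %/% (max_len + 200L))
    slot <- L %/% k
    width <- sample(seq(min_len, min(max_len, slot - 100L)), k,
                    replace = TRUE)
    start <- (seq_len(k) - 1L) * slot +
      vapply(slot - width - 1L, function(m) sample.int(m, 1L), integer(1L))
    out[[chrom]] <- data.frame(chrom = chrom, start = start,
                               end = start + width,
                               strand = sample(c("+", "-"), k,
                                               replace = TRUE),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$name <- paste0("gene", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Plant a methylome on a genome
#'
#' Every CNNR cytosine is considered: loci belonging to a symmetric
#' two-way category are methylated *jointly with their partner* with the
#' probability of their context (symmetric methylation); asymmetric loci
#' independently. The returned truth table records, for every planted
#' symmetric pair, the expected two-way fragment or the reason it is not
#' recoverable (cuts beyond the chromosome end, or competing cleavage /
#' product destruction by nearby methylated loci).
#'
#' @param genome Genome.
#' @param config [sim_config()].
#' @return list with `state` ([methylation_state()], explicit),
#'   `loci` (the planted loci), and `truth` (per symmetric pair: positions,
#'   category, context, expected fragment, `recovered`, `loss_reason`).
#' @export
simulate_methylome <- function(genome, config = sim_config()) {
  set.seed(config$seed + 1L)
  g <- as_genome(genome)
  loci <- scan_cnnr_loci(g, "both")
  p_of <- c(CG = config$p_CG, CHG = config$p_CHG, CHH = config$p_CHH)
  # joint (symmetric) planting only for mutual pairs: category precedence
  # can assign a locus to a different overlapping category than its
  # partner's, and such loci are planted independently like asymmetric ones
  key <- paste(loci$chrom, loci$pos, loci$strand)
  pkey <- paste(loci$chrom, loci$pos + loci$partner_offset_d,
                ifelse(loci$strand == "+", "-", "+"))
  pidx <- match(pkey, key)
  sym <- loci$category != "asymmetric" & !is.na(pidx) &
    loci$category[pidx] == loci$category &
    loci$partner_offset_d[pidx] == -loci$partner_offset_d
  sym[is.na(sym)] <- FALSE
  loci$mutual <- sym
  pair_id <- ifelse(sym,
                    paste(loci$chrom,
                          pmin(loci$pos, loci$pos + loci$partner_offset_d),
                          loci$category),
                    NA_character_)
  planted <- logical(nrow(loci))
  # symmetric pairs: one draw per pair, both partners planted
  ids <- unique(pair_id[sym])
  if (length(ids)) {
    first <- match(ids, pair_id)
    # a pair's context is its category's canonical (plus-strand) context
    cat_ctx <- stats::setNames(TABLE1_CATEGORIES$context,
                               TABLE1_CATEGORIES$pattern)
    draw <- stats::runif(length(ids)) < p_of[cat_ctx[loci$category[first]]]
    planted[sym] <- draw[match(pair_id[sym], ids)]
  }
  asym <- which(!sym)
  planted[asym] <- stats::runif(length(asym)) < p_of[loci$context[asym]]
  mloci <- loci[planted, , drop = FALSE]
  state <- methylation_state("explicit",
                             mloci[, c("chrom", "pos", "strand")])
  # truth per planted mutual symmetric pair
  msym <- mloci[mloci$mutual, , drop = FALSE]
  plus <- msym[msym$strand == "+", , drop = FALSE]
  truth <- data.frame(chrom = plus$chrom, plus_pos = plus$pos,
                      minus_pos = plus$pos + plus$partner_offset_d,
                      category = plus$category, context = plus$context,
                      d = plus$partner_offset_d,
                      expected_length = 33L - plus$partner_offset_d,
                      stringsAsFactors = FALSE)
  dig <- digest_genome(g, state)
  fr <- dig$fragments
  two <- fr[fr$scenario %in% c("E", "F") & !is.na(fr$category), ,
            drop = FALSE]
  fkey <- paste(two$chrom,
                pmin(two$locusA_pos, two$locusB_pos), two$category)
  tkey <- paste(truth$chrom, pmin(truth$plus_pos, truth$minus_pos),
                truth$category)
  hit <- match(tkey, fkey)
  truth$recovered <- !is.na(hit)
  truth$frag_start <- two$start[hit]
  truth$frag_end <- two$end[hit]
  lens <- genome_lengths(g)
  bound <- truth$plus_pos + 17L > lens[truth$chrom] |
    truth$minus_pos - 16L < 0L
  truth$loss_reason <- ifelse(truth$recovered, "",
                              ifelse(bound, "boundary", "competing"))
  list(state = state, loci = mloci, truth = truth, digest = dig)
}

#' Simulate the sequencing library
#'
#' Digests the genome under the planted state, size-selects, and samples
#' reads: each selected fragment yields `coverage` reads (Poisson unless
#' `fixed_coverage`), sequenced from a random strand, adapter appended
#' after the insert, truncated to the read length, with i.i.d. base
#' substitution errors (Q40 bases; errored bases Q10). Truth alignments of
#' the trimmed inserts are returned so no external aligner is needed.
#'
#' @param genome Genome.
#' @param state [methylation_state()].
#' @param config [sim_config()].
#' @return list with `reads` (id, seq, qual), `alignments` (truth,
#'   [write_sam()]-compatible), `fragments` (size-selected digest
#'   fragments with `n_reads`).
#' @export
simulate_reads <- function(genome, state, config = sim_config()) {
  set.seed(config$seed + 2L)
  g <- as_genome(genome)
  frs <- size_select(digest_genome(g, state),
                     config$size_min, config$size_max)
  if (!nrow(frs)) {
    warning("no size-selected fragments; empty library")
    return(list(reads = data.frame(id = character(), seq = character(),
                                   qual = character()),
                alignments = data.frame(qname = character(),
                                        flag = integer(),
                                        chrom = character(),
                                        pos = integer(),
                                        cigar = character(),
                                        seq = character()),
                fragments = frs))
  }
  n_reads <- if (config$fixed_coverage) rep(as.integer(config$coverage),
                                            nrow(frs))
    else stats::rpois(nrow(frs), config$coverage)
  frs$n_reads <- n_reads
  idx <- rep(seq_len(nrow(frs)), n_reads)
  if (!length(idx)) {
    frs$n_reads <- n_reads
    return(list(reads = data.frame(id = character(), seq = character(),
                                   qual = character()),
                alignments = data.frame(qname = character(),
                                        flag = integer(),
                                        chrom = character(),
                                        pos = integer(),
                                        cigar = character(),
                                        seq = character()),
                fragments = frs))
  }
  insert_fwd <- substring(unclass(g)[frs$chrom[idx]], frs$start[idx] + 1L,
                          frs$end[idx])
  rev <- stats::runif(length(idx)) < 0.5
  insert_read <- ifelse(rev, revcomp(insert_fwd), insert_fwd)
  raw <- substr(paste0(insert_read,
                       strrep(config$adapter,
                              ceiling(config$read_length /
                                        nchar(config$adapter)) + 1L)),
                1L, config$read_length)
  # i.i.d. substitution errors
  seqs <- strsplit(raw, "", fixed = TRUE)
  quals <- lapply(nchar(raw), function(L) rep("I", L))  # Q40
  err_n <- stats::rbinom(length(raw), nchar(raw), config$error_rate)
  for (i in which(err_n > 0L)) {
    p <- sample.int(nchar(raw[i]), err_n[i])
    for (j in p) {
      seqs[[i]][j] <- sample(setdiff(c("A", "C", "G", "T"),
                                     seqs[[i]][j]), 1L)
      quals[[i]][j] <- "+"  # Q10
    }
  }
  seq_chr <- vapply(seqs, paste, character(1L), collapse = "")
  qual_chr <- vapply(quals, paste, character(1L), collapse = "")
  within_frag <- sequence(n_reads)
  id <- sprintf("frag%06d_r%02d", idx, within_frag)
  ins_len <- frs$end[idx] - frs$start[idx]
  ins_err_read <- substr(seq_chr, 1L, ins_len)  # errored insert, read strand
  seq_ref <- ifelse(rev, revcomp(ins_err_read), ins_err_read)
  aln <- data.frame(qname = id, flag = ifelse(rev, 16L, 0L),
                    chrom = frs$chrom[idx], pos = frs$start[idx] + 1L,
                    cigar = paste0(ins_len, "M"), seq = seq_ref,
                    multiplicity = 1L, stringsAsFactors = FALSE)
  list(reads = data.frame(id = id, seq = seq_chr, qual = qual_chr,
                          stringsAsFactors = FALSE),
       alignments = aln, fragments = frs)
}

#' Simulate bisulfite-style per-site counts
#'
#' For every cytosine on both strands: coverage is Poisson, and the
#' methylated-read count is Binomial with success probability
#' `1 - error_rate` at planted sites and `error_rate` elsewhere.
#'
#' @param genome Genome.
#' @param state Planted [methylation_state()].
#' @param coverage Mean per-site coverage.
#' @param error_rate Non-conversion/sequencing error rate.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `pos`, `strand`, `methylated_reads`,
#'   `total_reads`.
#' @export
simulate_wgbs <- function(genome, state, coverage = 10,
                          error_rate = 0.01, seed = 1L) {
  set.seed(seed)
  g <- as_genome(genome)
  recs <- do.call(rbind, lapply(names(g), function(chrom) {
    s <- g[[chrom]]
    cpos <- as.integer(gregexpr("C", s, fixed = TRUE)[[1L]])
    gpos <- as.integer(gregexpr("G", s, fixed = TRUE)[[1L]])
    cpos <- cpos[cpos > 0L] - 1L; gpos <- gpos[gpos > 0L] - 1L
    data.frame(chrom = chrom, pos = c(cpos, gpos),
               strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
               stringsAsFactors = FALSE)
  }))
  recs <- recs[order(recs$chrom, recs$pos, recs$strand), , drop = FALSE]
  planted_key <- if (state$mode == "all_cnnr")
    with(scan_cnnr_loci(g, "both"), paste(chrom, pos, strand))
  else paste(state$loci$chrom, state$loci$pos, state$loci$strand)
  planted <- paste(recs$chrom, recs$pos, recs$strand) %in% planted_key
  recs$total_reads <- stats::rpois(nrow(recs), coverage)
  pmeth <- ifelse(planted, 1 - error_rate, error_rate)
  recs$methylated_reads <- stats::rbinom(nrow(recs), recs$total_reads,
                                         pmeth)
  rownames(recs) <- NULL
  recs
}
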