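#' Synthetic round-trip recovery of planted symmetric CG loci
#'
#' Runs the whole pipeline against its own generator: simulate a genome
#' and methylome, digest and sequence the size-selected band, QC and trim
#' the reads, call methylated loci from the truth alignments, and compare
#' the calls with the planted truth. The comparison is restricted to
#' symmetric CG (YNCGNR) loci whose 32-bp insert is unique in the genome;
#' planted pairs recorded in the truth table as unrecoverable (competing
#' cleavage or chromosome boundary) are excluded from the sensitivity
#' denominator, since no fragment exists for them by construction.
#'
#' @param config [sim_config()].
#' @return list: `specificity` (fraction of called unique CG loci that
#'   were planted), `sensitivity` (fraction of expected unique CG loci
#'   recovered), `n_expected`, `n_called`, `n_reads`, `n_reads_kept`.
#' @export
roundtrip_cg_recovery <- function(config = sim_config()) {
  g <- simulate_genome(config)
  meth <- simulate_methylome(g, config)
  lib <- simulate_reads(g, meth$state, config)
  pol <- qc_policy(adapter = config$adapter)
  flt <- filter_reads(lib$reads, pol)
  tr <- trim_adapter(flt[flt$keep, , drop = FALSE], pol)
  # a read enters calling when QC kept and its trimmed insert matches the
  # aligned span (a failed trim would not align end-to-end)
  aln <- lib$alignments
  want <- tr$id[tr$adapter_found]
  trimmed_len <- stats::setNames(nchar(tr$seq), tr$id)
  aln <- aln[aln$qname %in% want &
               nchar(aln$seq) == trimmed_len[aln$qname], , drop = FALSE]
  frs <- infer_fragments(aln, g)
  calls <- call_sites(frs, g, unique_only = TRUE)

  tt <- meth$truth
  cg <- tt[tt$category == "YNCGNR" & tt$loss_reason == "", , drop = FALSE]
  expected <- rbind(
    data.frame(chrom = cg$chrom, pos = cg$plus_pos, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(chrom = cg$chrom, pos = cg$minus_pos, strand = "-",
               stringsAsFactors = FALSE))
  if (nrow(expected))
    expected <- expected[fragment_uniqueness(g, expected), , drop = FALSE]
  ccg <- calls[calls$category %in% "YNCGNR", , drop = FALSE]
  if (nrow(ccg)) ccg <- ccg[fragment_uniqueness(g, ccg), , drop = FALSE]
  key_exp <- paste(expected$chrom, expected$pos, expected$strand)
  key_call <- paste(ccg$chrom, ccg$pos, ccg$strand)
  key_planted <- paste(meth$loci$chrom, meth$loci$pos, meth$loci$strand)
  list(specificity = if (length(key_call))
         mean(key_call %in% key_planted) else NA_real_,
       sensitivity = if (length(key_exp))
         mean(key_exp %in% key_call) else NA_real_,
       n_expected = length(key_exp), n_called = length(key_call),
       n_reads = nrow(lib$reads), n_reads_kept = nrow(tr))
}
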