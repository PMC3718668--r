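test_that("insert fragments are inferred from SAM with multiplicity", {
  toy <- toy_cg_genome()
  ins <- substr(unclass(toy)[["chr1"]], 4, 35)
  sam <- make_sam(toy, c(
    sprintf("r1\t0\tchr1\t4\t60\t32M\t*\t0\t0\t%s\t*\tNH:i:1", ins),
    sprintf("r2\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", ins),
    sprintf("r3\t0\tchr1\t4\t0\t32M\t*\t0\t0\t%s\t*\tNH:i:3", ins)))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  aln <- read_alignments(f)
  fr <- infer_fragments(aln, toy)
  expect_equal(nrow(fr), 2L)  # unmapped r2 skipped
  expect_equal(fr$start, c(3L, 3L))
  expect_equal(fr$end, c(35L, 35L))
  expect_equal(fr$multiplicity[fr$qname == "r3"], 3L)
  expect_equal(attr(fr, "n_reads"), 3L)
  expect_equal(attr(fr, "mapping_rate"), 2 / 3)
  expect_equal(attr(fr, "unique_rate"), 1 / 3)
  # multiplicity from repeated records when NH is absent
  sam2 <- make_sam(toy, c(
    sprintf("m\t0\tchr1\t4\t60\t32M\t*\t0\t0\t%s\t*", ins),
    sprintf("m\t256\tchr1\t5\t60\t32M\t*\t0\t0\t%s\t*", ins)))
  writeLines(sam2, f)
  expect_equal(unique(read_alignments(f)$multiplicity), 2L)
  expect_error(infer_fragments(data.frame(qname = "x", flag = 0L,
                                          chrom = "nope", pos = 1L,
                                          cigar = "32M"), toy),
               "absent")
})

test_that("notarization inverts the two-way digestion geometry", {
  toy <- toy_cg_genome()
  fr <- data.frame(chrom = "chr1", start = 3L, end = 35L, length = 32L)
  loci <- notarize_cnnr(fr, toy)
  expect_equal(loci$pos, c(18L, 19L))
  expect_equal(loci$strand, c("+", "-"))
  expect_equal(loci$category, c("YNCGNR", "YNCGNR"))
  # over featureless sequence nothing is notarized
  none <- notarize_cnnr(data.frame(chrom = "chr1", start = 0L, end = 14L,
                                   length = 14L), toy)
  expect_equal(nrow(none), 0L)
  # CHHG: 30-bp fragment carries its plus locus at end - 17
  g30 <- embed_core(category_cores[["CHHG"]])
  f30 <- digest_genome(g30)$fragments
  n30 <- notarize_cnnr(f30, g30)
  expect_equal(n30$pos[n30$strand == "+"], f30$end - 17L)
  expect_setequal(n30$category, "CHHG")
  expect_error(notarize_cnnr(data.frame(chrom = "chr1", start = 30L,
                                        end = 45L, length = 15L), toy),
               "bounds")
})

test_that("notarization is a right-inverse of digestion on random genomes", {
  for (s in 1:6) {
    g <- as_genome(random_genome(2000, seed = 400 + s))
    dig <- digest_genome(g)
    two <- dig$fragments[dig$fragments$scenario %in% c("E", "F"), ,
                         drop = FALSE]
    if (!nrow(two)) next
    rownames(two) <- NULL
    loci <- notarize_cnnr(two, g)
    for (i in seq_len(nrow(two))) {
      got <- loci[loci$frag_row == i, ]
      expect_setequal(paste(got$pos, got$strand),
                      c(paste(two$locusA_pos[i], two$locusA_strand[i]),
                        paste(two$locusB_pos[i], two$locusB_strand[i])))
    }
  }
})

test_that("site calling aggregates depth and honours unique_only", {
  toy <- toy_cg_genome()
  fr <- data.frame(chrom = "chr1", start = rep(3L, 10), end = rep(35L, 10),
                   length = 32L, multiplicity = 1L)
  calls <- call_sites(fr, toy)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$depth, c(10L, 10L))
  expect_equal(nrow(call_sites(fr[0, ], toy)), 0L)
  fr$multiplicity[1] <- 4L
  expect_equal(call_sites(fr, toy, unique_only = TRUE)$depth, c(9L, 9L))
  expect_equal(call_sites(fr, toy, unique_only = FALSE)$depth, c(10L, 10L))
})

test_that("multimapper resampling gives expected means and conserves reads", {
  regions <- data.frame(chrom = "chr1",
                        start = c(0L, 1000L), end = c(1000L, 2000L),
                        name = c("X", "Y"))
  two_pos <- data.frame(qname = "mm", chrom = "chr1",
                        start = c(100L, 1500L), end = c(132L, 1532L))
  res <- annotate_multimappers(two_pos, regions, n_resample = 1000,
                               seed = 1)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(res[["X"]] - 0.5), 4 * se)
  expect_lt(abs(res[["Y"]] - 0.5), 4 * se)
  expect_equal(sum(res), 1)  # conservation
  # unique reads are deterministic for any seed
  uni <- data.frame(qname = c("a", "b"), chrom = "chr1",
                    start = c(10L, 1200L), end = c(42L, 1232L))
  for (sd in c(1, 99))
    expect_equal(annotate_multimappers(uni, regions, 50, seed = sd),
                 c(X = 1, Y = 1, unassigned = 0))
  mixed <- rbind(uni, two_pos)
  resm <- annotate_multimappers(mixed, regions, n_resample = 200, seed = 2)
  expect_equal(sum(resm), 3, tolerance = 1e-9)
  one <- annotate_multimappers(two_pos, regions, n_resample = 1, seed = 3)
  expect_true(all(one %in% c(0, 1)))
})

test_that("region methylation reports density and mc fraction", {
  # genome with 4 CNNR loci in [0, 60): construct from 4 spaced CG cores
  g <- as_genome(c(chr1 = paste0(strrep("T", 5), "CGTA", strrep("T", 10),
                                 "CGTA", strrep("T", 37))))
  loci <- scan_cnnr_loci(g)
  expect_equal(nrow(loci), 4L)  # two CG pairs
  calls <- data.frame(chrom = "chr1", pos = loci$pos[1:2],
                      strand = loci$strand[1:2], depth = c(3L, 2L))
  calls <- calls[order(calls$pos), ]
  iv <- data.frame(chrom = "chr1", start = 0L, end = 60L)
  rm_ <- region_methylation(calls, iv, g, cnnr_loci = loci)
  expect_equal(rm_$n_cnnr, 4L)
  expect_equal(rm_$n_called, 2L)
  expect_equal(rm_$mc_fraction, 0.5)
  expect_equal(rm_$read_density, 5)
  empty <- region_methylation(calls,
                              data.frame(chrom = "chr1", start = 40L,
                                         end = 55L), g, cnnr_loci = loci)
  expect_equal(empty$read_density, 0)
  expect_true(empty$zero_denominator)
  expect_equal(empty$mc_fraction, 0)
  expect_warning(
    region_methylation(calls, data.frame(chrom = "chr1", start = 50L,
                                         end = 100L), g,
                       cnnr_loci = loci), "clipped")
})

test_that("full-coverage simulation recovers planted fractions per tile", {
  cfg <- sim_config(genome_length = 2e4, error_rate = 0, seed = 8,
                    p_CG = 1, p_CHG = 1, p_CHH = 1,
                    repeat_block_length = 0, fixed_coverage = TRUE,
                    coverage = 2)
  g <- simulate_genome(cfg)
  meth <- simulate_methylome(g, cfg)
  lib <- simulate_reads(g, meth$state, cfg)
  calls <- call_sites(infer_fragments(lib$alignments, g), g)
  tiles <- make_tiles(g, 5000L)
  rm_ <- region_methylation(calls, tiles, g)
  # every tile's called fraction reflects all-methylated truth up to
  # competing-cleavage losses: strictly positive everywhere
  expect_true(all(rm_$mc_fraction > 0))
  expect_true(all(rm_$mc_fraction <= 1))
})

test_that("length spectrum bins 26-39 with an overflow class", {
  fr <- data.frame(length = rep(32L, 5))
  sp <- fragment_length_spectrum(fr)
  expect_equal(sp[["32"]], 5L)
  expect_equal(sum(sp), 5L)
  expect_equal(sum(fragment_length_spectrum(fr[0, , drop = FALSE])), 0L)
  mixed <- data.frame(length = c(25L, 26L, 39L, 40L, 100L))
  spm <- fragment_length_spectrum(mixed)
  expect_equal(spm[["other"]], 3L)
  expect_equal(spm[["26"]], 1L)
})

test_that("position frequencies show the central CG of 32-mers", {
  toy <- toy_cg_genome()
  fr <- data.frame(chrom = "chr1", start = rep(3L, 1000),
                   end = rep(35L, 1000), length = 32L)
  pfm <- position_frequency_matrix(fr, toy, 32L, seed = 1)
  expect_true(all(pfm %in% c(0, 1)))
  expect_equal(unname(pfm["C", 16]), 1)  # 0-based position 15
  expect_equal(unname(pfm["G", 17]), 1)
  expect_equal(unname(colSums(pfm)), rep(1, 32))
  # fewer fragments than n_sample: all used
  pfm2 <- position_frequency_matrix(fr[1:3, ], toy, 32L,
                                    n_sample = 1000, seed = 1)
  expect_equal(pfm2, pfm)
  expect_error(position_frequency_matrix(fr, toy, 30L), "no fragments")
  # on simulated CG digests the central C is invariant
  cfg <- sim_config(genome_length = 2e4, p_CG = 1, p_CHG = 0, p_CHH = 0,
                    error_rate = 0, seed = 12, repeat_block_length = 0)
  g <- simulate_genome(cfg)
  meth <- simulate_methylome(g, cfg)
  dig <- size_select(digest_genome(g, meth$state))
  cg32 <- dig[dig$length == 32 & dig$category %in% "YNCGNR", ,
              drop = FALSE]
  pfm3 <- position_frequency_matrix(cg32, g, 32L, seed = 2)
  expect_equal(unname(pfm3["C", 16]), 1)
  expect_equal(unname(pfm3["G", 17]), 1)
})
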