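test_that("binomial site calling matches the closed-form tail", {
  rec <- data.frame(chrom = "c", pos = 0:3, strand = "+",
                    methylated_reads = c(10L, 0L, 1L, 0L),
                    total_reads = c(10L, 10L, 10L, 0L))
  out <- wgbs_call(rec, error_rate = 0.01, fdr = 0.05)
  expect_equal(out$p[1], 0.01^10)  # P(X >= 10) = p^10 exactly
  expect_true(out$called[1])
  expect_false(out$called[2])
  expect_false(out$tested[4])
  expect_false(out$called[4])
  any_ <- wgbs_call(rec, mode = "any_read")
  expect_true(any_$called[3])   # one supporting read suffices
  expect_false(any_$called[2])
  expect_error(wgbs_call(rec, error_rate = 0), "error_rate")
})

test_that("binomial calling controls the false-call rate on null sites", {
  set.seed(77)
  n <- 10000L
  rec <- data.frame(chrom = "c", pos = seq_len(n), strand = "+",
                    methylated_reads = stats::rbinom(n, 10L, 0.01),
                    total_reads = 10L)
  out <- wgbs_call(rec, error_rate = 0.01, fdr = 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(mean(out$called), 0.05 + 3 * se)
})

test_that("insert uniqueness distinguishes repeats and flags edges", {
  uniq <- random_genome(8000, gc = 0.5, seed = 14)
  g <- as_genome(uniq)
  cg <- scan_cnnr_loci(g)
  cg <- cg[cg$category == "YNCGNR" & cg$strand == "+", ][1:5, ]
  expect_true(all(fragment_uniqueness(g, cg)))
  block <- substr(uniq[[1]], 1, 1000)
  dup <- as_genome(c(c1 = block, c2 = block))
  cgd <- scan_cnnr_loci(dup)
  cgd <- cgd[cgd$category == "YNCGNR" & cgd$pos > 20 & cgd$pos < 980, ]
  cgd <- cgd[cgd$chrom == "c1", ]
  expect_false(any(fragment_uniqueness(dup, cgd)))
  near_start <- data.frame(chrom = "chr1", pos = 10L, strand = "+")
  expect_false(fragment_uniqueness(g, near_start))
})

test_that("specificity and sensitivity compare call sets within peaks", {
  peaks <- data.frame(chrom = "c", start = 0L, end = 10000L)
  mk <- function(pos) data.frame(chrom = rep("c", length(pos)),
                                 pos = pos,
                                 strand = rep("+", length(pos)))
  a <- mk(seq(10, 1000, by = 10))
  expect_equal(specificity_sensitivity(a, a, peaks),
               list(specificity = 1, sensitivity = 1, n_shared = 100L,
                    n_mspji = 100L, n_wgbs = 100L))
  half <- specificity_sensitivity(mk(seq(10, 500, by = 10)), a, peaks)
  expect_equal(half$specificity, 1)
  expect_equal(half$sensitivity, 0.5)
  # planted overlap structure: 76 shared, 4 enrichment-only, 19 wgbs-only
  msp <- mk(c(1:76, 901:904) * 10)
  wgb <- mk(c(1:76, 801:819) * 10)
  ss <- specificity_sensitivity(msp, wgb, peaks)
  expect_equal(ss$specificity, 0.95)
  expect_equal(ss$sensitivity, 0.8)
  sw <- specificity_sensitivity(wgb, msp, peaks)
  expect_equal(sw$specificity, ss$sensitivity)  # exchange on swap
  expect_equal(sw$sensitivity, ss$specificity)
  expect_warning(out <- specificity_sensitivity(mk(integer(0)), a, peaks),
                 "undefined")
  expect_true(is.na(out$specificity))
  # calls outside peaks are ignored
  np <- specificity_sensitivity(mk(c(100, 20000)), mk(100),
                                data.frame(chrom = "c", start = 0L,
                                           end = 1000L))
  expect_equal(np$n_mspji, 1L)
})

test_that("replicate correlation behaves at the fixed points and null", {
  set.seed(15)
  peaks <- data.frame(chrom = "c", start = (0:999) * 100L,
                      end = (1:1000) * 100L)
  pos <- sort(sample(0:(1000 * 100 - 1), 3000))
  calls <- data.frame(chrom = "c", pos = pos, strand = "+",
                      depth = stats::rpois(3000, 4) + 1L)
  expect_equal(replicate_correlation(calls, calls, peaks), 1)
  expect_equal(replicate_correlation(calls, calls, peaks, "depth_sum"), 1)
  # permuted depths across a permuted position set: near-zero correlation
  perm <- calls
  perm$pos <- sort(sample(0:(1000 * 100 - 1), 3000))
  r0 <- replicate_correlation(calls, perm, peaks)
  expect_lt(abs(r0), 3 / sqrt(1000) + 0.02)
  expect_error(replicate_correlation(calls, calls, peaks[1:2, ]),
               "3 peaks")
  flat <- data.frame(chrom = "c", pos = c(5L, 105L, 205L), strand = "+",
                     depth = 1L)
  expect_warning(rz <- replicate_correlation(flat, calls, peaks[1:3, ]),
                 "zero variance")
  expect_true(is.na(rz))
})

test_that("noisy replicates attenuate correlation as expected", {
  set.seed(16)
  n <- 400L
  x <- stats::rnorm(n, 50, 10)
  sigma <- 5
  y <- x + stats::rnorm(n, 0, sigma)
  expected_r <- 10 / sqrt(10^2 + sigma^2)
  expect_lt(abs(stats::cor(x, y) - expected_r), 0.05)
})

test_that("metagene profiles are flat under uniform methylation", {
  g <- as_genome(random_genome(3e4, gc = 0.5, seed = 17))
  loci <- scan_cnnr_loci(g)
  calls <- data.frame(chrom = loci$chrom, pos = loci$pos,
                      strand = loci$strand, depth = 1L)
  regions <- data.frame(chrom = "chr1", start = c(5000L, 15000L),
                        end = c(9000L, 19000L), strand = "+")
  prof <- metagene_profile(regions, calls, g, cnnr_loci = loci)
  expect_equal(nrow(prof), 40L)
  expect_true(all(prof$value == 1))
})

test_that("metagene profiles mirror for minus-strand regions", {
  g <- as_genome(random_genome(2e4, gc = 0.5, seed = 18))
  loci <- scan_cnnr_loci(g)
  # methylate only the left half: asymmetric profile
  calls <- data.frame(chrom = "chr1",
                      pos = loci$pos[loci$pos < 8000],
                      strand = loci$strand[loci$pos < 8000], depth = 1L)
  reg_p <- data.frame(chrom = "chr1", start = 6000L, end = 10000L,
                      strand = "+")
  reg_m <- transform(reg_p, strand = "-")
  pp <- metagene_profile(reg_p, calls, g, cnnr_loci = loci)
  pm <- metagene_profile(reg_m, calls, g, cnnr_loci = loci)
  expect_equal(pm$value, rev(pp$value))
  expect_false(all(pp$value == pp$value[1]))  # genuinely asymmetric
})

test_that("metagene profiles are translation invariant", {
  seqs <- random_genome(2e4, gc = 0.5, seed = 19)
  g1 <- as_genome(seqs)
  shift <- 4000L
  g2 <- as_genome(c(chr1 = paste0(strrep("T", shift), seqs[[1]])))
  l1 <- scan_cnnr_loci(g1)
  c1 <- data.frame(chrom = "chr1", pos = l1$pos[seq(1, nrow(l1), 3)],
                   strand = l1$strand[seq(1, nrow(l1), 3)], depth = 1L)
  c2 <- transform(c1, pos = pos + shift)
  r1 <- data.frame(chrom = "chr1", start = 5000L, end = 9000L,
                   strand = "+")
  r2 <- transform(r1, start = start + shift, end = end + shift)
  p1 <- metagene_profile(r1, c1, g1)
  p2 <- metagene_profile(r2, c2, g2)
  expect_equal(p1$value, p2$value)
})

test_that("regions shorter than the bin count are skipped with a warning", {
  g <- as_genome(random_genome(2000, seed = 20))
  calls <- data.frame(chrom = "chr1", pos = 100L, strand = "+",
                      depth = 1L)
  regions <- data.frame(chrom = "chr1", start = c(10L, 500L),
                        end = c(25L, 1500L), strand = "+")
  expect_warning(prof <- metagene_profile(regions, calls, g), "skipped")
  expect_equal(nrow(prof), 40L)
})

test_that("gene methylation normalizes against the genome mean", {
  g <- as_genome(random_genome(2e4, gc = 0.5, seed = 22))
  loci <- scan_cnnr_loci(g)
  genes <- data.frame(chrom = "chr1", start = c(2000L, 12000L),
                      end = c(6000L, 16000L), strand = c("+", "-"),
                      name = c("hyper", "hypo"))
  # call every locus inside gene 1, none in gene 2
  sel <- loci$pos >= 2000 & loci$pos < 6000
  calls <- data.frame(chrom = "chr1", pos = loci$pos[sel],
                      strand = loci$strand[sel], depth = 1L)
  out <- normalize_gene_methylation(genes, calls, g)
  gm <- nrow(calls) / nrow(loci)
  expect_equal(out$body_level, c(1 / gm, 0))
  expect_gt(out$body_level[1], out$body_level[2])
  expect_error(normalize_gene_methylation(genes, calls[0, ], g),
               "zero")
})
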