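---
title: "The MspJI digestion model: from cut geometry to methylation calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MspJI digestion model: from cut geometry to methylation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspjiseq)
```

## The enzyme model

MspJI is a modification-dependent restriction endonuclease. It recognizes
5-methylcytosine in the context ^mCNNR (R = A or G) and introduces a
double-strand break at fixed distances 3' of the methylated base: after the
12th nucleotide on the mC strand and after the 16th on the opposite strand,
leaving a four-base 5' overhang. In this package's 0-based, half-open
coordinates, a plus-strand mC at position $p$ cuts at between-base
coordinates $p+13$ (mC strand) and $p+17$ (opposite strand); a minus-strand
mC at $p$ mirrors leftward to $p-12$ and $p-16$. A cut that would fall
outside the chromosome makes no break.

When two methylated CNNR sites sit on opposite strands close enough that
their breaks face each other, both cuts release a short fragment containing
both methylated cytosines. Writing $d$ for the signed offset from the
plus-strand C to its minus-strand partner C, the end-repaired (outer-span)
fragment runs from $q - 16$ to $p + 17$, so its length obeys

$$L = 33 - d.$$

The seven degenerate strings in `TABLE1_CATEGORIES` describe the symmetric
site classes and their characteristic lengths: YNCGNR (32 bp, $d=1$),
YCHGR (31), CHHG (30), CYHAG (29), CHYAHG (28), TDDGCHHA (34, $d=-1$) and
TDDGNCHHA (35, $d=-2$). Size-selecting a 28–35 bp band after digestion
therefore enriches exactly these two-way products.

## Cleavage scenarios and the release model

Cleavage outcomes depend on the two nearest methylated loci
(`resolve_scenario()`):

* **A** — same strand, C positions ≥ 12 bp apart: two independent
  cleavages; the product between them has one recognition site and a wide
  length range.
* **B** — same strand, < 12 bp: competing cleavage; nothing but a cut
  terminus.
* **C** — opposite strands cutting toward each other, $d \ge 29$: a
  middle fragment with no recognition site.
* **D** — opposite strands, $16 \le d \le 28$: competing cleavage.
* **E** — opposite strands, $1 \le d \le 15$: two-way cleavage, fragment
  length $33 - d \in [18, 32]$ with both sites inside.
* **F** — opposite strands cutting away from each other ($d \le -1$):
  two-way fragment of length $\ge 34$.

Because the cleavage order of densely spaced sites is physically
unpredictable, the engine uses a single deterministic release model:
double-strand breaks are sorted along the chromosome, each adjacent pair is
resolved to a scenario, and a fragment spanning
`[min cut of left break, max cut of right break)` is emitted for scenarios
A, C, E and F — *unless* any cut of a third methylated locus falls strictly
inside that span, in which case the product is destroyed. Competing pairs
(B, D) are recorded as termini, not fragments; fabricating their products
would overstate what the model knows. Chains of more than two nearby loci
are handled implicitly by the same rule: greedy left-to-right adjacency on
cut coordinates, with third-cut destruction. The test suite proves this
sweep equivalent, fragment for fragment, to a brute-force oracle that
enumerates every opposite-strand pair and scans the full cut list, on 200
seeded random genomes.

Distances in the scenario thresholds are measured between C positions in
forward coordinates; only that reading makes the scenario-E bound of 15 bp
consistent with the 18–32 bp two-way lengths through $L = 33 - d$.

## Scanning and classification

Degenerate-motif scanning uses the IUPAC alphabet with one deliberate
exception: the letter N *in a genome* is unsequenced, not ambiguous, and
matches no pattern code (including pattern N), so no site is ever called on
unsequenced bases. Matches on the minus strand are evaluated on the reverse
complement and reported by the leftmost forward coordinate of the window
(BED convention). Overlapping matches are all reported.

Methylation context is the plant-standard trichotomy by the two bases 3'
of a cytosine on its own strand: CG, CHG, else CHH; an N among those bases
is flagged and binned as CHH. Each CNNR locus is assigned at most one
symmetric category by testing the seven strings anchored so the locus C
occupies the category's C position, longest pattern first with a fixed tie
order, first match wins. Category windows can overlap, and the precedence
rule then occasionally labels the two partners of one pair with different
categories (a few percent of symmetric loci on random sequence); the pair
relation used downstream — for planting symmetric methylation and for
attributing a category to a two-way fragment — therefore requires
*mutual* labels, and precedence-split loci are treated like asymmetric
ones. This is a package decision; the underlying category table gives no
rule for overlaps.

## The census

`census()` counts forward-strand matches of the seven category strings
(each match is one symmetric locus carrying two cytosines; the strings
subsume their own strand symmetry), total genomic cytosines as C plus G on
the forward strand, and the generation rate
$2 \sum_k n_k / n_{\mathrm{cytosines}}$ — the fraction of all cytosines
recoverable in the size-selected band if every CNNR cytosine were
methylated. The identity "cytosines in sites = 2 × summed locus count"
holds by construction and is asserted in the tests. Applied to a real
plant reference FASTA the same function reproduces that genome's category
table; the packaged tests exercise the arithmetic on synthetic genomes so
that nothing needs downloading.

## Read QC and trimming

Reads are dropped when more than 30% of bases are N or more than 10% have
Phred quality below 20 — both strict inequalities, read literally from the
filtering rule, so a 50-bp read with exactly 15 Ns is kept and one with 16
is dropped. Phred+33 encoding is assumed. Adapter trimming removes the
longest exact prefix of the configured adapter anchored at the read's 3'
end with a minimum overlap of 5 bases; exact matching keeps QC
deterministic and testable, at the cost of missing error-bearing adapter
copies (such reads simply fail to align end-to-end downstream). Filtering
is monotone (degrading a read never rescues it) and trimming is idempotent;
both are property-tested.

## Calling methylated loci

A mapped, trimmed read spans exactly one end-repaired insert. Inverting
the two-way geometry, the candidate plus-strand mC sits 17 bases left of
the insert's right edge (`end - 17`) and the candidate minus-strand mC 16
bases right of its left edge (`start + 16`); each candidate is accepted
only when the *reference* carries CNNR on that strand there, which is why
the surrounding reference sequence — not just the read — is consulted.
Depth (supporting fragments per locus) is the absolute methylation level;
a two-way fragment supports both of its loci, and duplicates are not
removed because depth is the signal. One-way products whose mC lies
outside the insert cannot be called at those offsets — an accepted
sensitivity loss of the size-selected design; conversely a coincidental
CNNR at the offset of a one-way fragment can produce a rare spurious call,
which bounds specificity just below one on dense methylomes. Cut wobble of
one base is off by default (`wobble = 0`) and intended for non-canonical
lengths such as 33-mers.

Region-level ("relative") methylation is computed in both printed senses,
kept distinct because they are genuinely different statistics: read
density (summed supporting depth of called loci in an interval) and
mc_fraction (distinct called loci over distinct CNNR loci). Multi-mapped
reads are handled by resampling one position per read uniformly, 1000
times by default, reporting mean per-region counts; assignment is by
midpoint with an explicit unassigned class, so means conserve the read
total exactly.

## Assessment statistics

Bisulfite-style per-site counts are called by a one-sided binomial test
against an error rate with Benjamini–Hochberg correction (defaults
`error_rate = 0.01`, `fdr = 0.05` — the conventional values for this
procedure; the source protocol does not print its own), or by the looser
any-supporting-read rule used when benchmarking enrichment data.
Specificity and sensitivity restrict both call sets to peak intervals and
to loci whose 32-bp insert is genome-unique (the insert or its reverse
complement hits exactly one window; a palindromic insert at one window
counts as unique). Replicate agreement is Pearson correlation of per-peak
site counts or depths. Metagene profiles scale each region to 20 body bins
with 1-kb flanks in 100-bp bins, reversing minus-strand regions; per-gene
levels are normalized by the genome-wide mean relative methylation
(genome-mean scaling is this package's choice of normalization, recorded
in the output), with promoters defaulting to 1 kb upstream of the TSS.

## The synthetic generator, and what it does not emulate

`sim_config()` defaults define the simulated study: one 100-kb chromosome
of i.i.d. bases at GC 0.36 (Arabidopsis-like), a planted 1-kb duplicated
block so uniqueness filters have something to reject, symmetric CG pairs
methylated jointly at `p_CG = 0.8`, CHG at 0.3 and CHH at 0.1, Poisson
coverage 10 per selected fragment, 50-bp single-end reads with the
Illumina read-1 adapter over a 28–35 bp band, substitution errors at
0.001, and a mandatory seed (stage $k$ seeds at `seed + k`, so every stage
is individually reproducible). The CG rate is set high to exercise
symmetric-CG recovery with tight binomial error bars at this genome size;
the non-CG rates echo the plant pattern of sparser non-CpG methylation.
The truth table records, for every planted symmetric pair, the expected
fragment or the reason none exists (competing cleavage, chromosome
boundary), so sensitivity accounting can separate caller misses from
losses that are unrecoverable by design.

Real data differ in ways the generator does not attempt: base composition
is not i.i.d. (real genomes have CpG depletion, repeats far beyond one
duplicated block, and context-dependent error profiles), errors carry no
indels, PCR duplication and partial digestion are absent, and truth
alignments replace a real aligner. Passing the round trip therefore
demonstrates the internal consistency of the cut model, caller geometry
and accounting — not performance on a real library.

## Numerical choices and problem sizes

Coordinates are 0-based half-open throughout; minus-strand features are
reported in forward coordinates. The size-selection window is inclusive
[28, 35] by default and configurable. Degenerate scanning delegates to
Biostrings with an explicit N post-filter; interval overlap to
GenomicRanges. The test suite runs everything at desk scale — 2-kb genomes
for the 200-genome oracle equivalence, 20–100-kb genomes for round trips
and profiles, 10,000 sites for the binomial null — sizes chosen so the
whole suite completes in a few minutes while keeping binomial standard
errors small enough for 3-s.e. assertions.

## Known limitations

Sensitivity is structurally limited to the symmetric two-way band;
asymmetric ^mCNNR sites and competing-cleavage clusters are invisible, as
is anything the 28–35 bp selection excludes. The engine is wobble-free;
enzymatic one-base wobble is accommodated only at calling time, per
length. Mappability is estimated by exact substring occurrence, a
best-case proxy for an aligner with mismatches. Hydroxymethylation is out
of scope.
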