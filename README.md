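# mspjiseq

In silico modelling and analysis of **MspJI methylation-dependent
digestion sequencing** — a cost-effective way to map 5-methylcytosine in
plant genomes by sequencing the short fragments that the enzyme releases
around methylated sites.

## The science

MspJI recognizes 5-methylcytosine in the context **^mCNNR** (R = A or G)
and cuts both strands at fixed distances 3' of the mC — after the 12th
nucleotide on the mC strand and the 16th on the opposite strand (N12/N16),
leaving a 4-base 5' overhang. When two methylated sites face each other on
opposite strands with partner offset *d* (minus-strand C position minus
plus-strand C position), two-way cleavage releases an end-repaired
fragment of length

> L = 33 − d

Seven degenerate site classes (YNCGNR, YCHGR, CHHG, CYHAG, CHYAHG,
TDDGCHHA, TDDGNCHHA) produce characteristic lengths 32, 31, 30, 29, 28,
34 and 35 bp, so size-selecting a 28–35 bp band enriches symmetric
methylated sites in all of CG, CHG and CHH contexts. The package
implements:

* IUPAC degenerate-motif scanning of genome FASTA on both strands
  (genome `N` matches nothing), context (CG/CHG/CHH) and category
  classification;
* the cleavage-scenario engine (six scenarios A–F: independent, competing
  and two-way cleavage), size selection, a per-category census with
  generation rate, and short-fragment mappability;
* FASTQ quality filtering (>30% N or >10% bases below Q20 dropped) and
  exact 3' adapter trimming;
* calling of methylated loci from mapped insert fragments by inverting
  the cut geometry (plus-strand mC at `end − 17`, minus-strand mC at
  `start + 16`, validated against the reference), with per-site depth as
  the absolute methylation level and two region-level relative measures;
* assessment statistics: binomial bisulfite-style calling with BH
  correction, specificity/sensitivity against peak regions restricted to
  genome-unique 32-bp inserts, replicate Pearson correlation, metagene
  profiles (20 body bins + 1-kb flanks in 100-bp bins), normalized
  per-gene levels;
* a fully seeded synthetic generator (genome, methylome, reads with
  adapters and errors, truth alignments, bisulfite-like counts) with a
  ground-truth table that distinguishes caller misses from
  competing-cleavage losses.

## Worked example

A 40-bp toy genome with one symmetric CG site (plus-strand C at
position 18):

```r
library(mspjiseq)
toy <- as_genome(c(chr1 = paste0(strrep("A", 16), "TACGTA",
                                 strrep("A", 18))))
census(toy)
#> MspJI two-way cleavage census
#>    pattern length  d count
#>     YNCGNR     32  1     1
#>      YCHGR     31  2     0
#>       CHHG     30  3     0
#>      CYHAG     29  4     0
#>     CHYAHG     28  5     0
#>   TDDGCHHA     34 -1     0
#>  TDDGNCHHA     35 -2     0
#> cytosines in sites: 2 of 2 (generation rate 100.00%)
```

Both cytosines of the pair (plus strand at 18, minus strand at 19) sit in
a YNCGNR window, so the generation rate — the fraction of all cytosines
recoverable in the band under the all-methylated assumption — is 100%.
Digestion releases the expected 32-bp scenario-E fragment, whose outer
cuts sit 16 bases left of the minus C and 17 bases right of the plus C:

```r
digest_genome(toy)$fragments[, c("start", "end", "length",
                                 "scenario", "category")]
#>   start end length scenario category
#> 1     3  35     32        E   YNCGNR
```

Calling from ten identical mapped inserts inverts that geometry and
recovers both loci with depth 10 (their absolute methylation level):

```r
fr <- data.frame(chrom = "chr1", start = rep(3L, 10), end = rep(35L, 10),
                 length = 32L, multiplicity = 1L)
call_sites(fr, toy)
#>   chrom pos strand context category partner_offset_d depth unique_only
#> 1  chr1  18      +      CG   YNCGNR                1    10        TRUE
#> 2  chr1  19      -      CG   YNCGNR               -1    10        TRUE
```

Running `census()` on a real plant reference FASTA (e.g. the TAIR9
Arabidopsis assembly) produces that genome's per-category site counts,
cytosine totals, generation rate and CNNR fraction in the same table
form: `mspji census --fasta TAIR9.fas --out census.tsv`.

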