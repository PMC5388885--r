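# barcodekit

Tools for two linked problems in plant DNA barcoding (*rbcL*, *matK*):

1. **Producing reference barcodes at scale** from amplicon sequencing,
   with two de-novo assemblers:
   * `eus_assemble()` — *extended unidirectional* assembly: per-colony
     quality filtering (< 5% `N` in the 5' twenty bases, < 1% overall),
     base-by-base directional consensus from each primer terminus, and a
     reverse-complement merge that sums base calls of both read sets
     inside their overlap.
   * `sma_assemble()` — *sonication micro-assembly*: quality masking
     (Q < 30 → `N`), read doubling with reverse complements, seeding on
     exact forward-primer prefixes, then iterative extension that
     recruits each unmerged read whose first 20 bases match the consensus
     of the 20 positions upstream of the cursor, followed by primer
     trimming. This reconstructs barcodes far longer than any single read
     (gene-length *matK* at ~1,456 bp).
2. **Quantifying what an incomplete reference database can honestly
   claim.** A Comprehensive Reference Barcode database (CRB) is the
   complete truth for a region; Incomplete Reference Barcode sets (IRBs)
   are sampled from it with replacement until they hold `N_s` species.
   Each distinct IRB barcode is *perceived species-unique* (one species),
   *ambiguous* (several), or *false species-unique* (unique in the IRB
   but shared in the CRB). Simulated field specimens (an Ecological
   Study Set, ESS) are identified against the IRB by exact or
   percent-identity matching, yielding perceived / ambiguous / unknown
   outcomes split into true and false by re-matching against the CRB.
   `scan_thresholds()` finds the optimal similarity threshold `O_t`;
   `fit_decay_curve()` fits `y = a·x^b` or `y = a·e^{bx}` to performance
   trajectories; `coverage_projection()` does the database-growth
   arithmetic.

Seeded generators (`simulate_crb()`, `simulate_eus_reads()`,
`simulate_sma_reads()`, `tile_template()`) produce databases and reads
with known ground truth, so the whole package is testable offline.

## Worked example

```r
library(barcodekit)

template <- withr::with_seed(1, paste(
  sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = ""))
fwd <- substr(template, 1, 20)
rev <- reverse_complement(substr(template, 881, 900))

reads <- simulate_sma_reads(template, n_reads = 2000, seed = 19)
asm <- sma_assemble(reads, fwd, rev)
asm
#> <sma_assembly> 860 bp trimmed barcode (900 untrimmed); 1672/2000 source reads used (83.6%)
identical(asm$consensus, substr(template, 21, 880))
#> [1] TRUE
```

The assembler recovered the exact 860-bp core of a 900-bp amplicon from
280-bp fragments carrying 1% substitution error and 5% sub-Q30 bases,
using 83.6% of the source reads.

```r
sim <- simulate_crb(n_species = 50, p_share = 0.1, seed = 7)
trend <- run_irb_size_experiment(sim$crb, "rbcL",
                                 n_grid = c(10, 25, 50),
                                 replicates = 100, seed = 11)
trend[, c("n_species", "mean_pct_perceived", "mean_pct_false")]
#>   n_species mean_pct_perceived mean_pct_false
#> 1        10           98.68889      8.6935897
#> 2        25           97.49776      4.8952248
#> 3        50           95.89697      0.3186279
```

Small reference sets look deceptively diagnostic: at `N_s = 10`, 98.7% of
barcodes appear species-unique but 8.7% of them are *falsely* so — the
sharing species simply have not been sampled yet. As the database
approaches completeness the false fraction collapses while genuine
ambiguity surfaces. `fit_decay_curve(trend$n_species,
trend$mean_pct_perceived, "power")` summarizes the decline
(`y = 102.9·x^-0.018`, R² = 0.97 on this run).

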