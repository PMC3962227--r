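# scskit

Frequency-based "linguistic" analysis of protein amino-acid sequences.

`scskit` treats a protein sequence the way quantitative linguistics treats an
English sentence: as a string of words. The words are **short constituent
sequences (SCSs)** — contiguous k-mers of length 3, 4, or 5 — and the central
question is how often each SCS is actually used in a proteome compared with
how often amino-acid composition alone predicts. The package is for
researchers doing alignment-free sequence comparison: finding candidate
functional sites along a single protein, extracting species-specific k-mer
signatures, studying k-mer co-occurrence "grammar", and comparing the
rank-frequency statistics of proteomes with natural-language text.

## The statistics

For a corpus (any FASTA proteome) and an SCS length *n*:

* **Real count** `R(w)`: the number of sliding windows equal to SCS *w*,
  pooled over all sequences; `Q` is the total window count.
* **Expected count** `E(w) = Q · P₁P₂…Pₙ`, where `Pᵢ` is the corpus-wide
  probability of the residue at position *i* of *w* (positional
  independence).
* **Availability** `A(w) = (R − E)/E = R/E − 1`. `A = 0` means usage exactly
  matches composition, large positive values mean the SCS is idiomatic,
  and `A = −1` means it never occurs (non-existent).

On top of availability the package builds:

* **Availability profiles** — per-residue traces of `A` along a query
  sequence at n = 3, 4, 5, rescaled so each series' maximum is 100%
  (a hydropathy-plot-style view of candidate functional sites).
* **Species comparison** — availability distance
  `m·A_focal − Σ A_other` and its rank-based analogue over up to 10
  comparison proteomes, with top/bottom listings, plus a substring search
  for the proteins containing a given SCS.
* **Triplet idioms** — for a core triplet *c*, a sub triplet *s*, and a
  signed relation *r* (±1…±10 adjacency slots; +1 = immediately
  C-terminal), the relation frequency `Y = relation_count/denominator`,
  the sub triplet frequency `X = sub_count/Q`, and the **evaluation score**
  `(Y − X)/X`. Idiom tables drive sequence annotation and greedy de-novo
  sequence design by idiom chaining.
* **Rank-frequency (Zipf) analysis** — ranked frequency tables for SCSs or
  for words of an English text, with a log-log power-law fit
  (Zipf's law corresponds to slope −1).
* **Synthetic corpora** — a seeded generator with controlled background
  residue frequencies, planted enriched SCSs, forbidden (never-occurring)
  SCSs, and planted idioms, so every statistic can be benchmarked without
  downloading a reference database.

## Worked example

```r
library(scskit)

toy <- as_scs_corpus(c("ACDEF", "ACD"), label = "toy")
t3  <- build_scs_table(toy, n = 3)
t3
#> # SCS table (n = 3) over 'toy': Q = 4 windows, 3 distinct SCS
#> # A tibble: 3 × 4
#>   scs       R      E     A
#>   <chr> <int>  <dbl> <dbl>
#> 1 ACD       2 0.0625    31
#> 2 CDE       1 0.0312    31
#> 3 DEF       1 0.0156    63
```

The corpus has `Q = 4` windows and residue probabilities
P(A) = P(C) = P(D) = 0.25. `ACD` occurs twice while composition predicts
`E = 4·0.25³ = 0.0625`, so its availability is `2/0.0625 − 1 = 31`: the
corpus uses `ACD` 32 times more often than its amino-acid content explains.
An SCS that never occurs scores −1:

```r
scs_lookup(t3, "AAA")
#> # A tibble: 1 × 4
#>   scs       R      E     A
#>   <chr> <int>  <dbl> <dbl>
#> 1 AAA       0 0.0625    -1
```

The same rank-frequency machinery applies to English text; on the short
worked passage shipped with the package:

```r
passage <- system.file("extdata", "english_passage.txt", package = "scskit")
rank_frequency(count_items(read_text_tokens(passage)))
#> # A tibble: 8 × 3   (first rows)
#>   item      frequency  rank
#> 1 of                7     1
#> 2 a                 4     2
#> 3 acid              4     2
#> 4 amino             4     2
#> ...
```

"of" is the most frequent word (7 occurrences, rank 1); tied words share a
competition rank. `power_law_fit()` then fits the Zipf slope on the log-log
rank-frequency table, and `autoplot()` draws the profile, histogram, and
Zipf plots.

A command-line wrapper over the same functions ships at
`inst/cli/scs.R` (subcommands `table`, `profile`, `species-diff`,
`scs-grep`, `idioms`, `annotate`, `design`, `zipf`, `simulate`).

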