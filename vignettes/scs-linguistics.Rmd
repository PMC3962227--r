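---
title: "Availability, idioms, and Zipf: the methods behind scskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Availability, idioms, and Zipf: the methods behind scskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scskit)
```

## The model

`scskit` analyses protein sequences through the frequencies of their short
constituent sequences (SCSs): contiguous k-mers over the 20-letter
amino-acid alphabet, by analogy with words in a sentence. All statistics
derive from one null model: if residues were drawn independently with the
corpus-wide probabilities $P_a$, an SCS $w = a_1 a_2 \dots a_n$ would be
expected $E(w) = Q \cdot P_{a_1} P_{a_2} \cdots P_{a_n}$ times among the
$Q$ windows of the corpus. The availability score

$$A(w) = \frac{R(w) - E(w)}{E(w)} = \frac{R(w)}{E(w)} - 1$$

measures the usage bias of $w$ relative to that composition-only
expectation: $A = 0$ is unbiased usage, $A = -1$ is a non-existent SCS,
large $A$ marks SCSs used far beyond what composition explains.

Assumptions worth keeping in mind:

* The background probabilities are estimated from the *same* corpus that is
  counted (self-referential background). No external or positional
  background is supported; `E` is a pure product, with no dipeptide or
  Markov correction, so `A` absorbs *all* positional structure, including
  trivial neighbour correlations.
* Counts are exact integers; `E` and `A` are doubles. By construction
  $\sum_w R = Q$, and over the full $20^n$ repertoire
  $\sum_w E = Q$ and $\sum_w E \cdot A = 0$ — the test suite asserts both
  to $10^{-6}$ relative, and they are useful smoke tests on any new corpus.
* $A$ is undefined when $E = 0$, which happens only when a residue of $w$
  is entirely absent from the corpus — realistic only for tiny corpora.
  Undefined scores are `NA`, excluded from rankings, and reported as a
  dropped count by the species-comparison functions. The availability
  *profile* is the one place where an unobserved SCS is scored $-1$ even if
  its $E$ is 0, because there the question is simply "does this window
  occur?".

### Choice of SCS length

The repertoire grows as $20^n$: 8,000 triplets, 160,000 quartets,
3.2 million pentats, $6.4\times 10^7$ hexamers. For n ≤ 5 a large proteome
populates most of the repertoire, so availability is informative; by n = 6
the repertoire is comparable to the window count of even a very large
database and most SCSs are absent for purely combinatorial reasons. The
package therefore supports n = 3..8 for counting but treats 3–5 as the
working range (profiles use all three; idioms use triplets).

## Availability profiles

`availability_profile()` slides windows of length 3, 4, 5 along a query and
assigns each window's availability to its **center residue**
(`start + floor((n-1)/2)`, i.e. the second residue for n = 4). Chain ends
carry no score because they complete no window; a length-$L$ query has at
most $L - n + 1$ scored positions per series. Center anchoring keeps the
three series aligned over the same residues and is configurable in the
sense that the raw `start` column is always returned alongside.

Relative scores rescale each series so its maximum raw availability is
100%, with negative values scaled proportionally (they can fall below 0%).
Scaling is **per series** by default: each n is scaled to its own maximum,
which keeps the three curves comparable in shape; `scaling = "global"`
uses one maximum across all three. A series whose maximum raw score is not
positive has no meaningful 100% anchor; its relative values are `NA` and a
warning is raised.

## Species comparison

Given a focal table and $m \le 10$ comparison tables at the same n,
`availability_distance()` scores every SCS as
$m \cdot A_{focal} - \sum_i A_{other,i}$ (the focal score is doubled when
two species are compared, and so on). `rank_distance()` first converts each
table to ordinal availability ranks (ties broken lexicographically, so the
ranking is a total order) and scores $\sum_i rank_{other,i} - m \cdot
rank_{focal}$. Both sign conventions are chosen so that **positive always
means "more characteristic of the focal species"**.

SCSs unobserved in one species still participate with $A = -1$: rarity in
the comparison species is exactly the signal a species-specific SCS search
is after. The scored universe is the union of SCSs observed in at least one
table rather than the full $20^n$ repertoire — an SCS absent from *every*
table would score exactly $m(-1) - m(-1) = 0$ and is uninformative, so the
restriction changes no top/bottom listing; `repertoire = "full"` is
available for small n when the exhaustive table is wanted.

## The idiom grammar

An idiom is a triple (core triplet $c$, sub triplet $s$, relation $r$) with
$r \in \pm1..\pm10$. Relations count **non-overlapping adjacency slots**:
$r = +1$ is the triplet immediately C-terminal of the core (sub start =
core start + 3), $r = +2$ leaves a one-residue gap, and negative relations
mirror to the N-terminal side. This "gap" convention follows from reading
"+1 = just next on the right" as adjacent non-overlapping units; because a
residue-offset reading is also defensible, `mode = "offset"` implements it
(sub start = core start + r, overlapping windows allowed). Gap mode is the
default throughout.

For each idiom the table records the relation count, the **denominator**
(core occurrences whose window at that relation lies fully inside the
sequence and is canonical — so $Y = $ relation count / denominator is a
proper conditional probability, $\sum_s Y = 1$ at fixed $(c, r)$), the sub
triplet's global frequency $X = $ sub count / $Q$, and the evaluation score
$(Y - X)/X$: how much more often $s$ appears at that position relative to
its unrestricted frequency. Internally the score is computed as
$\mathrm{rc} \cdot Q / (\mathrm{denominator} \cdot \mathrm{subcount}) - 1$,
which is algebraically the same number but gives bit-identical values for
an idiom and its mirror image $(s, c, -r)$, so exact ties resolve through
the deterministic tie-break (score desc, relation count desc, then core,
sub, relation) rather than floating-point rounding noise.

Annotation (`annotate_sequence()`) reports, N-terminal first, every (core
window, relation) of a query whose (core, sub, relation) is in the table at
rank ≤ the rank border (default 1000, the usual browsing default; 100
usually suffices). Design (`design_sequence()`) grows a sequence from a
seed triplet by repeatedly applying the best eligible idiom at
$|r| = 1$ — only adjacency gives a concrete residue-by-residue
construction; larger relations would need gap filling. A rightward step
takes the current C-terminal triplet as core and appends the sub of the
highest-ranked idiom at $r=+1$; a leftward step mirrors this through
$r=-1$, prepending. Because idiom tables are exactly mirror-symmetric in
their counts, the two directions see the same idiom inventory and differ
only in which side's score orders the greedy choice.

## The synthetic-corpus generator

`generate_corpus()` emulates the statistical skeleton of a proteome that
the availability machinery responds to: an i.i.d. residue background
(uniform 0.05 by default; `nr_aa_like_probs()` supplies a realistic uneven
preset with L ≈ 9% down to W ≈ 1.3%), Poisson-placed planted SCSs
(overwritten, never inserted, so lengths stay exact and expected counts are
rate × number of sequences), planted idiom pairs at a fixed relation, and
forbidden SCSs removed by rewriting any matching window until none remains
(error after a retry cap, e.g. when a forbidden SCS is wholly inside a
planted region). Generation is fully deterministic given the spec's seed
and leaves the caller's RNG stream untouched.

What it deliberately does **not** emulate: domain structure, repeats,
phylogenetic correlation between sequences, codon-level effects, or the
actual nr-aa SCS distribution. Passing recovery tests on this generator
therefore shows the *statistics* behave as designed — that planted signals
of known strength are ranked where the formulas say they must be — not that
any particular biological claim holds on real proteomes.

### Designing the planted-idiom benchmark

The evaluation score is approximately
$\mathrm{rc}\cdot Q/(\mathrm{count}_c \cdot \mathrm{count}_s)$, which has
two consequences for benchmark design that are easy to underestimate.
First, planting core and sub *adjacently* makes the planted hexamer's own
overlapping and flanking windows into idioms of their own, with scores that
tie or exceed the planted idiom's (the score is invariant to diluting the
flank across 20 letters, and denominators shrink — so scores grow — with
$|r|$ through edge effects). Second, with a minimum relation count of 1,
singleton coincidences between rare triplets reach scores near $Q$ and
swamp everything. The recovery benchmark therefore plants at relation +2
(the random gap letter decouples the pair's internal windows), uses 300
sequences of 80–120 residues under the uneven background, and evaluates
with `min_count = 50` — safely above both the Poisson-coincidence scale and
the largest flank-leak count (rate × sequences × max residue probability
≈ 28). Under that filter the idiom table contains exactly the planted
idiom and its mirror image, and the planted record ranks first. The same
reasoning is why `min_count` exists as a user-facing parameter: real
corpora produce the same two artifact classes.

## Numerical and interface choices

* Non-canonical letters (`B J O U X Z *`) are kept in stored sequences but
  excluded at the window level, so the SCS space stays exactly
  $20^n$ while inputs round-trip byte-for-byte.
* Rank-frequency tables use competition ranking by default (tied words
  share the minimal rank of their block, matching how tied words are
  listed in word-count tables); ordinal ranking with lexicographic
  tie-breaks is used wherever a total order is required (Zipf fitting,
  rank distance, idiom ranks).
* The tokenizer lowercases, keeps internal apostrophes and hyphens
  ("Zipf's", "three-dimensional" are single tokens), and strips
  surrounding punctuation; it counts singular and plural as distinct
  tokens. It is idempotent on its own joined output.
* The power-law fit is ordinary least squares on
  $(\log_{10} r, \log_{10} f)$, optionally over a rank window — a
  descriptive straight-line fit of the kind read off a log-log plot, not a
  heavy-tail maximum-likelihood estimator. $R^2$ is computed directly from
  residuals so numerically exact fits are handled quietly.
* Degenerate inputs fail loudly with classed conditions
  (`scskit_data_error`, `scskit_usage_error`); a sequence merely too short
  for a window yields an empty result instead.

## Problem sizes

The shipped tests and the acceptance script run corpora of 20–5,500
sequences (up to ~10⁶ windows for the mean-availability normalization
check), brute-force oracle comparisons on ≤100 sequences, and
planted-recovery designs of 100–300 sequences; these sizes put the
empirical checks well into the regime where the formulas' expectations
apply while keeping a full run in minutes on one core.

## Known limitations

* Availability inherits every bias of the input corpus (redundancy,
  contamination, uneven taxon sampling); the package applies no redundancy
  filtering.
* The independence null means common secondary-structure periodicities
  surface as "idiomatic" signal; that is intended (the point is to find
  such structure) but should not be read as motif discovery with
  significance control — no multiple-testing machinery is provided, by
  design.
* Greedy idiom chaining is a prototype sequence designer: it maximizes one
  step at a time and can dead-end; it makes no claim about foldability.
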