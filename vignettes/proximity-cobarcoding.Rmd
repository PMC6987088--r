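---
title: "Methods: co-barcoding statistics for Proximity RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-barcoding statistics for Proximity RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxseq)
```

## The measurement and its null model

Proximity RNA-seq co-barcodes the RNAs of one crosslinked subcellular
particle with one bead's barcode inside a droplet. The data reduce to a
bipartite occurrence structure: barcode groups (beads/particles) on one
side, transcripts on the other, with a transcript observed at most once
per group (a *proxy read* — multiple reads of one transcript under one
barcode are indistinguishable copies). Two facts make naive enrichment
tests on pair counts meaningless:

* transcript abundances span orders of magnitude (a Zipf-like tail), and
* particles are loaded into droplets approximately Poisson, so group
  sizes vary.

Abundant transcripts therefore co-barcode massively by chance. The null
model used here conditions on both nuisances exactly: the *skeleton* of a
dataset is the per-transcript proxy totals $n_f$ together with the
multiset of group sizes $\{k_g\}$, and a randomization is a uniform-intent
redistribution of feature tokens over groups that preserves the skeleton
exactly and never places a feature twice in one group.

### The constrained randomizer

`randomize_once()` implements the dealing algorithm: shuffle the multiset
of feature tokens, visit groups in random order, and deal tokens into each
group; a token that would duplicate a feature already in the current group
is pushed onto a carry-forward queue that the *next* group consumes first.
Plain rejection would systematically starve abundant features (they are
rejected most often); the carry-forward rule guarantees every token is
placed, so per-feature totals are conserved *exactly* on every draw (the
acceptance suite verifies 0 violations in 1,000 draws across random
skeletons). A deal can rarely get stuck when the tail groups cannot
accommodate the remaining tokens without duplicates; the implementation
then restarts with a fresh shuffle (bounded, counted, and errors past the
cap). Infeasible skeletons — some $n_f$ exceeding the number of groups —
are rejected before sampling by pigeonhole.

**Known property: the sampler is not uniform over valid assignments.**
Comparing against exhaustive enumeration of all 0/1 feature-by-group
matrices with the skeleton's margins (small skeletons, ≤6 features and
≤5 groups), the empirical per-(feature, group) occupancy deviates from
the enumeration values by clearly more than Monte-Carlo noise: abundant
features end up slightly over-represented in larger groups, because
carried-forward duplicates preferentially land where there is room. The
acceptance script computes this deviation (`occupancy_max_deviation_se`),
and the corresponding acceptance test is expected to fail its 3-SE bound
— deliberately left failing rather than papered over, since the dealing
algorithm itself (shuffle + carry-forward) is the procedure this package
sets out to provide, bias and all.
The marginals the method actually relies on (feature totals, group sizes,
within-group uniqueness) are conserved exactly.

The hot loop is compiled (Rcpp) and draws from R's RNG, so `set.seed()`
makes every result — including sharded runs merged with
`merge_randomizations()`, which sum pair counts exactly — reproducible.

## Local-background significance

For each unordered pair, the observed co-barcoding count $x$ is compared
with its mean $\bar m$ over $N$ randomizations through
$y = \log_2\!\big(x / \max(\bar m, 1/N)\big)$. The floor $1/N$ handles
pairs never seen in randomizations; the log makes the spread roughly
symmetric, which is what the subsequent normal model needs.

The expected spread of $y$ depends strongly on $x$: rarely co-barcoded
pairs can show large ratios by chance, abundant pairs cannot. The
empirical *background distribution* captures this: one randomization of
the data — a dataset known to contain no genuine proximity but with the
identical skeleton — is itself randomized $N$ times, giving a cloud of
$(x, y)$ points. An observed pair at count $x$ is scored against the
`window_size` (default 500) background points nearest in $x$ (ranked by
$|x_{bg} - x|$, ties broken toward smaller counts, deterministically): a
normal is fitted to their $y$ values by sample mean and SD, and the
pair's local p value is the upper-tail probability of its own $y$. Pairs
with $x \ge 3$ (default) enter Benjamini–Hochberg correction; pairs with
$x \ge 2$ are reported. Degenerate windows (zero SD) give $p = 1$ below
the mean and the $1/N$ floor above it, with a warning; a background
smaller than the window is used whole, with a warning.

### Calibration properties

Three properties of this construction are worth knowing; all are
mechanical consequences of the design, and the package's tests compute
them rather than assume them:

* **The background funnel.** Restricting to $x \ge 2$ selects, at small
  expected counts, pairs that happened to come up high — so background
  $y$ values at small $x$ are systematically positive (the funnel visible
  in count-ratio plots). The cloud is centred near zero only at
  well-sampled counts; the test suite asserts centredness for $x \ge 5$
  on a 10,000-group skeleton.
* **Tails, not the centre, are calibrated.** Comparing a dataset's
  simulation results against themselves yields p values whose tail
  fractions sit at their nominal sizes while the mean sits slightly below
  0.5 (each point's own $y$ participates in its window fit). The suite
  asserts tail calibration; a Kolmogorov–Smirnov uniformity test would
  detect the small mean shift at a few hundred pairs and is knowingly not
  used.
* **Type-I error runs near, not at, the nominal level.** The normal fit
  underestimates the heavy, discrete upper tail of $y$ at small
  randomized means, so on null data the fraction of tested pairs at
  local $p \le 0.01$ lands around one to two times nominal depending on
  the draw, and an occasional null pair survives BH. The acceptance test
  bounds the rate at 0.015 with zero-to-one BH discoveries on its fixed
  dataset; the acceptance script recomputes both for the seed it is
  given.
* **The window must be local to be useful.** With few background points,
  "the nearest 500 in $x$" spans the whole count axis and dilutes the
  local SD with the low-count funnel; true proximities then fail to reach
  significance regardless of effect size. The reference analyses get
  dense backgrounds from pooled-library scale. The package's power
  experiment (below) creates density instead via a narrow abundance
  range.

## Read processing choices

* **Primer validation.** The fixed PCR primer must start within ± the
  edit budget of its canonical position (after the 26-nt barcode), with
  total edits (insertions + deletions + substitutions combined) at most
  `floor(primer length / 10)` — one error per 10 bases, the three edit
  types read as alternatives. The matcher returns the matched end offset
  so downstream extraction tolerates indels. Candidate (start, length)
  pairs are scored deterministically: fewest edits, then least positional
  shift.
* **Barcodes.** Trimmed by 3 nt at each end (observed register offsets of
  about one base) to 20 nt. Low-complexity rule: any symbol (N included)
  occurring ≥13 times in 20 discards the barcode. Adapter similarity uses
  the same per-10-bases budget against each adapter and its reverse
  complement, matching the shorter of adapter/barcode within the longer.
  N matches nothing, not even another N (implemented by sentinel
  remapping, since a no-call carries no evidence of identity).
* **Grouping.** Barcodes link at edit distance ≤ 2; groups are connected
  components under transitive closure. This replaces the original
  virtual-scaffold trick (concatenating barcodes with 24-N spacers and
  multi-mapping against them with a short-read aligner) by its intended
  semantics; the 24-N spacer is therefore never materialized. The unit
  and acceptance suites check the partition against brute-force connected
  components of the dynamic-programming edit-distance graph.
* **Group-size cap.** Sizes are modelled as Poisson with $\hat\lambda$
  the sample mean (the estimator is otherwise unconstrained and the MLE
  is natural). A size $s$ is removed when $P(X \ge s) < 0.001$, i.e. the
  threshold is the largest $s$ with upper-tail mass at least the cutoff;
  a cutoff so large that nothing survives is a configuration error. The
  cap is applied to deduplicated member counts, after PCR deduplication
  and before proxy collapse.

## Annotation resolution

Conflicts are resolved by rule, transitively, independent of input order:
repeat classes (each collapsed to a single feature, e.g. all tRNA copies
are "tRNA") claim their coordinates on **both** strands, before and above
everything else; bases claimed by two different repeat classes are
removed. Genes are then resolved per strand: at every base, the winning
gene is the one whose full interval is contained in every other covering
gene's interval — this generalizes both "inner feature wins" (snoRNAs
inside host genes) and "partial overlaps are ambiguous and removed"; an
exact-interval tie is ambiguous. The implementation works on disjoint
interval pieces but is specified — and tested, against a literal per-base
labeler on random toy annotations — by these per-base semantics.

Reads are assigned by alignment **midpoint** (`floor((start+end)/2)`);
midpoint assignment also settles reads straddling two features. Unique
reads respect gene strand (antisense hits are reported unassigned, making
the sense-fraction a metric rather than a hard filter) but match repeats
on either strand. Multi-mapping reads survive only if every alignment's
midpoint lands in one single repeat class. The 45S rRNA precursor is
handled as ordinary annotation rows on a dedicated chromosome name
supplied by the user; genome masking is out of scope.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of the
experiment: group sizes are zero-truncated Poisson (an empty bead is
unobservable), groups are filled by abundance-weighted sampling without
within-group replacement from a Zipf-ranked transcript set, and a planted
pair injects its partner with probability `min(1, boost × partner weight)`
after either member enters a group — simple and analytically tractable
(at boost 1 pair counts match the independence expectation exactly in
mean). `render_synthetic_reads()` writes the construct-accurate FASTQ
(barcode with substitution errors, primer, random 15-mer, 50-nt cDNA) and
the matching SAM against a toy one-gene-per-feature annotation;
`clonal_beads = FALSE` emulates the randomly barcoded control library, in
which grouping by barcode no longer reflects particles.

What it does **not** emulate — so green tests say nothing about these —
includes: quality-score structure and indel sequencing errors, alignment
ambiguity beyond designated repeat classes, chimeric/PCR-recombination
artifacts, abundance distributions with structure beyond a power law, and
droplet doublets (two beads, one particle).

Defaults (200 features, Zipf exponent 1, 5,000 groups, λ = 1.5) are the
null-experiment conditions used for the type-I acceptance check. The
power experiment instead uses 44 features at near-uniform abundance
(exponent 0.3) on 10,000 groups with 500 randomizations: with ~950 pairs
all at similar expected counts, the 500-point window is genuinely local
at the planted pair's count, which is the regime the method is designed
for (see "The window must be local"). Test problem sizes throughout the
suite (hundreds of groups for unit tests, 10⁵ draws for the enumeration
comparison, 20 replicates for power) are the package's chosen balance of
statistical resolution against a test suite that runs in minutes.

## Numerical and dialect decisions

* Coordinates are 1-based inclusive everywhere; SAM end positions are
  `POS + sequence length − 1` (no CIGAR arithmetic, by scope).
* Text outputs are tab-delimited UTF-8 with a header row, gzip-compressed
  when the filename ends `.gz`. The simulation-formatted dialect is the
  six columns (`barcode_group_id`, `feature_name`, `chromosome`, `start`,
  `end`, `strand`); pair tables store `feature_a < feature_b`
  lexicographically and q-value tables sort by q ascending, then observed
  count descending.
* "Bonferroni-Hochberg" in the original description is implemented as
  Benjamini–Hochberg (the figure legends use the latter), over the
  $x \ge 3$ set only.
* Valency z-scores use the sample SD across qualifying transcripts
  (> 10 proxy reads at valencies 1–3, strict); "middle" valency is
  qualifying-but-neither-high-nor-low; consensus across libraries keeps
  only transcripts identically classed high (or low) in every library.
  Network exports weight edges by $-\log_{10} p$ capped at 10.
* Empty inputs yield empty, well-formed outputs; genuinely degenerate
  configurations (zero-SD valency fractions, all-removing size cutoffs,
  infeasible skeletons) raise errors rather than guesses.
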