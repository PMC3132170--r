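---
title: "Breakpoint pairs and 3D proximity: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint pairs and 3D proximity: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the data model

When two genomes are compared through their synteny blocks — orthologous
regions with conserved gene order and orientation — the regions between
consecutive blocks whose orthologous blocks are not consecutive (or not in
the same relative orientation) on the other genome are *breakpoint regions*:
the scars of evolutionary rearrangements. Because every breakpoint is flanked
by two blocks, each breakpoint on genome B is orthologous, at its two
extremities, to two breakpoints on genome A. Those two A-side breakpoints
form a *breakpoint pair*: genomically distant on A, adjacent on B.

The package asks whether such pairs, mapped onto fixed 1-Mb windows of
genome A, show elevated Hi-C contact counts relative to comparable locus
pairs — i.e. whether loci torn apart (or newly joined) by rearrangement
remain in 3D proximity — while controlling for the strong distance decay of
Hi-C signal, for gene density and chromatin openness, and for a mapping
artifact caused by segmental duplications (SDs).

## Breakpoint detection, pairing and origins

Detection works on *block extremities*: block $b$ has a tail ($2b-1$) and a
head ($2b$); an adjacency between consecutive blocks is the unordered pair of
facing extremities. An adjacency of genome A is broken iff that extremity
pair is not an adjacency of genome B, which makes a jointly inverted run of
blocks (correctly) not a breakpoint. Chromosome extremities can be emitted as
zero-length telomere sentinels: they have a single flanking block,
participate in pairing, but can never satisfy an interval-overlap condition.

Pairing iterates over internal genome-B breakpoints. The facing extremities
of the flanking blocks identify, on genome A, the two adjacent breakpoints
(or telomere sentinels) that the B breakpoint links. Duplicate candidate
pairs — a single inversion produces the same pair from both of its B
breakpoints — are merged with the link multiplicity retained. A pair is
*reciprocal* iff neither member occurs in any other pair (a membership
criterion, not a multiplicity one): the signature of one simple inversion or
translocation. Pairs sharing members are *non-reciprocal*, indicating
breakpoint re-use or complex event series.

Origins use outgroup parsimony. For a genome-A breakpoint $B_h$ with genome-B
partners $B_{m1}, B_{m2}$: origin *human* (genome-A lineage) iff $B_h$
overlaps an A-outgroup breakpoint and neither partner overlaps a B-outgroup
breakpoint; *mouse* iff the complementary pattern holds with both partners
overlapping; otherwise *unknown*. Overlap means an intersection of at least
1 bp — the threshold is a design choice, since the source analyses state
"overlaps" without quantifying. A pair inherits an origin only when both
members agree on a non-unknown origin. Telomere sentinels are zero-length, so
they can never be assigned an origin; consequently a reciprocal pair with a
telomeric member is reported `unknown` even when produced by a single event
in a known lineage. This is the same behaviour real telomere "breakpoints"
would show and the oracle-equivalence tests assert lineage recovery only for
pairs with two non-telomeric members.

Two conventions were genuinely open and are fixed as follows: a mouse
breakpoint's two human orthologous breakpoints are located by block-extremity
orthology (robust to flanking-block inversion), and pairs are stored with
members ordered by (chromosome, start) for determinism. Telomere–telomere
pairs are admissible and flagged via the member coordinates.

## Hi-C processing and the SD correction

Each autosome is tiled with 1-Mb windows (the last window may be short);
windows with assembly-gap fraction strictly above 0.5 are discarded — the
boundary case 0.5 is retained, since the filter is "more than 50 percent".
The contact estimate for a window pair is the raw count of read pairs with
one end in each window ($NR$). Genomic distance is the difference of window
start positions in Mb; the convention (starts rather than midpoints) is a
documented choice, immaterial at fixed window size. Self-pairs (distance 0)
are retained in the table but excluded from every log-distance analysis.

Short multi-mapping reads randomly assigned among near-identical SD copies
inflate apparent long-range contacts between loci carrying copies of the
same duplication. The correction discards every read with at least one end
inside an annotated SD ($SDR$) and rescales the remainder under the
assumption that read density inside an SD matches its surroundings:

$$NRCSD = \frac{NR - SDR}{(1 - FSD_1)(1 - FSD_2)}$$

with $FSD_k$ the SD fraction of window $k$. **Caveat:** the source text for
this correction breaks off mid-sentence before the formula; the form above is
adopted as the unique simple estimator consistent with the stated uniformity
assumption, and all downstream behaviour (identity on SD-free pairs,
monotonicity in $NR$, undefined when a window is entirely SD) follows from
it. When only binned counts are available, $SDR$ can only be estimated as
$NR\,(1-(1-FSD_1)(1-FSD_2))$, which makes the correction algebraically the
identity — the output is therefore labelled with the SDR mode, and read-level
(or simulator-provided) SD annotation is required for the correction to do
anything. Gap content is handled only by the 50% locus filter; no additional
rescaling by gap fraction is applied.

## The analysis table and the model family

Per-locus covariates are gene density (covered fraction of the genic union)
and DNaseI sensitivity (cleavage densities accumulated per window from a
fixed-step track). Pair covariates are products of the two per-locus values
($Gcov$, $DNase$). A locus pair is flagged ($BP = 1$) iff some breakpoint
pair has one member assigned to each window; assignment uses the breakpoint
midpoint by default (breakpoint regions of tens of kb can straddle window
boundaries; an any-overlap mode is available). All logarithms are natural
logs. Rows whose required log is undefined (zero corrected count, zero gene
density) are marked excluded per analysis rather than deleted; zero-count
pairs are excluded from the log-linear fits but still contribute to the
resampling test, which averages raw counts.

The embedded models, fitted by ordinary least squares on intra-chromosomal
pairs at $GD \ge 1$ Mb:

- M0: $\log RC = \mu + a \log GD$
- M1: M0 $+\, b\,BP$
- M2: M1 $+\, c \log GD \cdot BP$
- M3–M5: distance + $\log Gcov$, then $+BP$, then $+\log Gcov \cdot BP$
- M6–M8: distance + $\log DNase$, then $+BP$, then $+\log DNase \cdot BP$

Nested comparisons use the extra-sum-of-squares F statistic
$F = \frac{(RSS_s - RSS_b)/\Delta df}{RSS_b/df_b}$; the test suite
cross-checks it against `stats::anova`. Normal-theory p-values rest on
Gaussian, independent errors — an approximation whose tail behaviour
motivates the resampling test below. Inter-chromosomal pairs, which have no
genomic distance, are compared flagged-vs-unflagged by a two-sided Wilcoxon
rank-sum test on raw corrected counts.

## The stratified resampling null

Locus pairs are partitioned into strata: nine equal-width classes of
$\log GD$ between the observed intra-chromosomal minimum and maximum
(left-open, right-closed; the range and boundary conventions are data-driven
choices, unstated in the source) plus an `inter` class; optionally
gene-density classes with thresholds $\{0\}, (0,0.1], (0.1,0.25], (0.25,1]$
on $Gcov$; optionally DNase pair classes rich–rich / rich–poor / poor–poor,
with per-locus rich/poor split at the median per-locus signal (no threshold
is given in the source; the median is the package's choice). Each replicate
draws, per stratum, as many unflagged pairs (without replacement) as that
stratum holds flagged pairs, and records the pooled mean count; 500
replicates by default. The empirical p-value is one-sided with the
small-sample correction, $p = (1 + \#\{\bar x_{null} \ge \bar
x_{obs}\})/(B+1)$ — sidedness and estimator are package choices (the
alternative of interest is *closer* in 3D), and the observed mean is pooled
directly rather than per-stratum-then-pooled.

## What the simulator states, and what a green test establishes

The generator is a stated world, not a tuning dial:

- **Rearrangements**: signed permutations of equal-length blocks on one
  chromosome; the outgroup keeps the ancestral order. Inversions reverse a
  contiguous run; a translocation excises one block and reinserts it
  elsewhere (transposition-style three-breakpoint patterns arise from it).
  Blocks are separated by positive spacers so breakpoint regions have
  extent; per-lineage event counts are capped at `n_blocks - 1`.
- **Contacts**: $count = \mathrm{round}(\exp(\mu + a\log GD + BP(b + c\log
  GD) + \varepsilon))$, $\varepsilon \sim N(0, \sigma)$, with defaults
  $\mu = 6$, $a = -0.8$, $b = 0.728$, $c = -0.254$ taken from the printed
  fitted estimates of the real-data analysis, and $\sigma = 0.5$ (no
  residual scale is printed; 0.5 reproduces count dispersions of the right
  order at these means). Rounding, not truncation, maps the continuous model
  to counts. Inter-chromosomal pairs are Poisson with mean 5 (the reported
  average; no generative form is stated, the Poisson is a stand-in).
  Self-pairs draw from the decay model at an effective 0.5 Mb — the mean
  intra-window separation is of that order — so that the dominant Hi-C
  diagonal exists; they are excluded from every analysis downstream.
- **Tracks**: SD fraction and gene density are Beta (defaults emulating ~5%
  SD content and ~40% genic coverage), DNase log-normal; at
  breakpoint-containing windows the first Beta shape (or log-normal scale)
  is multiplied by an enrichment factor, so factor 1 reproduces the
  background distribution exactly.
- **SD bias**: a read end falls inside the SD portion of its window with
  probability $FSD$ (the same uniformity assumption the correction makes)
  and is then relocated to a random window sharing those SD copies with the
  configured probability, landing in the partner's SD region. Total count is
  conserved and the exact per-pair $SDR$ is emitted.

What the simulator does **not** emulate: nucleotide sequence, restriction
fragments, ligation artifacts, copy-number variation, or any Hi-C bias other
than SD relocation. A green end-to-end test therefore establishes that the
pipeline's logic is faithful to its own model — not that the model captures
real chromatin.

Power and calibration fixtures use $b = 0.728$ with $c = 0$: the criterion
under test is the main breakpoint effect, and with synthetic flags placed
uniformly over all distances the printed negative interaction would cancel
the main effect at large $GD$ — a property of synthetic flag placement (real
breakpoint pairs concentrate at short distances), not of the tests.

## Numerical and procedural choices

- Natural logarithms throughout (no base is ever stated in the source).
- Oracle-equivalence testing enumerates all single events for 3–8 blocks and
  all ordered two-event sequences at 4 blocks, plus seeded random two- and
  three-event scenarios up to 8 blocks; the full ordered three-event space is
  combinatorially out of reach of the test budget.
- Distance-class boundaries are computed from the data at hand; a degenerate
  range collapses to one class.
- Rank-deficient designs and a constant $BP$ column are rejected with the
  offending term named, rather than silently dropped.
- The resampling test consumes randomness stratum-by-stratum in a fixed
  order, so results are bit-reproducible given the seed and invariant to
  order-preserving relabelling of strata.
- All randomness flows from explicit seeds; every simulation helper restores
  the caller's RNG state.

## Known limitations

The printed real-data statistics (e.g. the headline M1-vs-M0 p-value, the
294 flagged locus pairs, the 373 breakpoints) depend on the original Hi-C
dataset and genome assemblies and are not reproducible here; the printed
coefficients serve as generative defaults instead. Breakpoint-coordinate
refinement by sequence alignment (the second step of the detection method
used on real data) is out of scope: refined breakpoint coordinates are an
input. No matrix balancing is performed — the source analysis predates and
does not use it.
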