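---
title: "Calling long tandem repeats in noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling long tandem repeats in noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

## The problem

Tandem repeat expansions longer than a kilobase - disease-associated
short tandem repeats, satellite arrays, centromeric monomers - are
essentially invisible to short-read sequencing, and long reads that do
span them carry 10-20% error. At that error rate an aligner sees a
substitution, insertion or deletion every five to eight bases, so naive
self-alignment of a read cannot resolve the repeat structure.
`tandemscan` exploits the one thing such repeats have in abundance:
copies. A repeat with hundreds of approximate copies of a 3-200 nt unit
shares many short, error-free k-mers between copies even when every
individual copy is corrupted. The caller works read by read, without a
reference genome, and reports for each repeat its interval, consensus
unit, copy number, score and identity.

## Boundary detection from k-mer frequency profiles

Positions in a read are inter-base and 0-based: position $i$ lies
between the $i$-th and $(i{+}1)$-th character, so $R[a,b]$ has length
$b-a$. For a window $W_i^w = R[i, i+w]$ the k-mer frequency vector
$\vec f_i^w$ counts all $4^k$ k-mers inside it (k-mers are coded as
quaternary integers with A,C,G,T $\mapsto$ 0,1,2,3). Two normalized
similarities between equal-sized windows are available:

* Manhattan: $\xi(\vec f, \vec h) = 1 - \lVert\vec f - \vec h\rVert_1 / 2w$,
* Pearson: $\xi(\vec f, \vec h) = (\rho(\vec f,\vec h) + 1)/2$.

Both behave comparably in our benchmarks; Manhattan is the default. A
zero-variance profile (homopolymer window) has no defined correlation;
its Pearson similarity is fixed at 0.5, the "no correlation" midpoint,
so the scores below degrade smoothly on low-complexity flanks rather
than spiking.

With $S(i,j)^w$ the similarity of the windows at $i$ and $j$, the
boundary statistics are

$$B(i,w) = S(i,i+w)^w - S(i-w,i)^w, \qquad
  E(i,w) = S(i-2w,i-w)^w - S(i-w,i)^w = -B(i-w,w).$$

At the start of a repeat the two windows right of $i$ both lie inside
the repeat and correlate strongly while the straddling pair does not,
so $B$ peaks; $E$ mirrors it at the end. A start is accepted where $B$
is a local maximum within distance $w$ (leftmost position on ties, for
determinism) and reaches the floor `theta_b`; the end is the closest
position at least $b + w$ further right where $E$ is a local maximum.
After an emission the scan resumes at $e$, so several repeats per read
are found. Local maximality alone fires on random fluctuation -
especially at the smallest windows, where the profiles hold only a
handful of k-mers - hence the configurable floor (default 0.2) and a
per-pattern cap on candidates (default 12, strongest by
`peak_b + peak_e`; genuine boundaries show both peaks, noise rarely
does).

A repeat of span $L$ with unit $u$ is detectable at $(k, w)$ when
$2|u| \le w \le L/2$ (windows hold at least two copies, the repeat
holds at least two windows) and $k \le |u| < c\,4^k$ with $c = 1/4$
(the unit is characterized by a sparse subset of the $4^k$ k-mers).
Sampling $w$ geometrically covers all unit sizes up to ~500 nt and
spans below $10^5$ with twenty patterns: $(5, 5\cdot 2^l)$ for
$l = 0..11$, $(3, 5\cdot2^l)$ for $l = 0..4$, $(1, 5\cdot2^l)$ for
$l = 0..2$. Larger $k$ would be knocked out by errors: at a 20%
per-base error rate a k-mer is error-free with probability $0.8^k$
(51.2% at $k=3$), so short k-mers carry the signal.

Because window profiles update in constant time per shift and the
similarity statistics update incrementally with them, a full scan is
linear in read length for each pattern.

## Unit assembly on a de Bruijn graph

For each candidate range (padded by $w/2$ per side - the scan is only
$w$-accurate) the k-mer de Bruijn graph is built for each $k$ in a
sweep (default 2..15). Frequent k-mers belong to error-free stretches
of unit copies; the consensus unit is a heavy cycle. From the most
frequent k-mer $\kappa$, frontiers $next^h(\{v\})$ - the successors of
maximal frequency over the whole frontier - are expanded until the
frontier is empty (failure), a singleton, or contains $\kappa$ (the
cycle closes). Paths through multi-step frontiers are reconstructed by
parent pointers, preferring the predecessor of maximal frequency
(ties: smallest code). If every forward search fails the graph is
traversed backwards. Ties for the most frequent k-mer are each tried
and the heaviest cycle kept; a graph whose modal count is 1 carries no
tandem signal at that $k$ and is skipped, and degenerate tie sets are
capped at 64 start vertices.

Candidate units from different $k$ are compared by the wraparound
alignment score $\sigma$ against a window at the center of the range
(the padding at the edges is putative flank; a tandem repeat is
homogeneous, so a central window holding many copies ranks the sweep
like the full span at a fraction of the cost). Ties prefer the shorter
unit - this is what resolves a doubled unit toward its primitive root -
then the smaller $k$. Cycles longer than half the range, or than
`max_unit` (default 500 nt, the regime the detection grid is built
for), are rejected.

## Consensus repair

Two repair stages run after assembly, both on the *trimmed* repeat
interval (see below) rather than the padded range - rows of random
flank forced through the unit concentrate spurious indel counts on
specific columns and would mislead the tests.

**Frequency transitions.** Scanning the k-mer frequencies along the
cyclic unit, an embedded error shows as a run of low-frequency k-mers
(below half the median, by default) flanked by sharp rises. At each
suspect position nine operations are scored - no-op, three
substitutions, deletion, four insertions - by the summed graph
frequency of the k k-mers covering the edited locus, and the best is
applied (no-op wins ties). When the modal frequency is below 10 the
stage is skipped entirely: for a low-copy repeat a rare k-mer may
simply be correct, and frequency evidence cannot tell the difference.

**Column tests.** The unit is wraparound-aligned to the repeat
interval; the traceback induces a multiple alignment of unit copies.
For each unit position the counts $n_j^a$ (base $a$ aligned at $j$),
$del_j$ and $ins_j^a$ are tested against the binomial upper tail
$p(K) = \sum_{k\ge K} \binom{d}{k} (\epsilon/4)^k (1-\epsilon/4)^{d-k}$
at depth $d$, with $\epsilon$ the observed error rate of the
alignment. There are $8|u|$ hypotheses (3 substitutions, 1 deletion, 4
insertions per position); an edit is applied when
$p(K) \le 1\%/(8|u|)$ (Bonferroni), at most one edit per position per
pass, re-aligning until fixpoint (pass budget 5). Two guards: columns
of depth below 2 are never edited, and an edit needs support from
$K \ge \max(3, 0.3d)$ rows - a genuine consensus error appears in
nearly every copy, while alignment edge artifacts (the terminal
partial copies) contribute a systematic event or two per column that
would otherwise reach formal significance whenever the estimated
$\epsilon$ is very small.

## Wraparound alignment, boundaries, copy number

The unit is scored against an interval by wraparound dynamic
programming: DP columns are unit positions and wrap from the last
column to the first, aligning the interval to an arbitrary substring
of $u^\infty$ at unit edit costs. Both terminal phases are free: a
repeat may begin and end with a partial copy, and a de Bruijn cycle
has no canonical start, so the score is exactly invariant under
rotation of the unit. The score is $\sigma = (e-s) - \delta$ with
$\delta$ the Levenshtein distance, i.e. matches minus differences.
Within-row cyclic dependencies (deletion runs crossing the wrap) are
resolved with a second relaxation pass; a run of $|u|$ deletions
returns to the same state at higher cost, so one wrap suffices for
optimality.

Row minima give the prefix scores $\sigma(u, R[s,x])$ for all $x$ in
the same pass. They serve twice:

* **Boundary trimming.** The padded range is cut at the argmax of the
  trimming score $x - 3\delta_x$ (match $+1$, difference $-2$),
  forward for the end and on the reversed strings for the start, ties
  resolved toward the tighter interval. Plain $\sigma = x - 2\delta_x$
  is unsuitable here: random sequence sits at $\delta \approx 0.48$
  per base against the tandem language of a short unit, so $\sigma$
  *rises* slowly through flank and drifts outward, while the
  3-weighted score falls at about $-0.44$ per flank base and rises
  inside the repeat. At zero error the trim recovers the planted
  boundaries exactly; the residual uncertainty is at most about one
  unit (the alignment cannot locate a boundary inside a partial copy).
* **Split points.** For chained calls that still overlap,
  $o(x) = \sigma(u_i, R[s_i,x]) + \sigma(u_j, R[x,e_j])$ is maximized
  over the overlap (smallest $x$ on ties) from the stored forward
  prefix array of the left call and a reversed alignment of the right
  call.

The traceback also yields the copy number (unit traversals of the
optimal path, a real number; reports round it) and the identity
(matches over alignment columns). Identity and the LCS-based
similarity of the evaluation module answer different questions and are
exposed under distinct names.

## Chaining

Each range that survives scoring yields a call $T = (s, e, u, \sigma)$;
calls whose $\sigma$ is below 0.2 of their span are dropped as junk.
Overlapping calls are resolved by pseudo-disjoint chaining: $T_i \to
T_j$ is allowed when the overlap is below $l = 10$ nt, which keeps the
problem an $O(n \log n)$ weighted interval chain (sort by end, best
predecessor via a running prefix maximum) instead of the $O(n^2)$
formulation that re-scores every overlap. Calls spanning less than $l$
are excluded up front: the overlap notion presumes
$s_i < s_j < e_i < e_j$, and an interval shorter than the tolerated
overlap could nest inside another while formally satisfying the
predicate. Residual overlaps of the optimal chain are then cut at
their optimal split points, scores recomputed on the trimmed intervals
(never higher than before), and the final records are disjoint and
sorted. Duplicate intervals from different grid patterns keep the best
$\sigma$; near-coincident candidate ranges (mutual overlap at least
80% of the wider) are assembled only once, and ranges almost entirely
inside already-called intervals are skipped.

## The synthetic benchmark

`make_truth()` plants a uniformly random *primitive* unit (a unit that
is itself a perfect power would make "the" unit ambiguous) repeated a
set number of times, flanked on each side by random sequence of the
same length as the repeat, so boundary detection is genuinely tested
on both sides. `apply_errors()` is an i.i.d. per-base channel:
substitution to a different base, deletion, and insertion of a random
base after a position, each at its own rate. Presets: `nanopore_like`
(10%/5%/5% substitution/insertion/deletion), `accurate` (1%/0.5%/0.5%,
~2% total), `pacbio_like` (5%/6%/4%, a stylized insertion-biased
profile), `none`. Truth coordinates are mapped through the channel
into read space. All randomness flows from a single seed; the same
seed reproduces the read set byte for byte.

What the generator does *not* emulate: burst errors, junk/chimeric
inserts, homopolymer-length artifacts, or quality-score structure of
real instruments (qualities are ignored throughout). Passing the
benchmark therefore demonstrates recovery under homogeneous noise of
realistic magnitude, not robustness to instrument-specific error
bursts; the published sensitivity curves produced with a full read
simulator are not comparable in absolute terms.

Evaluation is rotation-aware: a predicted unit matches the truth when
some cyclic rotation reaches global-alignment identity $\tau$ (a cycle
has no canonical start, so rotation invariance is the only defensible
reading of "perfect prediction"; $\tau = 1$ demands an exact
rotation). The repeat-length error is
$|\mathrm{len}_{pred} - \mathrm{len}_{true}| / \mathrm{len}_{true}$.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `similarity` | `"manhattan"` | window similarity measure |
| `theta_b` | 0.2 | floor on accepted B peaks |
| `max_cand_per_pattern` | 12 | strongest candidates kept per (k, w) |
| `k_range` | 2..15 | de Bruijn k sweep |
| `max_unit` | 500 nt | unit length cap |
| `min_sigma_frac` | 0.2 | junk filter, sigma over span |
| `min_span` | 10 nt | minimal reported span (>= overlap limit) |
| `overlap_limit` | 10 nt | pseudo-disjoint chaining tolerance |
| `low_frac`, `min_modal` | 0.5, 10 | transition-repair triggers |
| `alpha_total` | 0.01 | family-wise level of the column tests |
| `max_pass` | 5 | pass budget per repair stage |

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic
data generated at test time: the zero-error recovery check uses one
read per cell of the full 7 x 5 unit-length/copy-number lattice
(reads up to 120 knt); the 2%-error sensitivity check uses 50 reads
per cell of the reduced 7 x 3 lattice (1050 reads); oracle
equivalences use 500 random unit/region pairs (regions up to 60 nt)
and 200 random chaining instances (up to 10 intervals). These sizes
make each property statistically meaningful while keeping a full run
in the minutes range on one core.

## Known limitations

* Higher-order repeat structure (e.g. alpha-satellite HORs, where a
  large unit is itself a train of monomers) is reported at the monomer
  scale; the heavier higher-order cycle is not recovered.
* Very long units with few copies (unit near `max_unit`, under ~10
  copies) sit at the edge of both detection conditions and repair
  guards; sensitivity degrades there first.
* The caller assumes one strand of one read; no reverse-complement
  canonicalization is applied, by design.
* FASTQ qualities are read and discarded; no quality-aware weighting.
* Memory for the traceback alignment is capped (~1 GB of int cells);
  on longer intervals column counts are collected from a prefix of
  the interval and copy numbers extrapolated proportionally.
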