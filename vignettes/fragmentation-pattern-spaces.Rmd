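---
title: "Fragmentation pattern spaces: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentation pattern spaces: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragpattern)
```

## The model

RNA-seq coverage is routinely judged against an implicit ideal of uniformity:
if nothing biased the library, every position of a transcript should be
sequenced equally often.  `fragpattern` works out what that bias-free
expectation actually is when fragmentation is *exhaustive* — the regime of
low-input and single-cell protocols, where most fragments of each molecule
end up in the library and fragment placements on one molecule are therefore
strongly dependent.

A molecule of length $T$ (bp) is fragmented into non-overlapping fragments
with lengths drawn from a fixed set $F_1 < \dots < F_k$.  Placement is
maximal: every gap — before the first fragment, between fragments, after the
last — is strictly shorter than $F_1$, so no further fragment fits.  Each
such placement is a *fragmentation pattern*; the *pattern space* is the set
of all distinct patterns, and the model's single probabilistic assumption is
that **all patterns are equally likely**.  There is no sequence composition,
GC or primer bias, and no isoform structure: the model is deliberately
independent of the transcript sequence.

The number of patterns satisfies

$$FP(l) \;=\; \sum_{i=0}^{F_1-1}\sum_{j=1}^{k} FP(l - F_j - i),
\qquad l \ge F_1,$$

with $FP(l) = 1$ for $0 \le l < F_1$ (the empty placement: a transcript
shorter than every fragment has exactly one, trivial, pattern) and
$FP(l) = 0$ for $l < 0$.  The recursion is also valid at $l = F_1$, where it
agrees with the one-fragment base case; the package applies it from
$l = F_1$ upward so that weighted masses (below) remain correct there.

Expected coverage profiles sum a per-fragment *coverage vector* $C$ of
length $F_j$ over all fragments of all patterns:

* **SPP** (starting-point profile): $C = (1, 0, \dots, 0)$;
* **FCP** (fragment coverage profile): $C = (1, \dots, 1)$;
* **RCP** (read coverage profile): ones over the first and the last
  $\min(R, F_j)$ bases, added — so paired reads that overlap
  ($F_j < 2R$) produce values of 2, and $F_j \le R$ gives a constant 2
  across the fragment.

## The factorization behind the recursion

A naive vector recursion over suffixes is infeasible for ranged length sets
(hundreds of lengths at $T$ around $10^3$).  The package instead uses a
factorized form.  Prefix fillings of $[0, p)$ whose every gap — including
the one abutting position $p$ — is shorter than $F_1$ are mirror images of
suffix patterns, so the number of patterns containing a fragment of length
$F_j$ starting at $p$ is

$$M_{j,p} \;=\; FP(p)\cdot FP(T - p - F_j).$$

All three profiles are interval accumulations over this per-length start
matrix (`start_matrix()`), giving $O(T\,(k + F_1))$ overall.  The placement
of the $FP$ factors is enforced by the brute-force oracle
(`enumerate_patterns()` / `profile_from_patterns()`), to which the dynamic
program is held exactly equal on an exhaustive sweep of small models in the
test suite.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `transcript_length` ($T$) | transcript length | bp | — |
| `lengths` ($F_1 < \dots < F_k$) | allowed fragment lengths | bp | — |
| `read_length` ($R$) | bases sequenced from each fragment end | bp | — (only for RCP) |
| `weights` ($W(F_j)$) | observed/expected length-frequency ratio | dimensionless | none (unweighted) |
| `weight_mode` | how weights act | — | `"contribution"` |
| `molecules` ($M$) | molecules fragmented | count | — |
| `pcr_cycles` | uniform amplification $2^{\text{cycles}}$ | cycles | 15 ($\times$32,768) |
| `n_fragments` ($S$) | fragments sequenced | count | 100,000 |

$R$ matters only through $\min(R, F_j)$; $2R = F_j$ makes the RCP identical
to the FCP, which the suite asserts at $T = 1000$, $F = 200$, $R = 100$.

## Weighting: two modes, one default

Empirical insert-size distributions are bell shaped while the pattern
space's own length distribution is L shaped.  The weight
$W(F_j) = \text{observed}(F_j)/\text{expected}(F_j)$ imposes the former on
the latter.  Two readings of "weighted profile" are both defensible, so both
are implemented:

* **contribution** (default): patterns stay equiprobable; each fragment's
  coverage vector is scaled by $W(F_j)$.  This is the arithmetic under which
  expected frequency $\times$ weight, renormalized, reproduces the observed
  length distribution exactly — the identity the test suite checks to
  1e-9.
* **pattern**: each whole pattern is reweighted by the product of its
  fragments' weights.  This is the reading the simulator needs, because
  sampling requires a probability distribution over patterns (contribution
  mode does not change which patterns occur).  `sample_patterns()` therefore
  always uses pattern-mass semantics when weights are present.

Zero-weight lengths are kept in the model: in contribution mode they still
shape the pattern space (their patterns exist but contribute no coverage),
while in pattern mode they annihilate every pattern containing them.
Duplicate lengths are rejected.

The weight pipeline interpolates unobserved interior lengths linearly on
*counts* (via `zoo::na.approx`), before normalization; endpoints are never
extrapolated, and model lengths outside the observed range are dropped with
a message (their weights are undefined).  Interior interpolation on counts
versus frequencies is equivalent after normalization; the order is fixed for
determinism.

## Numerical regimes

Pattern counts grow exponentially in $T$, so three arithmetic paths share
the same recursion:

* **plain doubles** — the default; integer-exact below $2^{53}$, which
  covers every profile the test suite compares bit-for-bit;
* **log-space (logsumexp)** — the automatic fallback when doubles would
  overflow; raw matrices/profiles then carry a `log_scale` offset, and
  normalized profiles remain exact to machine precision;
* **exact big integers** — a minimal base-$2^{15}$ limb representation
  (`R/bigint.R`); `count_patterns()` always uses it (counts are exact at any
  magnitude), and `exact = TRUE` runs start matrices and unweighted profiles
  on it end to end, using the sliding-window form
  $S(l) = S(l-1) + G(l) - G(l-F_1)$, $G(m) = \sum_j FP(m - F_j)$.

The contract, asserted in the suite over singleton and multi-length models
up to $T = 60$: the floating path agrees with the exact path to relative
error $\le 10^{-9}$.  Exact mode is intended for validation at modest $T$;
the floating path is the performance path.  Degenerate inputs are defined,
not special-cased: $T < F_1$ yields $FP = 1$ and an all-zero profile with a
warning, and all-zero profiles refuse normalization (flag unchanged) rather
than dividing by zero.

Coordinates are 0-based half-open internally; every file format written by
the package is 1-based (TSV) or 0-based half-open (bedGraph), as each
format's convention dictates.

## The simulator

One simulated experiment is: draw one pattern per molecule, pool the
fragments, multiply every multiplicity by exactly $2^{\text{cycles}}$
(perfectly efficient, unbiased PCR — an idealization, with no duplicate or
efficiency model), then sequence by drawing $S$ fragments *without
replacement* from the amplified pool.

Pattern sampling is sequential: at remaining suffix length $l \ge F_1$ the
pair (gap $g$, length $F_j$) is drawn with probability
$W(F_j)\,\mathrm{mass}(l - g - F_j)/\mathrm{mass}(l)$.  The telescoping
product of these conditionals makes every unweighted pattern land with
probability exactly $1/FP$ — the test suite confirms this with a
chi-squared goodness-of-fit test on an enumerated 7-pattern space at 70,000
draws — and reproduces the starting-point and position-specific length
marginals of the pattern space by construction.

Two simulator choices the model description leaves open are fixed here: $S$
defaults to 100,000 and is always explicit in a `simulation_config`; and
sequencing consumes fragments (without replacement, a multivariate
hypergeometric draw).  With uniform amplification the difference from
multinomial sampling is negligible at the default depths, but the choice is
fixed for reproducibility.  Amplified pools can exceed integer range
(e.g. 50,000 molecules $\times$ ~9 fragments $\times$ 32,768
$\approx 1.5\times10^{10}$), so the draw is realized by sampling distinct
pool indices uniformly (`sample.int`, exact up to $2^{53}$) and mapping them
to fragment species through cumulative boundaries — exactly the
hypergeometric distribution, at any pool size.

All stochastic functions draw from R's global RNG in documented order;
identical seed and configuration give bit-identical libraries and profiles.

## The estimator

Because exhaustive fragmentation couples the fragments of a molecule, the
dispersion of an observed SPP carries information about how many molecules
produced it.  The estimator turns SPPs into ECDFs over the $T$
sum-normalized position values and compares them with

$$d(E_m, E_d) \;=\; \sum_{i=1}^{n-1}
\bigl(E_m(x_i) - E_d(x_i)\bigr)^2 (x_{i+1} - x_i),$$

over the sorted unique union $x$ of both supports, with right-continuous
step evaluation.  The upper limit $n-1$ means the largest merged value
contributes no interval; this is implemented exactly as written.

Open choices, fixed as follows:

* The reference ECDF of a repetition set *pools* all repetitions'
  normalized position values into one ECDF (rather than averaging
  per-repetition ECDFs or summarizing per-repetition distances); one rule,
  applied everywhere.
* ECDFs include all $T$ positions, including structural zeros such as the
  final $F-1$ positions where no fragment can start.  Excluding them would
  discard exactly the positions whose zero counts are most informative at
  low molecule numbers.
* The default molecule grid is 43 log-spaced integers from 50 to 50,000
  (`molecule_grid()`), overridable.
* Argmin ties are broken toward the smaller molecule number (a conservative
  copy-number call) and flagged.

## The synthetic insert-length generator

`synthetic_length_histogram()` produces a deterministic discretized,
truncated normal over an integer length range (default mean 151 bp, sd 80
bp, range 100–960 bp, $10^6$ fragments; the copy bundled at
`inst/extdata/synthetic_insert_lengths.tsv` is generated by exactly this
call).  It emulates the one feature of real insert-size data the weighting
machinery consumes — a smooth, unimodal, bell-shaped length distribution
with a defined support — and nothing else: no mapping noise, no multimodal
size-selection artifacts, no chimeric inserts, no reference-specific
structure.  Tests passing on it therefore demonstrate the correctness of
the interpolation/weighting arithmetic, not robustness to messy real
libraries; real alignments enter through `lengths_from_alignments()`
(SAM/BAM via Rsamtools, or any two-column TSV).

## Validation problem sizes

The simulation studies in the test suite and in `scripts/acceptance.R` use
$T = 1000$ with a single fragment length of 100 bp and sequencing depth
$S = 20{,}000$: large enough that every qualitative claim is comfortably
resolved, small enough to keep the full studies in the minutes range.

* **Variability trend**: 20 repetitions at
  $M \in \{50, 500, 5000, 50000\}$; the mean per-position standard
  deviation of sum-normalized SPs must decrease strictly in $M$
  (Spearman $\rho = -1$ over the four points).
* **Copy-number recovery**: reference grid
  $\{50, 150, 500, 1500, 5000\}$ with 20 repetitions per value, 20 test
  profiles per value; exact recovery is required in at least 90% of the 100
  trials (observed: 100% in the runs the acceptance script performs).
* **Convergence**: sequencing *all* fragments without amplification, the
  total-variation distance between simulated and expected normalized SPP
  decreases strictly over $M \in \{500, 5000, 50000\}$ and falls below
  0.03 at $M = 50{,}000$.  The bound reflects the sampling floor: with
  ~9 fragments per molecule, $M = 50{,}000$ yields ~450,000 starting
  points over 1000 positions, for an expected TV near
  $\tfrac12\sum_p \mathbb{E}|\hat p - p| \approx 0.019$; no implementation
  could do better at this depth.

## Known limitations

* One transcript, one length distribution: no isoform mixtures, no
  multi-reference aggregation, no sequence-dependent fragmentation
  chemistry.
* The estimator assumes the test profile was generated under the same
  $(T, F, R, S)$ conditions as the reference set; there is no
  model-mismatch diagnostic beyond the distance table, and no confidence
  interval.
* The exact big-integer path is pure R and intended for counting and for
  validation-scale profiles; ranged length sets in the hundreds at
  $T \sim 10^3$ count exactly in seconds, but exact *profiles* at that
  scale are not the design point.
* PCR is perfectly uniform by construction; amplification never changes
  normalized profiles (asserted in the suite), so cycles matter only for
  pool-size bookkeeping.
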