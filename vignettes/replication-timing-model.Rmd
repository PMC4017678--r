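---
title: "A mechanistic model of DNA replication timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of DNA replication timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(replitimer)
```

## The model and its assumptions

`replitimer` simulates genome replication as a population of independent
cells, each cycling between a non-replicating G state and a replicating S
state. The model is deliberately reductionist: it keeps only the
components needed for the *timing* program and omits molecular detail
(licensing chemistry, fork stalling, replication factories, variable fork
speed).

The state of one cell on one chromosome territory of $B$ bins (bin width
$w = 500$ bp by default) is a replicated-bin mask, a set of replication
bubbles, and a pool of $N$ rate-limiting factors. Each S step:

1. **Elongation.** Every bubble advances each unblocked fork edge by one
   bin. An edge that would enter replicated territory or run off the
   chromosome end blocks; a bubble with both edges blocked dissolves and
   its factor returns to the pool. Collisions are therefore *observed*
   during an advancement attempt — a bubble that finishes replication on
   the final step of S is still engaged when the cycle ends, which is why
   the conservation law asserted throughout is free + engaged $= N$, not
   "all free at completion".
2. **Initiation.** Each factor that was free at the start of the step
   makes one attempt: it selects one bin uniformly at random among the
   *unreplicated competent* bins (those with positive IPLS value) and
   engages there with probability IPLS($x$). Engagement replicates the
   selected bin immediately; elongation of the new bubble starts the
   following step.

The probability of initiating at bin $x$ at time $t$ is then exactly the
product of the uniform selection probability among unreplicated competent
sites, the landscape value IPLS($x$), and the number of free factors.
Selection over *competent* bins (rather than over all bins, replicated or
not) was a genuine design choice: it realizes that product form exactly,
it preserves the dependence of the effective initiation rate on the local
density of unreplicated sites (the free-factor count and the shrinking
competent pool still make the global rate time-dependent, rising through
S phase before collapsing at the end — see `initiation_rate()`), and it
makes the single-origin configuration deterministic, which gives the
engine a closed-form oracle: a lone zero-background origin at 0-based bin
$m$ on $B$ bins completes S in exactly $1 + \max(m, B-1-m)$ steps.

Each chromosome is simulated as an independent territory with its own
factor pool (the fork-count scaling below was fitted per chromosome); a
genome-shared pool is not the default. Per-cycle RNG streams derive from
the master seed and the cycle id, so populations are reproducible and
order-independent.

## Initiation probability landscapes

`build_ipls()` scales raw per-bin amplitudes by $x/\max(x)$ — the
landscape is invariant to the overall scale of the input — applies an
amplitude map (identity, square, square root, or constant-on-sites) and
floors the result at a background probability (default $10^{-4}$;
0 restricts initiation entirely to annotated sites). The amplitude map is
applied after scaling and before flooring so that square/sqrt act on
$[0,1]$; the order is a package choice. An all-zero raw track is a
degenerate landscape and errors at build time.

Builders cover the inputs a practitioner would reach for: BED scores
(`ipls_from_scores()`, binning by `max` by default because a peak score
is a site property rather than a density — `mean` is available via the
`mode` flag), TSS annotations (constant probability 1 per TSS bin), GC
fraction, CpG observed/expected
$(\#\mathrm{CG} \cdot \ell)/(\#\mathrm{C}\,\#\mathrm{G})$, and
G-quadruplex motifs. The G4 pattern is the canonical
`G{3,}(loop 1-7)G{3,}(loop 1-7)G{3,}(loop 1-7)G{3,}` with its C-run
mirror for the minus strand, scanned greedily and non-overlapping per
strand; run and loop bounds are parameters. The per-bin raw value is the
maximum motif length overlapping the bin, so longer motifs get higher
initiation probability.

Reduced landscapes: `subtract_overlap()` removes records sharing at least
one base with another annotation (a `slop` flag widens the other set
first; the default is 0 because "co-localized" has no canonical
distance), and `subtract_random()` removes an equal number of uniformly
chosen records as the size-matched control. `fuse_translocation()` builds
the landscape of a derivative chromosome; a junction bin straddling the
breakpoint takes the value of the donor covering the majority of the bin,
so no probabilities are fabricated.

## Flow-sorter emulation and gate optimization

DNA content maps affinely onto the replicated fraction, so gates live on
$(0,1)$: G gates are G−1 strictly increasing boundaries, and a snapshot
falls in the half-open interval $(b_{g-1}, b_g]$. The timing value of a
bin is the count-weighted mean gate index $\sum_g g\,c_g / \sum_g c_g$,
normalized so that it is bounded by $[1, G]$; bins never observed
replicated are missing. Snapshots are taken on a fixed absolute-time
cadence (default every 10 steps — the cadence is a technical parameter,
not a biological one) and the geometric G wait (default rate 1/500 per
step, giving G and S comparable expected lengths and hence an
asynchronous population) randomizes the cadence phase across cycles.
Incomplete cycles (those hitting the safety cap of
$50\lceil B/2N \rceil$ steps) are excluded from profiles and counted.

`optimize_gates()` anneals the boundary vector against an empirical
profile under the Euclidean distance over bins defined in both profiles.
Proposals perturb one uniformly chosen boundary by a
$\mathcal{N}(\text{old}, \sigma)$ draw with $\sigma = 0.01$ on the
fraction scale — one percentage point of DNA content; a unit-interval
$\sigma = 1$ would be non-local, so the percent reading was adopted.
Ordering/range violations are rejected outright; otherwise the Metropolis
rule under a geometric temperature schedule (default $T_0$ = one tenth of
the starting objective, cooling 0.995) decides, and the best-ever vector
is returned. The annealer re-gates via a per-bin histogram of
replicated-counts (a sufficient statistic for any boundary vector), so
each proposal costs $O(BG)$ rather than a pass over all snapshots. The
gate count G is a parameter (default 6).

## Fork counts and S-phase duration

The single adjustable biological parameter is $N$.
`scan_fork_count()` simulates each chromosome at every candidate $N$,
correlates against an empirical profile and picks the argmax (ties to
the smallest $N$); with two or more chromosomes, OLS of the optima on
chromosome length gives the linear scaling. `estimate_forks()` applies
the default coefficients $N = \mathrm{round}(10.24 + 7.9\times10^{-7}
\ell)$, clamped to at least one fork; the slope corresponds to about
1.3 Mb per fork (`fork_density_mb()`).

Wall-clock conversion: each step advances every unblocked edge one bin
and a bubble carries two forks, so
$\text{hours} = \text{steps} \cdot w / (2 v) / 3600$ at fork speed $v$
(default 50 bases/s). `sphase_stats(5965)` gives 8.3 h at the defaults.

## Plasticity regions

`call_plasticity_regions()` subtracts one profile from another, fits a
normal null to the *whole* distribution of differences by moments
(including any candidate regions — a median/MAD option exists but is off
by default), assigns two-sided p-values (plasticity can go either
direction), and reports maximal runs of at least 3 consecutive bins at
$p \le 0.001$; missing bins break runs and no merging of nearby regions
is performed. Two exactly identical profiles have a zero-variance
difference and error as degenerate by design. On pure Gaussian noise the
run-of-3 rule at $p\le10^{-3}$ has a per-genome expected false-region
count around $10^{-4}$ at $10^4$ bins, which the test suite verifies
empirically.

## Synthetic fixtures: what they do and do not emulate

All tests run on generated data. `make_ipls_fixture()` produces
single- or multi-chromosome landscapes under three site models —
clustered (evenly spaced cluster centers, so distance-to-site is known),
uniform, and lone (the closed-form oracle input) — with gamma-distributed
(shape 2, right-skewed, mimicking peak-score distributions) or constant
amplitudes. `make_pseudo_empirical()` runs the real engine at a fixed
seed to produce reference profiles for recovery tests, and
`make_sequence_fixture()` plants literal G4/GC/CpG features on an A/T
background.

The fixtures emulate the *structure* that drives the model — clustered
accessible sites on an otherwise quiet background — but not the width,
spacing and score distributions of real DNase hypersensitivity data, nor
mappability gaps, copy-number variation or sorter measurement noise.
Passing tests therefore demonstrate that the engine, gating and
statistics behave as specified, not that any particular correlation with
real Repli-seq data would be attained; real-data use requires
user-supplied tracks.

Problem sizes were chosen so the whole suite runs in minutes on one CPU:
fixtures of 300–2,400 bins, populations of 20–500 cycles, a 10,000-bin
noise genome for the plasticity null, and 2,000 annealing iterations.
These are the package's documented study conditions; the acceptance
script uses the same scales.

## Numerical choices and degenerate inputs

* Coordinates are BED-style 0-based half-open; bin $k$ (1-based in R)
  covers $[(k-1)w, kw)$, and an interval ending exactly on a boundary
  does not touch the next bin.
* Gate boundaries are half-open on the right; a fraction exactly equal to
  a boundary belongs to the lower gate. A replicated fraction of 0 is a
  G-phase cell and is the caller's responsibility to filter.
* Track values are written at full precision (17 significant digits), and
  bins fed by a single source record on re-reading take the value
  verbatim, so write-then-read round-trips are exact.
* Degenerate inputs error loudly: empty landscapes, zero-variance
  difference profiles, non-positive chromosome lengths, breakpoints
  beyond chromosome ends, subsampling counts exceeding the set size.
* Profile comparisons require at least 3 shared defined bins and drop
  masked bins pairwise; chromosome means are unweighted, with the SEM
  across chromosomes reported.

## Known limitations

* Factors diffuse implicitly (uniform selection); no sub-diffusive search
  process is modeled.
* Fork speed is constant and stalling is not modeled; licensing and
  activation are subsumed into the IPLS.
* The flow sorter is idealized: no measurement noise on DNA content and
  no S/G1 normalization of empirical inputs — empirical tracks are
  assumed preprocessed to timing values on the simulator's orientation
  (use `flip = TRUE` in `compare_profiles()` for higher-is-earlier
  conventions).
* Chromosomes are independent territories; trans effects between
  chromosomes (shared factor pools) are available only by running a
  single concatenated territory.

```{r example}
fx <- make_ipls_fixture(fixture_spec(n_bins = 800, n_clusters = 4, seed = 1))
st <- simulate_replication(fx$ipls, n_factors = 6, n_cycles = 200, seed = 1)
prof <- timing_profile(st)
prof
sphase_stats(s_lengths(st)$chrF)
```
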