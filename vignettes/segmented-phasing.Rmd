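---
title: "Segmented haplotype phasing: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented haplotype phasing: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segphase)
```

## The problem

A diploid individual genotyped at $m$ biallelic SNP sites yields a vector
over $\{0, 1, 2, ?\}$: homozygous major, homozygous minor, heterozygous,
missing. Phasing resolves each such vector into the two haplotype vectors
over $\{0, 1\}$ that produced it. Every heterozygous site doubles the
number of consistent haplotype pairs, so the information that picks one
resolution comes from the population: haplotypes are shared, and nearby
alleles travel together (linkage disequilibrium, LD).

segphase is built for *long* sequences (up to millions of SNPs) phased on
commodity hardware. Since LD decays with distance, sites far apart carry
essentially no phase information about each other; the package therefore
cuts the sequence into segments of $s$ sites (default 1,000), phases each
segment independently, and joins adjacent segment results. Memory per
worker then depends on $(n, s)$ and not on $m$, and segments parallelise
trivially.

## The three-phase segment core

**Phase 1 — LD chaining.** For two sites $s,t$, the unambiguous two-site
gamete counts $n_{00}, n_{01}, n_{10}, n_{11}$ are accumulated over the
population: an individual homozygous at both sites contributes two
identical gametes; homozygous at exactly one site, one gamete to each
compatible cell; double-heterozygous or missing individuals contribute
nothing. The sign of $D = n_{00} n_{11} - n_{01} n_{10}$ estimates whether
allele 0 at $s$ co-resides with allele 0 or 1 at $t$. Each individual's
heterozygous sites are chained left to right: the first takes the
canonical orientation, each subsequent one is oriented relative to its
predecessor by the sign of $D$ ($D = 0$ counts as coupling, for
determinism). This is a per-pair majority call: individuals whose true
configuration is the minority one at some adjacent pair start out wrong,
which the later phases must repair.

**Phase 2 — scalable sliding windows.** The repair currency is the
*support weight*: the number of other individuals' current haplotype
fragments that exactly match a candidate fragment inside a window. For
each *breakpoint* (the gap between an individual's consecutive het sites)
the two relative orientations of the suffix are compared across windows of
length $l_\min, 2 l_\min, \dots, \le l_\max$ (defaults 8 and 64), at every
placement that keeps one of the individual's het sites on each side of the
gap. Toggling the orientation at a breakpoint is implemented as a suffix
swap of the pair from the right-hand het site on; this changes exactly
that breakpoint's orientation and nothing else, so breakpoints are
independent coordinates.

Exact-match support behaves very differently in two data regimes, and the
acceptance rule must respect that:

* In a **low-diversity** population (a handful of founder haplotypes,
  every true haplotype common) an unsupported fragment is almost surely a
  phase error, and errors should be consolidated aggressively. The
  `"consolidate"` mode sweeps windows left to right, shortest length
  first, applying any weight-improving flip immediately and updating the
  pool, so corrections cascade: once one carrier of a founder is fixed,
  its fragments support the next carrier's fix. Short windows repair
  isolated errors first; longer windows then enforce long-range
  consistency.
* In a **diverse** panel (coalescent-like data, many rare haplotypes) an
  unsupported fragment is often a genuine singleton haplotype, and
  consolidating it into common fragments *creates* switch errors.
  The `"repair"` mode therefore accepts a flip only as a corroborated
  repair: the current pair must contain a zero-support fragment, both
  flipped fragments must have support, and the flip must win the weight
  comparison. This fixes minority-configuration errors from phase 1 while
  leaving true rare haplotypes alone.

The default `"auto"` mode chooses between the two using a
phase-independent statistic: the mean number of distinct genotype row
patterns in windows of length $l_\max$. $K$ founder haplotypes can
generate at most $K(K+3)/2$ diplotype patterns, so a mean at or below 16
(about four or five founders) selects `"consolidate"`; anything richer
selects `"repair"`. A third mode, `"argmax"` — flip when the single best
flip weight over all windows beats the single best keep weight — is kept
for comparison; raw supports are systematically larger in short windows
than long ones, so a global argmax across window lengths is dominated by
the least discriminative windows and measurably degrades diverse panels.
The mode is exposed through `core_config(refine_mode = ...)`.

Sweeps repeat up to `refine_passes` times (default 2) and stop early when
nothing changes, which also makes the operation idempotent on a converged
configuration.

**Phase 3 — maximum parsimony.** Natural populations carry far fewer
distinct haplotypes than $2n$. The polish is a deterministic hill climb
over the same suffix-flip moves: a move is accepted only if it strictly
reduces the number of distinct haplotypes in the $2n$-row pool, or keeps
it equal while strictly increasing the summed pool multiplicity of every
individual's haplotypes — equal to $\sum_v c_v^2$ over haplotype
multiplicities $c_v$, which is how it is maintained incrementally. Sweeps
run in index order until no move is accepted or `parsimony_passes`
(default 3) is reached. The distinct count never increases, and the climb
stops on plateaus rather than wandering.

## Divide and conquer

`plan_segments()` cuts $[1, m]$ into intervals of $s$ sites; a final
remainder shorter than 1,000 sites is folded into the previous interval
(a short segment may lack heterozygous sites entirely, which makes it
unmergeable, so segments shorter than 1,000 sites are refused unless
forced). Each segment is phased by the three-phase core.

Adjacent results are joined left to right. For individual $i$ the join is
a binary choice: STRAIGHT concatenates $h^f_{i1}$ with $h^{f+1}_{i1}$,
CROSS with $h^{f+1}_{i2}$. A window of length $l_\max$ slides across the
junction (every placement covering at least one site of each segment);
placements without a het site of $i$ on both sides are skipped, the rest
score both pairings by support against all other individuals' current
straight concatenations, and the single best weight decides, ties going
to STRAIGHT. Decisions are evaluated per individual against the same
frozen pool and applied together.

Three boundary cases lack scoreable windows. With hets on both sides of
the junction but outside the scope window on one side (CASE1) or both
sides (CASE2), the two-site LD rule between the last het of the left
segment and the first het of the right segment decides, exactly as in
phase 1. When one side has no het anywhere in its segment (CASE3) the
choice is immaterial on that side's labels; a deterministic pseudo-random
bit keyed by (seed, junction, individual) picks it, so the draw is
reproducible and independent of worker scheduling. A NORMAL individual
whose windows all get skipped falls back to the CASE1/CASE2 rule and is
flagged in the decision table.

Parallel mode distributes segments over forked workers
(`threads > 1`). Because per-segment seeds are derived deterministically
from the master seed and segment index, and junction draws are keyed as
above, the output is bit-identical to a serial run — worker count is not
allowed to leak into results.

## Evaluation

`switch_error_rate()` counts, per individual, flips in the relative
orientation of consecutive heterozygous sites between inferred and true
pairs, anchored at the first het site, and divides the total by the total
number of heterozygous loci. This follows the stated definition of the
reference results; the more common convention divides by het loci minus
one per individual and is available as `denominator = "het-1"`.
`individual_error_rate()` is the fraction of individuals whose pair is
wrong under both labelings; with many SNPs essentially every individual
carries at least one switch, so the IER saturates and the SER is the
informative metric at scale. Sites that were missing in the genotypes
(and therefore imputed) are excluded from both metrics.

## The synthetic-data generator

`simulate_block()` draws one neutral-coalescent genealogy (exponential
coalescence times at rate $\binom{j}{2}$, time in units of $2N_e$
generations) and drops $\mathrm{Poisson}(\theta/2 \times \text{total
branch length})$ infinite-sites mutations on it, one polymorphic column
per mutation. `simulate_dataset()` concatenates independent blocks at
$\theta = 5$ per nominal 2,501-site block until the target SNP count is
reached, trims, pairs consecutive haplotypes into diploid genotypes, and
optionally injects missing calls. Everything is driven by one seed.

What this emulates — and what it does not. Within a block, the data have
perfect tree-like LD; across blocks they are independent, which acts as
free recombination between blocks. Real coalescent data with
recombination parameter $\rho$ has LD that decays smoothly rather than
dropping to zero at block edges. The distinction matters for phasing:
across a boundary between independent blocks there is *no* information —
for any individual, the other individuals' left-type/right-type
combinations are independent of its true pairing — so any phaser incurs
about half a switch error per individual per boundary. With blocks of
roughly $\theta \sum_{i<2N} 1/i \approx 33$–$37$ segregating sites, a
10,000-SNP dataset contains close to 300 such boundaries, which places an
information-theoretic floor of roughly $0.5 \times \text{boundaries} /
\text{het loci} \approx 0.09$–$0.10$ on the achievable SER under this
generator. Passing tests on these data therefore demonstrate correct
behaviour of the machinery, within-block accuracy, and junction handling —
not the lower SER attainable on data with genuine recombination
continuity. Users who need that continuity can feed real `ms` output
(which may include intra-block recombination) through `read_ms()` and
`pair_random()`; simulating the coalescent with recombination natively is
out of scope. The recombination parameter `rho` is recorded in
`sim_params()` for provenance only.

## Numerical and engineering choices

* **Fingerprints.** The hot loops identify fragments by 64-bit polynomial
  (Rabin) fingerprints computed from per-row prefix hashes, giving O(1)
  substring and spliced-substring keys; support counting per window is
  then O(n). Distinct strings colliding at 64 bits is vanishingly
  improbable at these problem sizes ($\sim 10^3$ fragments per window);
  the exported `window_support()`, `candidate_weight()` and
  `distinct_haplotypes()` are exact and the test suite checks the
  compiled path against them.
* **Ties.** $D = 0$ counts as coupling; refinement ties keep the current
  orientation; junction ties choose STRAIGHT; parsimony requires strict
  improvement. Every tie-break is fixed, so identical inputs and
  configuration give bit-identical output.
* **Missing data.** `?` calls are imputed to the column's major allele
  (a het call contributes one of each allele; ties go to 0), carried on
  both haplotypes, masked, excluded from gamete counts and from both
  error metrics.
* **Degenerate inputs.** All-homozygous rows phase trivially; individuals
  with fewer than two het sites have no breakpoints; empty pools (n = 1)
  leave orientations untouched; segments without hets merge via the
  seeded draw.
* **Coordinates.** The R interface is 1-based with closed intervals, as R
  users expect; the compiled core is 0-based internally.

## Problem sizes used by the shipped checks

The test suite exercises the core on populations of 10–40 individuals and
25–200 sites (oracle comparisons are brute-force, so they stay small),
and the end-to-end checks phase 200 and 500 genotypes at 10,000 sites —
the latter standing in for the published 50,000-site run, whose reported
accuracy is stable across lengths at fixed $N$ since the SER is dominated
by local structure. The acceptance script (`scripts/acceptance.R`)
regenerates those two panels from scratch for three derived seeds each
and reports mean SERs.

## Known limitations

* Exact-match support cannot certify a haplotype seen only once; in
  diverse panels the repair mode simply leaves such configurations at
  their phase-1/parsimony state.
* The diversity statistic switches refinement modes globally; a dataset
  mixing founder-like and diverse regions uses one mode for both.
* The junction merge considers the two whole-segment pairings only; a
  within-segment error near a junction cannot be repaired at merge time.
* IER is reported but saturates near 1 for long sequences; compare
  phasers on SER at scale.
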