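---
title: "Contact model, sampler, and correction: how scaffoldmc works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact model, sampler, and correction: how scaffoldmc works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scaffoldmc orders and orients draft-assembly contigs into chromosome-level
scaffolds using Hi-C contact counts. This vignette is the package's own
account of the underlying model, the choices made where the design was
genuinely open, and what the bundled synthetic benchmarks do and do not
demonstrate.

## The contact model

Hi-C contact frequency between two loci decays with their genomic distance
$s$. scaffoldmc models the expected contact count between two bins as

$$
P(s) = \begin{cases}
\max(A\, s^{-\alpha}, \delta) & \text{same scaffold (cis)}\\
\delta & \text{different scaffolds (trans)}
\end{cases}
$$

with three parameters: the prefactor $A$ (expected count at unit
distance), the decay exponent $\alpha$ (typically near 1 for the
polymer-physics regime of chromosome folding), and the floor $\delta$, the
trans level: the expected count between bins of different chromosomes.
Counts are treated as Poisson with these means. The Poisson family makes
the zero-count part of the likelihood decomposable (see below) and is the
natural first model for sequencing counts; overdispersion is absorbed, in
practice, by the fact that only likelihood *differences* between
arrangements matter.

## Bins, units, and the pyramid

The atomic unit is the restriction fragment (RF): the interval between
consecutive restriction sites (default site `GATC`, DpnII; the cut is
placed at the site start, which shifts all boundaries by a constant and is
irrelevant to the model). Fragments shorter than 50 bp are discarded, then
fragments whose contact coverage is more than one (population) standard
deviation below the mean, and finally contigs left with fewer than 5
surviving fragments are put aside entirely — such remnants carry too
little signal to be placed by the model and are restored during
correction. Surviving fragments are sum-pooled in groups of `fold = 3`
consecutive fragments per contig, recursively, giving a pyramid of maps:
a level-$L$ interior bin holds $3^L$ fragments. Pooling never crosses
contig boundaries, so every bin maps to one source interval.

The sampler permutes bins at a chosen *working level* but evaluates the
likelihood one level below, over what we call *units* (the working bins'
sub-bins). This is what makes orientation identifiable: flipping a bin
reverses its unit order, which changes unit-level distances and therefore
the likelihood; at bin-level resolution a flip would be invisible.

## The grid distance convention

Inside the likelihood, the genomic distance between two units of the same
scaffold is measured on a uniform grid:

$$ s_{ij} = u \cdot |r_i - r_j|, $$

where $r$ are unit ranks along the scaffold and $u$ is the mean unit
length of the map. Units at a given level are nearly equal-sized and the
power law is scale-free, so the approximation error is small; in exchange
the zero-count term becomes an *exact* function of scaffold sizes:

$$ \sum_{\text{intra pairs}} \lambda = \sum_{\text{scaffolds}}
   \sum_{d=1}^{S-1} (S-d)\,\lambda(ud), \qquad
   \sum_{\text{inter pairs}} \lambda = \delta\, N_\text{inter}, $$

which is what allows the log-likelihood change of any single-bin move to
be computed exactly and incrementally: only non-zero pairs involving the
moved bin's units, plus non-zero pairs whose rank distance shifts across
the removal/insertion cuts (accumulated in one difference-array pass per
affected scaffold), plus a table lookup for the scaffold-size terms. The
incremental deltas agree with full recomputation to floating-point
precision; the test suite checks this on thousands of random mutations.
`genomic_distance()` reports bp-exact center distances (used by the
simulator and for reporting); the grid convention is internal to the
likelihood.

## Parameter estimation

After every sampler cycle the parameters are re-estimated from scaffolds
with at least 10 units:

* **$\delta$ (trans level).** While scaffolding is incomplete, many
  cross-scaffold cells actually join pieces of one chromosome; a plain
  mean over inter-scaffold cells is inflated by orders of magnitude,
  which in turn destroys the $\ln(\lambda/\delta)$ merge incentive.
  $\delta$ is therefore estimated from the Poisson zero fraction
  ($P(0) = e^{-\delta}$) of cross-scaffold cells, seeded by the
  cell-weighted median per-scaffold-pair rate and iteratively excluding
  scaffold pairs whose non-zero rate exceeds five times the current floor
  (those pairs are linked, not trans). With no inter-scaffold cells at
  all, $\delta$ is clamped to $10^{-9}$.
* **$A$, $\alpha$.** A distance profile is built from intra-scaffold
  pairs: counts are tallied per grid distance, grouped into 20 geometric
  distance bins, and the mean count per available pair (zeros included)
  is regressed on $\log s$ by least squares. Distance bins below twice
  the floor — the larger of $\delta$ and the level of the most distant
  part of the profile itself — are excluded, since the flat floor region
  would otherwise bias $\alpha$ shallow; the self-floor matters when the
  map has a single scaffold and $\delta$ is unidentified. $\alpha$ is
  clamped to $(0, 10]$.

Parameter recovery is verified by simulation: on Poisson maps drawn from
known parameters over a 500-bin scaffold, the median relative error of
$\hat\alpha$ is well under the 10% the acceptance suite requires.

## The sampler

One *cycle* visits every bin once in random order. For each bin, the
candidate set is: stay, flip, eject (to a new singleton scaffold),
insertion before/after each of the $k = 5$ highest-contact anchor bins in
either orientation, and a swap with each anchor — no-ops and duplicates
removed. The chain samples one candidate with probability proportional to
$\exp(\Delta \log L / T)$ (Gibbs among candidates; stay has $\Delta = 0$,
so rejection is always possible). With a fixed seed the run is fully
deterministic.

Two dynamics choices deserve explanation:

* **Coarse-to-fine initialization.** Joining two scaffolds by single-bin
  moves is nearly likelihood-neutral per step (the moved bin trades its
  old-side neighbors for new-side ones), with a barrier of the order of
  the counting noise of one bin's contacts. At the top pyramid level a
  whole contig is typically a single bin, so scaffold joins are single
  high-signal moves. `run_scaffolder` therefore runs a short pre-pass at
  the coarsest available level and projects the resulting structure down
  through the parent links to initialize the working level
  (`init = "contigs"` restores a flat start from the input contigs).
* **Pulsed annealing.** A contig-initialized chain still has to cross
  junction barriers. Destroying a correct junction costs roughly
  $\lambda_1 \ln(\lambda_1/\delta)$ (with $\lambda_1$ the expected
  adjacent-unit count) while crossing a junction plateau costs only about
  $\sqrt{\lambda_1}\,\ln(\lambda_1/\delta)$ — an order of magnitude less.
  The temperature schedule exploits this gap: pulses that hold at
  $T_0 = 2\sqrt{\lambda_1}\ln(\lambda_1/\delta)$ for several cycles
  (joins proceed bin by bin, so the hot phase must be sustained), cool
  back down, and repeat over the first 80% of the cycles; the remainder
  runs cold. $T_0$ is far too cold to melt correct structure but hot
  enough to cross plateaus. Coarse-initialized chains run cold
  throughout, so as not to disturb the initialization.

Convergence is monitored as in the trajectory plots of Hi-C scaffolders:
the interquartile range of each model parameter (and of the
log-likelihood) over the trailing 20% of cycles; near-zero IQRs mean the
structure has stopped evolving. Quartiles use linear interpolation at
positions $(k-1)/(n-1)$ (R's type-7 default).

The Gibbs-among-candidates kernel has state-dependent candidate sets and
is therefore not globally reversible; on an exhaustible two-bin system the
visit frequencies *within* the family of merged arrangements match the
likelihood ratios (checked to 3 SE in the test suite), while the
split/merged ratio deviates from the naive Gibbs prediction. For
scaffolding this is immaterial — the chain is used as a stochastic
optimizer with a deterministic correction step, not as a posterior
sampler.

## Correction

The sampler occasionally flips or displaces single bins inside contigs —
flipping a bin barely changes its distances to neighbors, so such errors
carry almost no likelihood penalty. The correction step trusts the input
contigs and reinstates their local structure while preserving the
scaffold-level arrangement:

1. **reorient**: each maximal run of same-contig bins is rewritten in
   original-rank order with a uniform orientation chosen by majority vote
   of the bins' orientations (ties forward).
2. **rearrange**: a contig present as several runs is gathered at its
   largest run (ties toward the run containing the lowest original rank),
   as one block in original order and anchor-majority orientation;
   emptied scaffolds are deleted. Removing a run from between two runs of
   another contig can make those adjacent, so `rearrange` finishes with a
   consensus pass, making `rearrange(reorient(x))` a fixpoint.
3. **reinsert_filtered**: filtered fragments adjacent (in contig order)
   to a placed fragment are inserted back at the corresponding junction
   or extremity, runs as blocks; fully filtered contigs are appended as
   standalone scaffolds.

A misassembly proxy report counts, per contig: inversions (maximal blocks
of bins disagreeing with their run's majority orientation), relocations
(original-rank discontinuities within a run), and splits (extra maximal
runs). Counting blocks rather than bins matches event-style misassembly
counting. The acceptance suite verifies that reorient + rearrange heal
200/200 randomized flip/relocation/split perturbations completely.

## Linkage validation and correction

A genetic linkage map is an independent order oracle: markers with
centimorgan positions anchored to input-contig coordinates. Each linkage
group is paired with the scaffold holding most of its markers (two groups
may pair to one scaffold — the signature of a genuine chromosome fusion).
Validation projects marker cM order onto bin order and counts the
marker-bearing bins outside the longest order-consistent subsequence (in
either direction, as the group's orientation is free) plus any placed on
other scaffolds; zero changes means full consistency. Correction is
parsimonious and block-first: the marker sequence is segmented into
maximal monotone runs, descending blocks are flipped and blocks reordered
by median cM (interstitial unmarked bins travel with their block), then
any stray marker bins and translocated bins are relocated individually to
their cM slot; the pass is iterated to a fixpoint. Bins without markers
between consistent markers are never moved across scaffolds.

## The simulator

The generator defines the study conditions for every end-to-end check:

* chromosomes of uniform random sequence; in fixed-spacing mode the
  restriction site is planted exactly every 800 bp (within the typical
  DpnII density of one site per 600-1000 bp) and background occurrences
  are mutated away, so fragment sizes are controlled;
* contigs obtained by shredding at ~40 kb (about 100 contigs for the
  default 4 x 1 Mb genome), shuffled and randomly strand-flipped, with
  optional planted inversions recorded in a truth table;
* contact counts drawn per fragment pair from Poisson with mean
  $\text{depth} \cdot \max(A s^{-\alpha}, \delta)$ at the true bp
  distance; defaults $A \cdot \text{depth} = 8000$ bp (about 10 contacts
  between adjacent fragments, i.e. roughly 60-fold fragment contact
  coverage — a deeply sequenced library at this genome size), $\alpha = 1$,
  and $\delta \cdot \text{depth} = 6\times10^{-4}$ per fragment pair
  (about 0.05 per level-2 bin pair). Floor-level cells are drawn by first
  sampling the number of non-zero cells, keeping the simulation linear in
  the non-zero contacts.

What the simulator does **not** emulate: mapping artifacts (dangling
ends, re-ligations, multi-mapping), GC/coverage bias along the genome,
duplications and repeats, structural heterozygosity. Passing the bundled
benchmarks therefore demonstrates the correctness of the model,
likelihood machinery, sampler dynamics, and correction logic under the
stated model — not robustness to every artifact of real libraries. The
fragment-level filters (length, coverage, orphaned contigs) are the
method's first line of defense on real data, and real runs should expect
to rely on them more heavily.

## Problem sizes and numerical choices

The bundled benchmarks use 4 chromosomes of 1 Mb (about 5,000 fragments,
530 level-2 bins, 1,500 level-1 units and 200k non-zero cells), 50
working-level cycles after a 24-cycle coarse pre-pass — sizes chosen so
the full 10-seed recovery study runs in a few minutes on one core while
still exercising ~100-contig assemblies. Other conventions: coordinates
are 0-based half-open throughout; orientation is `+`/`-`; scaffold FASTA
output joins segments with 100 `N`s (configurable); the sparse map
dialect is a headered upper-triangle 0-based TSV; incremental deltas are
tested against full recomputation at $10^{-6}$ and agree to ~$10^{-13}$;
ejecting a bin that is already a singleton scaffold is a likelihood
no-op; degenerate inputs (empty maps after filtering, single-scaffold
maps with no trans information, fewer than two usable distance bins)
raise informative errors rather than silently fitting.

## Known limitations

* Single-bin moves only: no explicit block moves in the sampler; large
  rearrangements are reached through the coarse pre-pass and annealing,
  and residual block-level errors are the correction's and linkage
  module's job.
* The trans floor is a single global $\delta$; no per-chromosome or
  distance-dependent trans structure.
* No explicit coverage-bias normalization — deliberately, since the
  model estimates its parameters from the raw counts; biased bins are
  filtered instead.
* The likelihood's uniform grid slightly misprices units of unequal
  size (contig remainders); at the default depths this is far below the
  decision noise, but it is the first thing to revisit for very uneven
  restriction maps.
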