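---
title: "Detecting recombination hotspots from linkage disequilibrium with ldhotscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination hotspots from linkage disequilibrium with ldhotscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Recombination hotspots are narrow intervals (on the order of 2 kb) where
the recombination rate is many-fold higher than in the surrounding
sequence.  In species where direct measurement of recombination is
impractical, hotspots are inferred from the footprint recombination leaves
in patterns of linkage disequilibrium (LD) among SNPs in a population
sample.  A local dip in LD may, however, reflect chance variation in the
genealogical process rather than a genuine rate elevation, so hotspot
detection needs a calibrated hypothesis test, not just a rate map.

`ldhotscan` implements a composite-likelihood ratio scan of phased
haplotype data, simulation-based calibration of its p-values, three
published protocols for turning per-window tests into hotspot calls, and a
coalescent simulation framework for measuring how well the whole pipeline
recovers known truth.

## The test statistic

All rates below are population-scaled: $\rho = 4N_e r$ per kb for
recombination and $\theta = 4N_e\mu$ per kb for mutation.

For a putative hotspot interval (2 kb by default) inside an analysis
window of $X$ kb, the data are the SNPs $s_1, \dots, s_S$ in the window.
Every unordered SNP pair contributes a two-locus sampling probability
$\mathrm{lik}(s_i, s_j \mid \rho)$ — the probability of the pair's observed
two-locus haplotype counts under the neutral coalescent with scaled rate
$\rho$ between the sites.  The composite likelihood of a rate model is the
product of these pairwise terms over all pairs, treating pairs as if they
were independent.  Two models are compared:

* a two-rate model with background rate $\rho_0$ outside the test interval
  and rate $\rho_1$ inside it, and
* a constant-rate model with a single $\rho$.

With $\rho(i,j)$ the model rate integrated over the physical span between
sites $i$ and $j$, the statistic is

$$\Lambda \;=\; 2\Big(\sup_{\rho_0,\rho_1} \sum_{i<j} \log
\mathrm{lik}\big(s_i,s_j \mid \rho_{0},\rho_1\big) \;-\;
\sup_{\rho} \sum_{i<j} \log \mathrm{lik}\big(s_i,s_j \mid \rho\big)\Big).$$

Both suprema are taken by exhaustive grid search, and the constant model's
grid is included as the diagonal of the alternative's, so $\Lambda \ge 0$
holds exactly rather than up to optimizer tolerance.  Grids (per kb) are
$\rho_0 \in \{0, 0.05, \dots, 5\}$, $\rho_1 \in \{0, 0.5, \dots, 100\}$
(both log-ish spaced) and the constant grid is $\rho_0$'s extended to 10.
$\rho_1$ is deliberately not constrained to exceed $\rho_0$.  Ties break
toward the smaller rate everywhere, so estimates are parsimonious and
reproducible.

A composite likelihood is not a true likelihood — the same SNP enters many
pairs, so evidence is overcounted and $\Lambda$ has no chi-square null
distribution.  All significance therefore comes from simulation.

## Two-locus sampling probabilities

The pairwise term is read from a Monte Carlo table built by
`build_two_locus_table()`.  For each grid value of $\rho$ (23 points from
0 to 500 scaled units, dense below 10) it simulates the joint genealogy of
two loci for $n$ haplotypes, then places exactly one mutation on each
locus's marginal tree at a point chosen proportional to branch length
below the locus's most recent common ancestor.  This is the
$\theta \to 0$ limit of the two-site likelihood: it conditions on both
loci being polymorphic and removes $\theta$ from the table entirely.
Gamete counts are stored in a canonical form invariant to allele
relabeling at either locus and to exchanging the loci (the
lexicographically smallest of the eight equivalent count vectors).

Numerical choices:

* Lookups interpolate the log-probability linearly in $\rho$ between
  bracketing grid points; rates beyond the grid maximum clamp to the last
  column (by 500 scaled units the configuration distribution has
  essentially reached its independence limit).
* Configurations never observed at a grid point get a floor probability of
  $0.5/\mathrm{reps}$ instead of $-\infty$, so one rare pair cannot veto a
  whole window.  The floor is configurable and recorded in the table.
* Tables are deterministic given their seed, and serialize to a plain-text
  TSV (integer Monte Carlo counts plus a JSON metadata header) that
  reloads bit-exactly; mismatched formats are refused.

The default 10^4 replicates per grid point keep each column's Monte Carlo
error well below the composite-likelihood differences that drive calls at
the study's sample sizes; users scanning real data can raise `reps`.

## Null calibration by lookup table

Because $\Lambda$ has no analytic null distribution,
`build_null_table()` simulates many constant-rate windows of the same size
$X$, drawing $(\theta, \rho)$ uniformly from a generation grid (defaults
$\theta \in \{0.5, 1, 2, 5\}$/kb, $\rho \in \{0.1, 0.2, 0.5, 1, 2.5,
5\}$/kb), and records for each the statistic $\Lambda$, the segregating
site count $S$, and the constant-rate composite estimate $\hat\rho$.  When
a real window is tested, `p_value()` conditions on the observed $(S,
\hat\rho)$: it selects null records with $S$ within $\max(2, 5\%\,S)$ of
the observation and $\hat\rho$ in the same decile bin of the null
$\hat\rho$ distribution, widening both symmetrically until at least
`min_m` records are available, and returns the add-one estimate

$$p = \frac{1 + \#\{\Lambda_{\mathrm{null}} \ge \Lambda_{\mathrm{obs}}\}}{m + 1},$$

which is strictly positive and valid under the simulation null.  The
conditioning is what makes one archive serve all windows: $S$ carries the
dependence on $\theta$ (and window truncation at region edges), and
$\hat\rho$ the dependence on the local background rate.  The acceptance
suite verifies the property this scheme is designed for — p-values of
fresh constant-rate windows are uniform.

One subtlety: $\Lambda$ is a discrete statistic with a large atom at
exactly 0 (under the null the grid maximum frequently sits on the
constant-rate diagonal).  A deterministic tie-inclusive p-value can
therefore never be exactly uniform; it is conservative at the atoms,
which shows up as an atom at $p = 1$ and is harmless for hotspot calling,
where only small p-values matter.  `p_value(randomize = TRUE)` implements
the standard randomized-rank construction
$p = (\#\{\Lambda > \Lambda_{obs}\} + U(1 + \#\{\Lambda =
\Lambda_{obs}\}))/(m+1)$, which is exactly uniform under exchangeability;
the calibration check uses it, while calling uses the deterministic,
conservative default.

Because $p \ge 1/(m+1)$, a protocol that requires $p < 0.001$ can only
ever fire if the conditioning bin holds at least 1000 records;
`scan_region()` therefore requests occupancy
$\max(500, \lceil 1/\alpha_{\mathrm{strict}}\rceil)$ from the lookup.

One table is built per (window size, sample size) pair and the interface
refuses mismatched lookups rather than extrapolating.

## Scanning and the three calling protocols

`scan_region()` tests every 2 kb interval at a 1 kb step, analyzing the
$X$ kb window centered on it (truncated at region edges; windows with
fewer than two SNPs are emitted with $p = 1$ and a flag).  Candidate
hotspot regions are the merged extents of windows with $p < 0.01$, where
abutment counts as overlap since consecutive 2 kb windows share 1 kb.
The protocols then differ only in how candidates are filtered:

| protocol    | window size used in its source | retention rule |
|-------------|-------------------------------|----------------|
| `auton2012` | 200 kb | candidate kept if $\le$ 5 kb long **and** peak profiled rate $\ge$ 5/kb |
| `auton2014` | 100 kb | candidate kept (at full extent) if it contains a window with $p < 0.001$ |
| `mlehot`    | 20 kb  | candidate partitioned into 1 kb tiles anchored at 0; tiles with profiled rate $\ge$ 5/kb kept, adjacent kept tiles merged |

The 5/kb rate threshold is the convention for a 0.5/kb background; for
other backgrounds the analyses switch to 10$\times$ the background rate
(`rho_min`).  Window size is a free parameter of `scan_region()` for every
protocol, which is exactly what the simulation study varies.

## The profiled local rate

The original filters consult an external variable-rate map estimate
(an LDhat-style program).  `rho_profile()` provides a self-contained
stand-in: for each 1 kb window it fits the two-rate model to the 2 kb
interval centered on the window, using 9 kb of context on each side (a 20
kb fit, matching the smallest analysis window), and reports a local rate
for the interval.  Two choices matter:

* **Support-interval parsimony.**  The reported rate is the smallest
  $\rho_1$ grid value whose profile log-likelihood (maximized over
  $\rho_0$) lies within 2 log-units of the maximum, not the raw argmax.
  When a window's data barely constrain the local rate, the composite
  surface is nearly flat over a wide range and its argmax is effectively
  arbitrary — often enormous; a genuinely elevated rate keeps the entire
  support set high.
* **Median smoothing.**  A running median of 3 is applied across adjacent
  windows.  Real hotspots (~2 kb) always span at least two adjacent 1 kb
  windows, so the median suppresses isolated single-window spikes, the
  same role the smoothness priors of variable-rate map estimators play.

This stand-in is a documented deviation from using an external map
program: ordering and calibration properties are insensitive to it (the
test suite checks them), but absolute power and FDR percentages shift with
the profile's behavior, which is one reason the study quantities are
reproduced with tolerance bands rather than to the digit.

## The coalescent simulation engine

`simulate_haplotypes()` implements the neutral constant-size coalescent
with recombination (an exact ancestral-recombination-graph simulation, not
a sequential approximation).  Lineages carry their ancestral material as
segment lists with descendant sets; time is in units of $2N$ generations,
so a lineage pair coalesces at rate 1, a lineage recombines at rate equal
to half the scaled map length of its material span (supporting arbitrary
piecewise-constant maps), and mutations fall on material at rate
$\theta_{bp}/2$ per bp.  Material whose descendant set reaches the full
sample is dropped, so every emitted mutation is a segregating biallelic
site.  Only the embedded jump chain is simulated, since outputs need event
order, not times.  Infinite-sites mutation positions are rounded to
integer bp; collisions move to the next free integer (downstream code
indexes integer positions).  Recombination breakpoint positions are
returned as an attribute, which the test suite uses to verify that
breakpoints concentrate inside map hotspots.

`generate_study_region()` builds the study's truth: by default 1 Mb
regions with eight 2 kb hotspots at 10-, 20-, 50- and 100-fold the 0.5/kb
background (two per intensity — the even split is an assumption, flagged
in the configuration), centers evenly spaced across the interior with a
50 kb margin from the edges.  Even spacing is a design choice: it avoids
edge effects and inter-hotspot interference, which the sources do not
specify how to handle.  The intensity-to-position assignment is shuffled
per replicate.

All randomness flows from one root seed through `derive_seed(root,
purpose, index)` (a 64-bit hash), so any replicate, table or figure-level
experiment can be replayed in isolation.

## The study driver and its metrics

`evaluate_calls()` scores calls against truth at base-pair resolution:
power is the fraction of true hotspot bp called, the false positive rate
the fraction of non-hotspot bp called, and the false discovery rate the
fraction of called bp not in any true hotspot.  With no calls at all the
FDR is reported as 0 with a `no_calls` flag so pooling stays total.
`run_power_study()` pools bp counts across replicates before forming
ratios (replicates thereby self-weight), reports per-intensity power by
intersecting calls with that intensity's truth only, and reports FPR/FDR
only pooled over all intensities, since a call on one intensity's hotspot
is not a false positive of another.

## Problem sizes used by the shipped runs

The full published design (hundreds of 1 Mb regions, ~5×10^6 null records
per window size) is supported by configuration.  The shipped runs use
desk-scale sizes chosen to keep results stable while remaining routine to
re-run: the acceptance script runs 20 regions of 1 Mb with a 2×10^4-record
20 kb null table and a 10^4-replicate two-locus table; the test suite uses
a 10^5-record null archive (10 kb windows, n = 16) for the calibration
check, 20 pooled replicates for the ordering checks, and a generation
mixture restricted to the rate ranges the analyzed data actually occupy
(records far from the observed $(S, \hat\rho)$ are never selected by the
conditioning, so simulating them adds nothing).  At these scales the
stochastic study percentages carry sampling noise of several points, which
is why ordering claims are asserted as orderings.

## Known limitations

* The composite likelihood treats overlapping pairs as independent;
  $\Lambda$ is anticonservative in itself and meaningful only through the
  simulation calibration.
* Demography is the constant-size neutral coalescent: bottlenecks,
  growth, selection and gene conversion are out of scope, and violations
  will distort both the test and its calibration.
* Two-locus tables support $n \le 64$ haplotypes (descendant sets are
  bitmasks); the region simulator supports $n \le 128$.
* The profiled local rate is a stand-in for an external variable-rate map
  estimate (above).
* P-value resolution is bounded by conditioning-bin occupancy; strict
  cutoffs need proportionally large null tables.
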