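---
title: "Automatic methyl resonance assignment from NOESY networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic methyl resonance assignment from NOESY networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylassign)
```

## The problem

Methyl-TROSY NMR of large, selectively methyl-labeled proteins (Ile, Leu,
Val, Ala, Met, Thr in a deuterated background) delivers sharp 2D
[¹H,¹³C]-HMQC peaks — one per methyl — but those peaks are anonymous: the
spectrum alone does not say which residue each peak belongs to. When a 3D
structure of the protein is known, methyl–methyl NOESY cross peaks provide
the missing information: two methyls closer than roughly 10 Å in space give
rise to a pair of reciprocal cross peaks, so the measured NOE network is a
noisy, incomplete copy of the structure's methyl contact graph. Assignment
then becomes a combinatorial matching problem: find the mapping from
methyls (with known coordinates) to HMQC peaks (with known shifts) that
best superimposes the expected contact network onto the measured one.

`methylassign` implements this structure-based assignment protocol
end-to-end: expected-peak generation from the structure, peak-list
preparation (filtering, residue typing, type splitting), a stochastic
combinatorial optimizer run many times from random starts, and a
consolidation step that turns the ensemble of runs into consensus chemical
shifts with a calibrated strong/weak confidence label.

## Expected peaks from a structure

For every labeled methyl pair the nine inter-proton distances are
aggregated into an effective distance

$$d_\mathrm{eff} = \Big(\sum_{i=1}^{3}\sum_{j=1}^{3} d_{ij}^{-6}\Big)^{-1/6},$$

the natural distance scale of the NOE. When all nine distances are about
equal, $d_\mathrm{eff} \approx 9^{-1/6} d \approx 0.693\,d$, so a 5 Å
cutoff on $d_\mathrm{eff}$ admits inter-carbon separations up to
$5/0.693 + 2\times1.1 \approx 9.4$ Å (`max_carbon_separation()`). A
directional expected NOESY peak is generated for every ordered methyl pair
with $d_\mathrm{eff} \le d_\mathrm{cut}$; expected HMQC peaks (one per
methyl) and expected geminal HCcCH correlations (one per ordered Leu/Val
pair, when such a spectrum is available) carry observation probability 1,
expected NOESY peaks carry $p_\mathrm{NOE} = 0.1$ by default — most
expected NOEs are *not* observable in a real spectrum, and the low weight
expresses that an individual missing NOE is unremarkable.

Structures may be supplied as PDB files. If methyl protons are absent
(X-ray structures), they are constructed with ideal tetrahedral geometry:
C–H bond length 1.1 Å, H–C–stem angle 109.47°, torsions staggered at 60°,
180° and 300° from a reference substituent. Methyl rotation is not
averaged: the $r^{-6}$ sum over nine distances is insensitive to the
torsion at the precision relevant here, and only the bond length enters
the contact scale.

Because the choice of $d_\mathrm{cut}$ is necessarily arbitrary, the full
protocol runs three series of optimizations at $d_\mathrm{cut}-0.5$,
$d_\mathrm{cut}$ and $d_\mathrm{cut}+0.5$ Å and consolidates across all of
them; assignments that depend delicately on the cutoff do not survive
consolidation.

## Peak-list preparation

Measured NOESY lists are optionally filtered for reciprocity (a cross peak
must have a transposed partner within the matching tolerances) and
signal-to-noise ($S/N \ge 2$ by default). Reciprocity is evaluated after
the S/N cut: a partner removed by S/N also removes its mate. For 3D lists,
whose transposition is underdetermined, the two dimensions of the shared
nucleus are swapped and the unpaired dimension is left unconstrained.

Each NOESY peak is then attributed to the residue types of the two HMQC
peaks with the closest matching shifts (box metric, scaled by the
tolerances; ties break toward the lower HMQC peak id) and written to a
per-type-pair list; peaks matching no HMQC peak within tolerance go to an
untyped catch-all list matched against all types downstream. Residue
typing can come from labeling information, from a file, or from a
best-guess classification of the HMQC plane using packaged per-type shift
statistics (mean ± one standard deviation boxes; Ile δ1 is usually
resolved by its upfield ¹³C shift, Leu and Val are always merged into a
joint type, and the Ala/Leu-Val overlap region is either attributed to Ala
up to the sequence count or labeled ambiguously).

The matching tolerances — 0.4 ppm for ¹³C and 0.04 ppm for ¹H — are used
identically in preparation, optimization, consolidation and evaluation.

## The assignment state and its score

The optimizer works on the mapping $q$ from methyls to measured HMQC peaks
(0 = unassigned), restricted by residue typing. The shifts implied by a
state are the coordinates of the mapped HMQC peaks; every NOESY/geminal
expected peak is mapped to the measured peak (within its type-pair list or
the catch-all) that maximizes a Gaussian alignment factor
$\prod_d \exp(-\Delta_d^2 / 2\sigma_d^2)$ subject to all deviations lying
within the tolerances, or left unmapped. The score of a state is

$$S(q) = \sum_{\text{mapped } e} p_e \prod_d e^{-\Delta_d^2/2\sigma_d^2}
\;-\; \lambda \sum_{\substack{\text{same-nucleus pairs}\\ |\Delta| < \sigma}} (1 - |\Delta|/\sigma)^2
\;-\; \mu \, \#\{\text{unexplained measured HMQC peaks}\},$$

with $\lambda = 0.05$ and $\mu = 0.3$ by default. The three terms express
peak alignment, minimization of chemical-shift degeneracy, and
completeness. The concrete form of the two penalty terms is this
package's own construction, and two design choices deserve comment:

* The degeneracy penalty is *proximity-weighted* rather than a bare count
  of near-degenerate pairs. A bare count cannot distinguish two methyls
  legitimately crowded 0.3 ppm apart from two methyls artificially mapped
  onto the same peak; with realistic shift distributions, a count-based
  penalty strong enough to matter actively rewards un-assigning or
  doubling peaks in crowded regions. The weight $(1-|\Delta|/\sigma)^2$ is
  1 for exact coincidence and 0 at the tolerance edge, so artificial
  doubling costs the full penalty while natural crowding costs little. The
  weight $\lambda$ is deliberately small: on clean data the ground-truth
  mapping must remain the global score optimum, and the penalty acts as a
  tie-breaker, not a driving force.
* The completeness term charges $\mu$ for every measured HMQC peak that no
  methyl explains. Every HMQC peak of a selectively labeled sample *is* a
  methyl, so a state that leaves peaks unexplained while doubling methyls
  elsewhere contradicts the data. Without this term, sparse expected
  networks admit high-scoring degenerate states that explain extra
  expected peaks through borrowed coordinates.

On noise-free synthetic data with every expected peak observed, the
ground-truth mapping is a global optimum of this score (asserted against
an exhaustive oracle on small instances in the test suite).

## Optimization

Assignments are optimized by a memetic evolutionary algorithm: a
population (200 by default) of random residue-type-consistent starts;
score-ranked tournament selection; uniform per-methyl recombination (each
methyl inherits its peak from one parent, so an atom's peak mappings
travel together); sparse random remapping mutation; and, decisive in
practice, greedy local search applied to every offspring. The local search
mixes five proposal kinds: steepest single-methyl moves, random
reassignments, unassignments, pair swaps, and a ruin-and-recreate move
that tears out a methyl together with its expected-network neighbors and
greedily reinserts them (seeded preferentially at methyls with unrealized
expected-peak mass). An ejection-chain move seeded at unexplained HMQC
peaks rotates assignment cycles that single moves cannot traverse. All
moves are accepted greedily (never decreasing the score), so the score
trace of a run is non-decreasing.

The completeness penalty $\mu$ is annealed from 0 to its full value over
the first half of the generations: early on, doubled peaks act as cheap
transit states for the search; by the end they are fully penalized. The
best state ever seen, judged at the full penalty, is returned.

The local-search budget (`iterations`, 15,000 by default) is interpreted
as the total number of stochastic proposals per optimization run,
apportioned evenly across the generations to every offspring; the
steepest-descent sweeps that polish each offspring come on top of this
budget. One hundred independent runs per distance cutoff are performed,
each from a different random start; run $i$ uses seed $\mathrm{base}+i$,
so the whole batch is reproducible bit-for-bit. The generation budget (40,
with early stopping after 10 stagnant generations) bounds each run; the
reduced configurations used in the test suite scale population,
iterations, runs and generations down together (population 50, 3,000
proposals, 20 runs per cutoff, 14 generations, stagnation 5), sizes at
which the optimizer still reaches the exhaustive-search optimum on every
clean benchmark instance we generate.

## Consensus, confidence and geminal pairs

Each run delivers per-atom shifts (the median of the measured coordinates
mapped to the atom) and a count of supporting methyl–methyl NOEs. Pooling
all runs (3 × 100 in the full protocol), the consensus shift of an atom is
the global maximum of a sum of Gaussians centered at the per-run values,
with standard deviation equal to the tolerance; the maximum is located
over the run values refined by a grid of spacing tolerance/20, ties
breaking toward the lower ppm. An assignment is **strong** when more than
80% of the runs agree with the consensus within tolerance for both nuclei
*and* at least one methyl–methyl NOE supports it; everything else is
**weak** but still reported, with up to three alternative shift options.
The agreement criterion is implemented as the run fraction, not as the
literal integral of the Gaussian sum over the consensus window: a
unanimous run set concentrates only ≈68% of a single Gaussian's mass
within ±1 sd, so the integral reading would label unanimity weak — an
evident internal contradiction that the fraction reading resolves.

Geminal Leu δ1/δ2 and Val γ1/γ2 pairs need special care because no
stereospecific assignment is attempted: individual runs may deliver the
two methyls' shifts in either order. Before consolidation the two
(¹³C, ¹H) shift pairs of each run are sorted so slot 1 receives the
smaller values (ordered by ¹³C, ties by ¹H), keeping each ¹H attached to
its own ¹³C. Sorting the two nuclei independently can pair the lower ¹³C
with the wrong ¹H whenever the two orders disagree; the joint treatment
cannot. The per-atom NOE support reported is the median over the runs in
which the atom was assigned, and geminal HCcCH correlations do not count
as NOE support — the ≥1-NOE rule is about through-space evidence.

Against a reference shift list, a strong assignment is *correct* when
both consensus shifts lie within the tolerances of the reference values
of the same atom, with geminal pairs compared as ordered pairs after the
same sorting.

## The synthetic benchmark generator

`simulate_methyl_dataset()` builds complete benchmark datasets with ground
truth. Methyl carbons are packed by rejection sampling into a sphere of
radius $3.7\,n^{1/3}$ Å — about 220 Å³ per methyl, the density of folded
proteins, which yields the ~5 NOE contacts per methyl observed in real
filtered methyl-NOESY data — with 3.5 Å minimum separation and geminal
partners placed 1.8–3.0 Å apart. Protons are built with the ideal
geometry above; shifts are drawn per residue type from the packaged
statistics. The HMQC list contains one peak per methyl (minus an optional
dropout rate); directional NOESY peaks are emitted for every pair with
$d_\mathrm{eff} \le 6$ Å — NOEs remain observable beyond the 5 Å
expected-network cutoff — each observed with probability `p_obs`,
jittered by a configurable fraction of the tolerance, and augmented by
artifact peaks drawn uniformly over the occupied shift ranges. Peak
signal-to-noise follows a log-normal distribution whose median decays
with $d_\mathrm{eff}^{-6}$, consistent with the volume model, so the
standard $S/N \ge 2$ filter removes most contacts beyond ≈5.5 Å exactly
as intensity filtering does on real spectra. Everything is a pure
function of the seed.

What the generator does *not* emulate: spin diffusion, chemical exchange,
overlap-induced peak merging in crowded regions, spectrometer artifacts
with structured (non-uniform) positions, and shift correlations between
neighboring methyls. Passing the synthetic benchmarks therefore
demonstrates correct network matching and calibration under controlled
imperfections, not performance on any particular real protein.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; the C++ optimizer uses its
  own portable 64-bit generator so results are identical across platforms.
* Score ties in the optimizer are broken by move order under the run's
  seed; exact co-optima (e.g. network automorphisms, or the two
  within-pair orders of a geminal pair) are *intended* to scatter across
  runs and be resolved — or flagged weak — by consolidation.
* Methyls with no NOE contact under the cutoff are unconstrained beyond
  their residue type; they can never become strong (no NOE support) and
  their reported shifts are arbitrary among the unused peaks of their
  type.
* Coincident proton positions (distance 0) and collinear stem geometries
  are rejected with errors rather than silently propagated.
* An empty measured HMQC list, a labeling scheme letter with no residues,
  and sequence/structure mismatches all fail before any optimization
  starts.

## Problem sizes used in the tests

The acceptance-style tests run the full protocol on 50-methyl synthetic
datasets with 3 × 20 runs, population 50 and 3,000 local proposals —
roughly one minute per dataset on one CPU — over ten seeds for the clean
benchmark and five for the noisy one (10% artifacts, 10% missing NOEs,
jitter 0.25 × tolerance). The oracle-equivalence tests use 6-methyl
instances where exhaustive enumeration over all type-consistent
injections is feasible. The same configurations are exercised by
`scripts/acceptance.R`, which regenerates the benchmarks and recomputes
coverage, error and explained-NOE fractions from scratch.

## Known limitations

* The exact weighting of alignment, completeness and degeneracy in the
  score is a design choice of this package; its stated properties
  (alignment, completeness, degeneracy minimization, truth-optimality on
  clean data) are what the tests enforce.
* Stereospecific geminal assignment is out of scope by design.
* Spectra are never touched: the package starts from peak lists, and no
  peak picking or shift prediction is provided.
* Multimeric proteins are handled by collapsing identical chains onto one
  renumbered sequence when reading the structure; inter-chain NOEs then
  map onto the same resonances, which matches the NMR equivalence of
  identical subunits but gives up chain-specific information.
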