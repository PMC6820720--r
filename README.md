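# methylassign

Structure-based automatic assignment of methyl ¹H/¹³C NMR resonances.

Methyl-TROSY spectroscopy of large, selectively methyl-labeled proteins
(Ile, Leu, Val, Ala, Met, Thr) gives one sharp 2D [¹H,¹³C]-HMQC peak per
methyl group — but the peaks are anonymous. When a 3D structure is
available, methyl–methyl NOESY cross peaks tie the peaks together into a
network that mirrors the structure's methyl contact graph, and assignment
becomes a combinatorial matching problem. `methylassign` solves it for
NMR spectroscopists working on large systems where classical
through-bond assignment is impossible: it generates expected peaks from
the structure, matches them to the measured HMQC/NOESY peak lists with an
evolutionary algorithm plus greedy local search, repeats the optimization
hundreds of times over a triplet of NOE distance cutoffs, and
consolidates the runs into consensus chemical shifts with a calibrated
**strong**/**weak** confidence label.

## The model in brief

* Effective inter-methyl distance: the r⁻⁶ sum over the nine
  proton–proton distances,
  *d*_eff = (ΣᵢΣⱼ d_ij⁻⁶)^(−1/6) ≈ 0.693 d for equal distances; expected
  NOESY peaks are generated for ordered pairs with *d*_eff ≤ *d*_cut
  (5 Å default, run jointly with *d*_cut ± 0.5 Å).
* Assignment state: a residue-type-consistent mapping from methyls to
  HMQC peaks; NOESY/geminal expected peaks map to their best in-tolerance
  measured peak. Score = Σ p·Π_dims exp(−Δ²/2σ²) − λ·(proximity-weighted
  shift-degeneracy) − μ·(unexplained HMQC peaks), with tolerances
  σ = 0.4 ppm (¹³C) / 0.04 ppm (¹H).
* Consensus: the global maximum of a Gaussian-kernel sum over the per-run
  shifts; an assignment is strong when >80% of runs agree within
  tolerance on both nuclei **and** at least one methyl–methyl NOE
  supports it. Geminal Leu/Val pairs are consolidated jointly
  (smaller/larger sorting, ¹H kept attached to its ¹³C) — no
  stereospecific claim is made.

The package also ships XEASY/Sparky peak-list IO, reciprocity + S/N ≥ 2
NOESY filtering, residue-type attribution of NOESY peaks from the HMQC
plane, best-guess residue typing from packaged shift statistics, a
synthetic benchmark generator with ground truth, and a parameter-sweep
harness. See the methods vignette (`vignettes/methyl-assignment.Rmd`) for
the full account.

## Worked example

```r
library(methylassign)

# a 30-methyl synthetic protein with full ground truth
ds <- simulate_methyl_dataset(sim_config(n_methyls = 30, seed = 7))
ds
#> <methyl_simulation> 30 methyls (radius 11.5 A), 30 HMQC, 260 NOESY, 26 geminal peaks, seed 7

res <- run_methyl_pipeline(ds, config = optimizer_config(
  population = 50, runs = 10, iterations = 3000,
  generations = 14, stagnation = 5, seed = 1))
res
#> <methyl_pipeline> 30 methyls | 30 runs | strong 28 (correct 28, erroneous 0) | explained NOEs 78.0%

head(tidy(res)[, c("methyl_id", "restype", "shift_c", "shift_h",
                   "fraction", "noe_support", "strength", "status")], 5)
#> # A tibble: 5 × 8
#>   methyl_id restype shift_c shift_h fraction noe_support strength status
#>   <chr>     <chr>     <dbl>   <dbl>    <dbl>       <dbl> <chr>    <chr>
#> 1 1-CB      ALA        18.8   1.53     1               2 strong   correct
#> 2 2-CD1     LEU        22.2   0.817    0.867          12 strong   correct
#> 3 2-CD2     LEU        23.1   0.588    0.867          14 strong   correct
#> 4 3-CG1     VAL        21.0   0.722    0.5            10 weak     not-strong
#> 5 3-CG2     VAL        22.8   1.02     0.9            10 strong   correct
```

28 of 30 methyls are assigned with high confidence and all of them match
the ground truth; methyl 3-CG1 only reached the same shift in half of the
30 pooled runs, so it is reported weak (with ranked alternatives) rather
than guessed. `autoplot(res)` draws the consensus HMQC plane colored by
confidence; `glance(res)` returns the one-row summary. Real data enter
through `run_methyl_pipeline(structure_file = , hmqc_file = ,
noesy_file = , ...)` or the stage functions (`read_structure()`,
`extract_methyl_groups()`, `filter_noesy()`, `attribute_noesy_types()`,
`assign_runs()`, `consolidate_runs()`, `write_reports()`); the reports
are a `consol.prot` shift list, a `consol.tab` assignment table (strong
rows carry the literal label `strong`) and `flya.txt` peak-count
statistics. A thin command-line front end with `prep / assign /
consolidate / simulate / sweep / run` subcommands is installed under
`inst/cli/methylassign`.

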