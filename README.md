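# phaseseed

Seed-phase dual-space phasing for centrosymmetric (P2₁/c) small-molecule
crystal structures, with a classical direct-methods engine, a prior-weighted
tangent formula, and the statistical machinery to decide — automatically and
reproducibly — when phasing succeeded.

## Who this is for

Crystallographic methods developers who want a self-contained, fully
synthetic test bed for seed-phase strategies: a small subset of reflections
(the *seed* — in production the output of a neural-network phase predictor,
here also ground truth, a controlled noise model, or a TSV import) gets
assigned 0/π phases, and dual-space electron-density-modification (EDM)
cycles extend them to the full data set. Everything runs from code: no
structure database, no trained network, no binary fixtures.

## The core machinery

For a centrosymmetric structure every phase is a sign, `F_h = ±|F_h|`.
The package provides:

- **Synthetic ground truth** (`generate_structure`, `generate_cohort`):
  P2₁/c cells with volumes 1000–3500 Å³, 10–55 non-H atoms, optional heavy
  atoms and pseudo-translation, packed at a 1.5 Å minimum distance.
- **Reflection machinery** (`make_reflections`): Laue 2/m orbit reduction,
  P2₁/c systematic absences, ε factors, structure factors by direct
  summation, and normalized `E` values (shell-flattened Wilson
  normalization).
- **Seeds** (`true_seed`, `noisy_seed`, `random_seed`, `import_seed`): the
  index box √(h²+k²+l²) ≤ 10, h ∈ [−10,10], k,l ∈ [0,10], with quality
  metrics MPE_seed and CORR_seed.
- **Direct methods** (`select_n_large`, `find_triplets`, `run_tangent`,
  `multisolution`): triplet invariants with
  `G = 2σ₃σ₂^(−3/2)|E_h E_k E_{h−k}|` and the centric tangent update
  `sign(Σ G cos(arg) + G′ cos(φ_seed))`, where the seed enters as a prior
  with weight `G′_h = prior_scale · 2σ₃σ₂^(−3/2)|E_h|⟨E²⟩_seed` and enhances
  the reliability of triplets whose contributors it phases.
- **EDM** (`edm_refine`, `solve_structure`): sharp E-map truncation cycles
  for phase extension, followed by a gated positivity consolidation on the
  damped F(000)-augmented map under which a true solution is a provably
  exact fixed point. Strategies: path A (seed + EDM), path B (multisolution
  DM + EDM), path C (DM with seed prior + EDM), and `auto` (C when the data
  resolution is worse than 1.4 Å, A otherwise).
- **Metrics** (`mean_phase_error`, `map_correlation`, `r_factor`): all
  origin-aware over the 8 permissible origins of P2₁/c.
- **Evaluation** (`cluster_solved`, `efficiency`, `class_thresholds`,
  `rf_classify`, `resolution_benchmark`): 2-means solved/unsolved
  clustering with silhouettes, efficiency `E = 100D/N` with
  `σ_E = √(E(100−E)/N)`, Q1/Q3 seed-quality classes, a tenfold
  cross-validated random forest with ROC-constrained thresholding and Gini
  importances, and resolution cut-off benchmarks.

## Worked example

```r
library(phaseseed)

st <- generate_structure(vol_range = c(1000, 2000),
                         n_asym_range = c(10, 25), rng_seed = 42)
st
#> crystal_structure [P21/c]: N_asym=10 Vol=1915 A^3 maxW=16.0 Pseudo=0%

rs <- make_reflections(st, res_limit = 0.9)
rs
#> reflection_set: 2755 unique reflections, res_limit=0.90 A

seed <- noisy_seed(rs, flip_fraction = 0.1, rng_seed = 42)
seed
#> phase_seed [noisy(0.1)]: 933 reflections, coverage 33.9%

ev <- evaluate_seed(seed, rs)
sprintf("MPE_seed = %.1f deg, CORR_seed = %.3f", ev$MPE_seed, ev$CORR_seed)
#> "MPE_seed = 17.9 deg, CORR_seed = 0.768"

sol <- solve_structure(rs, seed, strategy = "seed", rng_seed = 1)
sol
#> phase_solution [path A]: MPE_final=11.56 deg CORR_final=0.920 R_f=0.315 (converged)
```

Reading the numbers: the seed covers a third of the 2755 unique reflections
and 10% of its signs are wrong (MPE_seed ≈ 18° since each wrong centric
phase contributes 180°). EDM extension and consolidation recover the full
phase set to an 11.6° mean phase error with a map correlation of 0.92
against the ground-truth density — a solved structure; with a `true_seed`
the same call converges to ~3° and CORR ≈ 1.0, with a `random_seed` it
stalls near 90°/0. The 2-means criterion in `cluster_solved()` makes that
solved/unsolved call automatically on cohorts.

A thin command-line front end ships in `inst/scripts/phaseseed`
(subcommands `simulate`, `seed`, `dm`, `solve`, `bench`, `evaluate`), each
echoing its full configuration and seed into the JSON report.

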