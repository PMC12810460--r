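---
title: "Seed-phase dual-space phasing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-phase dual-space phasing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An X-ray diffraction experiment on a single crystal measures structure-factor
amplitudes $|F_h|$ for Miller indices $h = (h,k,l)$ but not their phases
$\varphi_h$, and both are needed to compute the electron density. For a
centrosymmetric space group such as P2$_1$/c, with the origin on an inversion
centre, every phase is restricted to $0$ or $\pi$ — the phase problem becomes
a sign problem, but with $2^{N}$ sign combinations it is still far from
trivial. `phaseseed` implements, end to end, a seed-phase strategy for this
setting: a small subset of reflections (the *seed*) receives externally
estimated phases — in practice from a neural-network phase predictor, here
also from ground truth, a noise model, or a TSV import — and dual-space
electron-density-modification (EDM) cycles extend and refine those phases to
the full data set. A classical direct-methods (DM) engine is included both as
a baseline and as a host for the *prior-weighted tangent formula* that lets
seed phases steer multisolution DM.

All structures handled are P2$_1$/c, monoclinic b-unique, with the four
operators $(x,y,z)$, $(-x,y+\frac12,-z+\frac12)$, $(-x,-y,-z)$,
$(x,-y+\frac12,z+\frac12)$, Laue class 2/m, systematic absences $h0l$ with
$l$ odd and $0k0$ with $k$ odd, and $\varepsilon = 2$ on the $h0l$ and $0k0$
zones.

# Synthetic ground truth

Because the packaged experiments must be reproducible without an external
network or a structure database, the `crystal` module generates ground-truth
structures whose feature ranges emulate published small-molecule cohorts:
unit-cell volumes of 1000–3500 Å$^3$, 10–55 non-hydrogen atoms in the
asymmetric unit, $\beta \in [95^\circ, 120^\circ]$, a C/N/O palette with one
optional heavy atom drawn from {S, Cl, Fe, Br, Mo, I, W} (present with
probability $2/3$ under the default `heavy = "random"`), a minimum
inter-atomic distance of 1.5 Å between symmetry-expanded sites, a uniform
$B_{\mathrm{iso}}$ of 3 Å$^2$, and an optional pseudo-translation $(0,0,\frac12)$
applied to a chosen fraction of atoms. The feature `maxW` is the standard
atomic weight of the heaviest element (the scale on which heavy-atom
stratification bins ≤50, 50–100, >100 are meaningful), while the atomic
number $Z_j$ is kept separately for the scattering sums. Scattering uses the
point-atom model $f_j(s) = Z_j e^{-B s^2/4}$ with $s = 1/d$; the
normalization to $E$ values divides the radial falloff back out, so a full
multi-Gaussian form factor would change nothing downstream of the $E$'s.

What the generator does *not* emulate: measurement errors beyond a simple
multiplicative Gaussian on $|F|$, absorption and extinction, disorder,
twinning, hydrogen contributions, and — most importantly — any coupling
between structure features and seed-phase quality. The noisy seed provider
flips a *uniformly chosen* fraction of seed signs, so synthetic cohorts can
validate the machinery (clustering, efficiency curves, classifier plumbing)
but cannot reproduce the field-data phenomenology where seed quality depends
on the structure itself. Tests passing on these cohorts show the pipeline is
correct, not that any particular real-data efficiency will be attained.

# Normalization, seeds and metrics

$E$ values are computed per reflection as $E_h^2 = |F_h|^2 / (\varepsilon_h
\Sigma_j f_j^2)$ from the known cell content (or a Wilson fit
$\ln\langle|F|^2/\varepsilon\rangle = \ln K - 2Bs^2$ when only amplitudes are
available), then flattened in ten equal-count resolution shells with linear
interpolation of the shell scale between shell centres in $s^2$, and finally
rescaled so $\langle E^2\rangle = 1$ exactly.

The seed is the set of reflections whose canonical indices satisfy
$\sqrt{h^2+k^2+l^2} \le 10$ inside the box $h\in[-10,10]$, $k\in[0,10]$,
$l\in[0,10]$ — inclusive bounds, matching a $21\times11\times11$ input grid;
a strict-bounds switch exists because the printed inequalities of the source
conventions are ambiguous. Canonical representatives carry the sign factor
$(-1)^{k+l}$ relating orbit members' phases, and imported phase lists are
mapped through that convention.

Solution quality is scored by three origin-aware metrics. The mean phase
error (MPE) is the unweighted mean of the wrapped $|\Delta\varphi|$,
minimized over the eight permissible origins $(0/\frac12)^3$ of P2$_1$/c. The
map correlation (CORR) is the Pearson correlation of the two maps synthesized
with common amplitudes; since F(000) is excluded both maps have zero mean and
Parseval's theorem turns the correlation into a multiplicity- and
$E^2$-weighted mean of $\cos\Delta\varphi$, which is how it is evaluated (the
grid route exists and is cross-checked in the tests). When a solution is
reported, one shift — the MPE-minimizing one — is used for both metrics: a
solution has one physical origin. $R_f = \sum\bigl||F_o| - k|F_c|\bigr| /
\sum|F_o|$ with the least-squares scale $k$.

# The direct-methods engine

Strong reflections ($|E| > 1.2$, strict) form $N_{\mathrm{large}}$; fewer
than 30 of them aborts with an *insufficient statistics* error, the same
condition under which low-resolution data sets are dropped from DM
benchmarks. Triplets $h = k + (h-k)$ are enumerated over all orbit members
with the concentration parameter $G = 2\sigma_3\sigma_2^{-3/2}|E_h E_k
E_{h-k}|$, $\sigma_n = \sum_j Z_j^n$ over the unit-cell content. In the
centric case the tangent update is the sign of $T = \sum_j G_j\cos(\arg_j) +
G'_h \cos(\varphi^{\mathrm{seed}}_h)$ — precisely the maximizer of the
two-point von Mises product probability, against which it is tested
exhaustively — with reliability $\alpha = |T|$.

When a seed is present, each seeded reflection carries the prior weight
$G'_h = s\,\cdot 2\sigma_3\sigma_2^{-3/2}|E_h|\,\langle E^2\rangle_{\mathrm{seed}}$
(`prior_scale` $s$, default 1; $s = 0$ reproduces the seed-free trajectory
exactly), and a triplet with one (both) seeded contributors has $G$ multiplied
by $1 + s/2$ ($1 + s$): externally estimated phases enhance the reliability
of the invariants they enter without overriding the triplet consensus. These
two couplings are this package's concrete reading of a prior-weighted tangent
formula stated only qualitatively in the literature it follows; both collapse
smoothly to classical DM as $s \to 0$.

Updates are Jacobi-style full sweeps (deterministic and order-independent),
stopping when a sweep changes no sign, with a cap of 50. Seed-free trials fix
the origin by setting up to three strong reflections with GF(2)-independent
index parities to $\varphi = 0$ at the start; seeded trials skip this — the
seed pins the origin. Multisolution runs `n_trials` random starts, ranks them
by mean $\alpha$, re-ranks the top ten by the R factor after a short
extension-only EDM, and returns the winner.

# EDM: extension and consolidation

The dual-space refinement is deliberately two-stage, and this is the one
place where the package departs from the most obvious single-recipe design,
for a reason worth recording.

**Extension** is the classical aggressive recycling: synthesize a sharpened
E-map from $|E|$-amplitudes and current signs, zero negative density, keep
only the top `keep_fraction` (default 2.5%) of grid points, invert, snap each
phase to the sign of the recovered coefficient, reimpose observed amplitudes;
seed phases are held fixed for the first `lock_cycles` (default 15 of 30)
cycles. This stage has the phasing power: it routinely pulls a
58%-coverage true seed plus random fill to a few degrees of MPE.

**Why a second stage exists.** A band-limited point-atom map carries Fourier
ripple, so *any* hard truncation perturbs every coefficient by a finite
amount; reflections with $|E|$ below that perturbation can flip even when the
input phases are exactly true. A single-stage truncation EDM therefore has no
exact fixed point at the truth — started from true phases it drifts a few
degrees and reports a large truncated-map R factor. Since "a correct solution
is a fixed point" is both a sanity property and the natural convergence test,
the final **consolidation** stage restores it: amplitudes are damped to a
constant band-edge attenuation $e^{-\mathrm{att}}$ (`consol_att`, default 5),
the F(000) term is added (from the cell content, or a carbon-equivalent
estimate of one C per 18 Å$^3$ when the content is unknown), so a correctly
phased map is essentially non-negative; the only modification is zeroing
negative density; and a phase flip is accepted only when the read-back
coefficient exceeds the rigorous bound $|\delta F_h| \le \mathrm{mean}\,
|\delta\rho - \mathrm{median}(\delta\rho)|$ on what the modification could
possibly have done. At a true solution no flip can pass that gate, so the
truth is *provably* invariant — MPE $= 0$ exactly, not approximately — and
the consolidation R factor is small (order $10^{-3}$ on noise-free data)
because the map actually satisfies the positivity constraint.

Convergence is detected by a consolidation probe run first: the start is
declared converged only if the gated step changes nothing *and* the worst
per-resolution-shell R factor of the modified map is below `consol_rf_tol`
(default 0.1). The shell-wise form matters: damping makes the *global* R
factor insensitive to badly phased high-resolution shells, and a
gate-stability test alone would be vacuous whenever the bound is large. A
run whose extension R factor rises for ten consecutive cycles is rolled back
to its best state and flagged as non-converged.

Solution strategies: path A (`"seed"`) is seed + random fill + EDM; path B
(`"dm"`) is multisolution DM + EDM of the best trial; path C (`"dm_seed"`) is
DM with the seed prior + EDM; `"auto"` chooses C when the data resolution is
worse than 1.4 Å and A otherwise, the decision rule suggested by comparing
the two families across resolution cut-offs.

# Evaluation harness

Solved/unsolved labelling is a 2-means clustering (Hartigan–Wong, ten random
starts under a fixed seed) of standardized (MPE$_{\mathrm{final}}$,
CORR$_{\mathrm{final}}$, $R_f$); standardization is essential because MPE
lives on $[0,180]$ and $R_f$ on $[0,1]$. The cluster with the lower mean
MPE is "solved"; silhouette widths come from `cluster::silhouette`. In the
resolution benchmark all cut-offs and providers are pooled into a single
clustering so that the solvability criterion is shared across the factorial
design — per-cell clustering would let the criterion drift between cells that
contain no genuine failures. Efficiency is $E = 100D/N$ with
$\sigma_E = \sqrt{E(100-E)/N}$, exact closed forms.

Class labels for seed quality use type-7 (linear-interpolation) quantiles —
stated explicitly because Q1/Q3 drive the labels: Class 1 means
MPE$_{\mathrm{seed}} \le$ Q1(MPE$_{\mathrm{seed}}$ of the unsolved cluster)
and CORR$_{\mathrm{seed}} \ge$ Q3(CORR$_{\mathrm{seed}}$ of the unsolved
cluster), boundaries inclusive; the fixed "reliable seed" box is
MPE$_{\mathrm{seed}} < 25^\circ$ and CORR$_{\mathrm{seed}} > 0.8$. The random
forest uses 500 trees, $\sqrt{p}$ features per split and stratified tenfold
cross-validation with pooled out-of-fold probabilities (pooling, rather than
averaging per-fold curves, is the reading taken of a "global ROC curve");
the operating threshold is the highest sensitivity with specificity
$\ge 80\%$, ties toward higher specificity; importances are mean decrease
Gini from a forest refitted on all records.

# Problem sizes and numerical choices

The packaged experiments run at sizes a laptop handles in minutes, chosen
once as the study conditions of the synthetic cohorts: path-A cohorts of
18–30 structures with $N_{\mathrm{asym}} \in [10,25]$ and
$V \in [1000,2000]$ Å$^3$ at 0.9 Å resolution; the resolution benchmark uses
20 structures with $N_{\mathrm{asym}} \in [15,30]$ and $V \in [2200,3200]$
Å$^3$ at 0.95 Å base resolution with cut-offs {none, 1.0, 1.2, 1.4, 1.6 Å},
so that seed coverage stays below 1 across most of the grid. FFT grids are
the smallest 2-3-5-smooth integers with step $\le d_{\min}/3$ per axis.
Phases are snapped by the sign of the real part, ties keep the previous
phase; special positions deduplicate at $10^{-4}$ fractional; the
reflection-order convention (canonical representative has $k \ge 0$ and
$l > 0$, or $l = 0, h > 0$, or $h = l = 0, k > 0$) is fixed so that file
output is bit-stable.

# Known limitations

Only P2$_1$/c is supported; non-centrosymmetric phase binning is out of
scope. The noisy seed provider's structure-independent flips mean synthetic
RF classifiers are validated on constructed generative cohorts, not on an
emergent feature–quality coupling. The EDM consolidation bound is
conservative: phases of very weak reflections may be left unchanged when the
evidence cannot exclude a modification artefact, which is visible as a few
degrees of residual MPE in solved-but-noisy runs. No atom picking or model
building is attempted — the deliverable is the phase set and its metrics.
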