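---
title: "Methods: chemical-shift-driven ensemble selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-shift-driven ensemble selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the geometric and
energetic conventions, the synthetic benchmark and the numerical
choices behind `shiftsel`. It states no empirical result beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## The selection model

Each assigned atomic site carries an experimental shift distribution
modelled as a Gaussian with mean $\mu$ and width $\sigma$ (ppm),
obtained by least-squares peak fitting (`fit_gaussian_peak()`).
Overlapping sites fitted together to a single peak are stored once with
the co-fitted labels in `lumped_with`; every member site is scored
against the shared $(\mu, \sigma)$.

For a candidate environment with predicted shift $\delta$ at a site,
the per-site probability is the **two-sided Gaussian tail**

$$p = \mathrm{erfc}\!\left(\frac{|\delta - \mu|}{\sigma\sqrt{2}}\right),$$

the probability that a draw from $N(\mu, \sigma^2)$ lies farther from
the mean than the prediction. It is 1 at zero deviation, symmetric in
the sign of the deviation, and decreases monotonically with
$|\delta-\mu|$. The environment's score is the **geometric mean** of
the per-site probabilities over a fixed scored-site subset, computed in
log space with a floor of $10^{-300}$ per site so a single catastrophic
site cannot underflow the product. The per-site form is isolated behind
`shift_probability()` so an alternative (for instance a width convolved
with the predictor's own error) can be swapped in without touching the
rest of the pipeline.

The NMR set is the top-$N$ environments after a stable descending sort
by p-value with ties broken lexicographically by environment id — the
tie rule makes selection reproducible across platforms. Predicted
shieldings are converted to the shift scale by $\delta = -\sigma_{calc}
+ \text{offset}$, with offsets 30.78 (1H), 170.04 (13C) and 227.9 (15N)
ppm by default.

Chemically equivalent protons (CH2/CH3) can be arithmetically averaged
before scoring (`equivalent_groups`), reflecting their experimental
averaging by fast rotation/exchange; the toy molecule has no such
group, so the default is off.

## Geometry conventions

* Dihedrals follow the IUPAC sign convention (cis = 0°, range
  (−180°, 180°]); mirror images flip the sign.
* All intermolecular distances use the minimum-image convention in
  general triclinic cells: a fractional-coordinate wrap followed by a
  27-neighbour-image refinement, exact below half the shortest cell
  height (and verified against a brute-force image search in the
  tests).
* Hydrogen bonds use the standard geometric criterion, H···A ≤ 2.5 Å
  and D–H···A ≥ 120° with N/O acceptors, the acceptor with the shortest
  H···A distance winning. The criterion is a parameter
  (`hbond_criterion()`) because published occurrence plots rarely print
  one. Intramolecular acceptors are reported per atom label;
  intermolecular acceptors may be grouped into chemical classes through
  a user-supplied map rather than a guessed taxonomy.
* Histograms are probability densities normalized to unit integral so
  sets of different size (full ensemble vs top-$N$) are comparable.
  Periodic (dihedral) histograms centre bins on multiples of the bin
  width with a single wrap-around bin at ±180°. Defaults: 10° bins for
  dihedrals, 0.5 Å for distances — fine enough to resolve basin
  structure without empty-bin noise at a few thousand environments.
* Promotion/demotion classifies each bin by the NMR/MD density ratio
  with thresholds 1.25 / 0.8; bins with zero MD density are flagged
  rather than classified, and `run_pipeline()` additionally requires a
  minimum MD occupancy (default 25 environments) before flagging a bin
  as promoted, since ratios on nearly empty bins are noise.

## Formation energies

Local environments are clusters: the central molecule plus every
molecule with at least one atom within 7 Å (boundary inclusive),
neighbours shifted to the periodic image nearest the central molecule.
Three backend evaluations give
$\Delta = E_\text{with} - E_\text{without} - E_\text{central}$;
$E_\text{with} - E_\text{without}$ is stored too, since the two
readings differ only for backends with intramolecular terms. Profiles
along a geometric feature report per-bin means referenced to the
minimum MD-sample bin (so the MD profile's minimum is 0 and both sets
share that zero) with, by default, the within-bin standard deviation of
the per-environment energies as the spread (the standard error of the
mean is available via `spread = "se"`).

The built-in backend is a deliberately simple pairwise intermolecular
potential, not a stand-in for any particular level of theory: a
truncated-and-shifted Lennard-Jones term between heavy atoms
(ε = 0.4 kJ/mol, σ = 3.0 Å, cutoff 10 Å, frozen below 2.5 Å so steric
overlaps in randomly placed glasses cannot produce divergent energies)
plus a Gaussian donor–acceptor well for H···N/O contacts (depth
10 kJ/mol at 1.9 Å, width 0.3 Å). Hydrogens carry no Lennard-Jones
term — united-atom style — so a 1.9 Å hydrogen bond is net stabilizing,
as it must be for the energetics stage to be interpretable. Because
the potential is strictly intermolecular, a cluster's $\Delta$
decomposes exactly into central↔member pair sums, which the tests
exploit as an analytic oracle. Precomputed energies from an external
engine enter through `file_backend()` (CSV of
`env_id,e_with,e_without,e_central`).

## The synthetic benchmark

The generator emulates the *shape* of the real problem — a flexible
molecule whose donor can lock an intramolecular H-bond while the rest
stays disordered — with fully known ground truth:

* **Molecule**: 12 atoms; hydroxyl-like donor O1–H1, four backbone
  torsions τ1–τ4, acceptor N7, and a rigid four-carbon ring on C2.
  Geometry is a deterministic function of (τ1..τ4).
* **Basins**: "closed" τ = (−60°, 4°, 105°, −28°), width 3° →
  H1···N7 ≈ 1.9 Å at a ≈160° donor angle; "open" τ = (180°, ...),
  width 15° → H1···N7 ≈ 7.3 Å. Torsion jitter is a ±3σ-truncated
  normal, and any draw violating its basin's guarantee (closed
  < 2.5 Å, open > 4 Å) is redrawn, so basin labels are exact and
  recomputable from the emitted geometry (`recompute_ground_truth()`).
* **Packing**: molecules are placed at random positions/orientations
  in a 30 Å periodic cube with centres ≥ 8 Å apart. Placement ignores
  intermolecular energetics on purpose: the pipeline consumes
  ensembles, not their provenance.
* **Surrogate shifts** (stand-in for a learned predictor):
  $\delta(\mathrm{H1}) = \delta_0 + A_{hb} e^{-r_{HA}/r_0}$,
  similarly for N7 with a larger amplitude, ring carbons couple to τ1
  as $B\cos\tau_1$, all sites get $N(0, 0.1^2)$ ppm noise. Defaults
  ($A_{hb}=8$, $A_{hb,N}=20$, $r_0=1$ Å, $B=4$ ppm) give a planted
  H-bond signature of ~1 ppm on H1 — large against the noise, as in
  well-resolved solids.
* **Scale**: 4 runs × 50 frames × 25 molecules = 5,000 environments
  with $N = 500$ selected (10%), a desk-scale mirror of selecting a
  few thousand environments from hundreds of thousands. The
  energetics stage samples 75 environments per run (300 total) plus
  300 NMR-set members; these sizes keep the full acceptance
  computation around a minute while leaving per-bin counts in the
  dozens.

**Presets.** `planted_hbond` (bias 0.40, distributions from the closed
basin) tests signal recovery; `planted_torsion` zeroes the H-bond
amplitudes so only the ring-carbon torsion coupling carries signal;
`null` uses a symmetric mixture (bias 0.5) with *all couplings zeroed*
and distributions fitted to the whole ensemble.

A subtlety worth recording: fitting distributions to the whole ensemble
while keeping the couplings is **not** a null experiment. The fitted
Gaussian then straddles both basins, and the geometric-mean score
favours whichever basin has the larger within-basin shift variance (its
members get more draws near the grand mean) — in calibration runs this
"pseudo-null" enriched the closed basin to ~0.69 at bias 0.5. A true
null requires shifts that carry no conformational information at all,
which is what the null preset does; its enrichment ratios then sit
within binomial Monte-Carlo bounds of 1, as the acceptance tests check.
The pseudo-null behaviour is a real property of tail-probability
scoring against overdispersed distributions, and users comparing
broad-distribution fits should be aware of it.

## What the synthetic tests do and do not show

Passing the planted-recovery and null benchmarks shows the machinery is
sound: scoring, ranking, censusing and promotion analysis recover known
structure and fabricate none. It does **not** validate shift-prediction
accuracy on real molecules (the surrogate is a closed form, not
physics), force-field realism (there is no dynamics, only placement),
or the energetic realism of the toy potential. Real applications
substitute tabular predictions from a learned model, real experimental
distributions, and (optionally) precomputed quantum-chemistry cluster
energies via the file backend — the interfaces are identical.

## Degenerate inputs and edge rules

* Gaussian fitting: means are initialized at successive residual
  argmaxima, widths at ¼ window width; up to 5 deterministically
  jittered restarts; windows without positive signal raise an
  "empty window" error.
* Assignment refinement is per-site independent (two solution shifts
  may match one solid peak — lumped peaks make many-to-one legitimate);
  deviations beyond 1 ppm (1H) / 5 ppm (13C, 15N) flag a site
  unassigned. The 13C ceiling leaves headroom above the ~3 ppm
  solution↔solid deviations seen in practice.
* Scoring requires the identical scored-site set in every environment;
  duplicate environment ids abort. With all widths inflated, every
  p-value tends to 1 and selection degenerates to the documented tie
  rule.
* `extract_cluster()` refuses cutoffs at or above half the shortest
  cell height, where periodic neighbour search becomes ambiguous.
* Planted distribution widths are floored at 0.01 ppm so a noiseless,
  coupling-free site cannot produce a zero-width (infinitely sharp)
  distribution.

## Command-line use

The package's interface is its R functions; the end-to-end driver is
`run_pipeline()`, and `scripts/acceptance.R` is a worked, seeded,
non-interactive entry point that regenerates the benchmark and writes
the headline quantities as JSON (see the README).
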