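# shiftsel

Chemical-shift-driven ensemble selection ("NMR crystallography") for
amorphous molecular solids.

## The problem

Amorphous drugs — including modern heterobifunctional degraders
(PROTACs) — have no crystal to solve, yet their local structure controls
stability and dissolution. Solid-state NMR chemical shifts encode each
atom's local environment, so the atomic-level structure of a glass can
be characterized by **matching predicted shifts of many candidate
environments against the experimental shift distributions**:

1. Model each assigned site's experimental shift as a Gaussian
   (mean μ, width σ, in ppm), from peak fits of the solid-state spectra;
   solution-state assignments are refined to the nearest solid-state
   peaks.
2. Generate a large, diverse ensemble of candidate molecular
   environments (e.g., molecular-dynamics snapshots of a model glass)
   and predict each atom's chemical shift in every environment
   (machine-learned predictors; an affine shielding→shift referencing
   with slope −1 per nucleus).
3. Score each environment by the **geometric mean of the per-site
   probabilities** that its predicted shifts fall within the
   experimental distributions, where the per-site probability is the
   two-sided Gaussian tail
   `p = erfc(|δ_pred − μ| / (σ√2))`.
4. Select the top-N environments (the **NMR set**) and compare its
   structural motifs — hydrogen-bond acceptors, dihedral and distance
   histograms, 2D correlations, cluster formation energies — against the
   full ensemble (the **MD set**). Motifs with higher probability
   density in the NMR set are *promoted*; lower, *demoted*.

The package implements this whole analysis plus a synthetic-data
generator with planted ground truth (a flexible 12-atom model molecule
with a closable intramolecular H-bond), so every stage is testable
end-to-end without external data. Cluster formation energies use the
three-calculation decomposition
`Δ = E(environment with central molecule) − E(environment without) −
E(central molecule alone)` over 7 Å neighbourhoods, with a pluggable
backend (a documented toy pairwise potential is built in; precomputed
energies can be read from CSV).

## Worked example

```r
library(shiftsel)

# a 5,000-environment synthetic glass: 40% of molecules carry the
# planted intramolecular H-bond; "experimental" distributions are
# derived from that closed-basin subpopulation
case <- make_benchmark_case("planted_hbond", seed = 42)

sel <- score_dataset(case$predictions, case$distributions,
                     atom_subset = case$config$scored_sites, n = 500)
sel
#> ensemble selection: 5000 environments, 500 selected
#>   min selected p-value: 0.5761666

# H-bond census: MD set vs NMR set
envs <- environments(case$frames)
hbond_census(case$frames, envs$env_id, sel$nmr_set,
             data.frame(donor_h = "H1", donor_heavy = "O1"))
#>   donor_h acceptor_class fraction_md fraction_nmr
#> 1      H1       N7|inter      0.0014            0
#> 2      H1       N7|intra      0.3958            1
#> 3      H1           none      0.6028            0

# promotion of the closed-basin torsion
tau1 <- feature_values(case$frames,
                       feature_spec("dihedral", c("O1", "C2", "C3", "C4")))
pm <- promotion_map(histogram1d(as.numeric(tau1), 10, periodic = TRUE),
                    histogram1d(as.numeric(tau1[sel$nmr_set]), 10,
                                periodic = TRUE))
pm[pm$center == -60, c("center", "promotion", "class")]
#>    center promotion    class
#> 13    -60  2.787068 promoted
```

Reading: the planted H-bonded subpopulation makes up ~40% of the MD set
but 100% of the selected NMR set, and the torsion bin at −60° (the
closed-basin conformation) is promoted ~2.8×: the selection recovered
the planted structural signal from the shifts alone. `run_pipeline()`
chains the same stages (scoring, histograms, census, energetics) over
file or in-memory inputs and writes provenance-stamped CSV/JSON
outputs.

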