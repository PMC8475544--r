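# benthosdm

Ensemble species distribution modeling for deep-sea benthic taxa — corals
and sponges recorded as presence-only observations on seamount-studded
terrain.

## The problem

Occurrence records for deep-water corals and sponges come from expeditions,
towed cameras and dredges: they say where organisms were *seen*, never where
they are absent, and they are strongly clustered wherever ships happened to
survey. `benthosdm` implements the presence–background strategy built for
this situation:

- **terrain predictors** from bathymetry: slope (4-cell method), eastness /
  northness aspect indices, Evans-fit curvatures, surface-ratio roughness,
  topographic position index (TPI, multi-scale), vector ruggedness measure
  (VRM, multi-scale);
- **seafloor upscaling**: coarse depth-layered oceanographic fields
  (nutrients, oxygen, carbonate saturation) interpolated horizontally and
  then vertically to each cell's bathymetric depth;
- **bias-matched pseudoabsences**: a 2-D Gaussian kernel density estimate of
  survey effort built from the presence locations, from which 10,000
  background points are drawn so they carry the *same* sampling bias as the
  presences;
- **four learners** with fixed, documented hyperparameters — boosted
  regression trees (Bernoulli loss, tree complexity 3, ≥ 1,000 trees),
  binomial GAM (thin-plate splines, basis dimension 12), a maximum-entropy
  model authored via its penalized-logistic equivalence (linear + quadratic
  + hinge features, regularization multiplier β = 5), and random forest
  (501 trees, depth ≤ 10, mtry = ⌊√p⌋);
- an **AUC-weighted ensemble**: suitability = Σᵢ wᵢ pᵢ with
  wᵢ = AUCᵢ / Σⱼ AUCⱼ;
- **evaluation**: k = 10 Monte-Carlo 80/20 cross-validation reporting AUC
  (rank-sum probability) and TSS (max over thresholds of sensitivity +
  specificity − 1), per-cell uncertainty maps (SD across resampled refits),
  evaluation-strip response curves, permutation variable contributions, and
  the share of highly suitable habitat (> 0.7) per geomorphic class.

Everything is testable without external data through a synthetic seascape
generator (`make_bathymetry()`, `make_env_fields()`, `simulate_species()`)
whose true suitability surfaces are known.

## Worked example

The headline end-to-end check simulates a species with a Gaussian niche in
silicate (optimum 60 µmol l⁻¹, width 8) on a 120×120-cell seamount
seascape, samples 200 presences under two broad effort hotspots, and runs
the full pipeline — effort KDE, 10,000 bias-matched pseudoabsences, all four
learners, ensemble, 10×80/20 CV:

```r
library(benthosdm)
bench <- niche_recovery_benchmark(seed = 1)
bench$summary
#>      model test_auc_mean test_auc_sd test_tss_mean test_tss_sd training_auc training_tss
#> 1      BRT     0.9814713 0.004548104       0.88045  0.03131688    0.9965297       0.9613
#> 2 Ensemble     0.9812688 0.004622132       0.88375  0.02225640    0.9918760       0.9346
#> 3      GAM     0.9672075 0.004026014       0.86920  0.02242048    0.9730120       0.8845
#> 4   MAXENT     0.9652800 0.006254077       0.86485  0.01594618    0.9676175       0.8622
#> 5       RF     0.9814344 0.008162704       0.89100  0.02722132    0.9999735       0.9957
bench$optimum_error_frac   # fitted niche optimum vs truth, fraction of range
#> [1] 0.07286743
bench$contributions
#>   variable         importance contribution
#> 1 silicate         0.97002782   88.643947
#> 2 dissolved_oxygen 0.05269381    4.815313
#> 3 poc_flux         0.03633912    3.320774
#> 4 omega_aragonite  0.03523598    3.219966
```

Every learner ranks held-out presences above held-out pseudoabsences with
mean AUC > 0.96; the ensemble's response curve places the silicate optimum
within ~7% of the variable's range of the planted truth; and the true niche
variable receives 89% of the permutation contribution. Plotting helpers:
`autoplot(bench$suitability)`, `plot_response_curves(bench$curve)`,
`plot_contributions(bench$contributions)`,
`autoplot(bench$evaluation)`.

A config-driven run over the same machinery (YAML in, ASCII grids + CSV +
JSON manifest out) is available as `run_pipeline("config.yaml", "run_dir")`,
with a thin CLI in `inst/cli/benthosdm.R` (`synth`, `terrain`, `run`
subcommands).

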