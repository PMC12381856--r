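# crypticfold

Why does stabilizing a protein sometimes ruin its solubility?
`crypticfold` is an R package for diagnosing the stability–solubility
trade-off of engineered enzymes (its motivating system is the haloalkane
dehalogenase family). It implements the full computational chain linking
thermal-unfolding experiments, unfolding-simulation ensembles and
aggregation predictions:

1. **Global kinetic fitting** of multi-technique thermal denaturation
   data — DSC excess heat capacity, nanoDSF barycentric-mean (BCM)
   curves, CD melts at several scan rates, and isothermal unfolding
   traces — to a three-state irreversible model
   N →(k₁) I →(k₂) D with
   kᵢ(T) = exp[(Eₐᵢ/R)(1/T*ᵢ − 1/T)] (min⁻¹), plus Eyring barriers
   ΔG‡ᵢ(T) = −RT ln[kᵢ h/(k_B T)] at 40/60/80 °C, curve descriptors
   (apparent Tm, Agg_max, onset temperature, reversibility ratio,
   Θ_MRE conversion) and SLS-vs-state-fraction correlation to identify
   the aggregating species.
2. **Markov state models** over 1-D Cα-RMSD feature series: Kabsch
   superposition, microstate k-means, lag-time transition-matrix
   estimation on the largest strongly connected set, PCCA-style coarse
   graining into folded / intermediate / unfolded (with two-intermediate
   merging), Chapman–Kolmogorov validation, per-residue backbone
   B-factors and representative-frame sampling.
3. **Solvent-exposure analysis**: Shrake–Rupley per-residue SASA,
   relative accessibility rASA = SASA/SASA^max (Tien et al. maxima),
   exposed at rASA ≥ 0.25, and detection of residues that cross the
   threshold between the native and intermediate ensembles.
4. **Cryptic-APR analysis**: segmentation of aggregation-score profiles
   into aggregation-prone regions (score > 0.25), the percentage of
   unfolding-exposed residues inside APRs, flagging of *cryptic* APRs
   (natively buried segments that become exposed), mutation-string
   parsing (`"E20S + F80R + ..."`), surface/buried classification of
   mutation sites, and surface-hydrophobicity change on Kyte–Doolittle
   and Eisenberg scales.
5. **Synthetic-data generators** for every input class, with stored
   ground truth, making the whole pipeline testable end to end without
   any external data.

## Worked example

Simulate a complete thermal-unfolding study from known kinetics, fit it
globally, and run the cryptic-APR analysis on a profile with planted
aggregation-prone regions:

```r
library(crypticfold)

truth  <- default_truth_params()
scans  <- gen_thermal_datasets(truth, noise_sd = 0.02, seed = 42)
traces <- gen_isothermal_traces(truth, noise_sd = 0.02, seed = 43)

fit <- global_fit(c(scans, traces), constraint = "auto",
                  n_starts = 10, seed = 1)
print(fit)
#> <fit_result> constraint=fix_dh2, weighted rss=2003.86, converged=TRUE
#> Three-state irreversible unfolding parameters
#>   step 1 (N->I): Ea = 398.3 kJ/mol, T* = 337.01 K, dHcal = 453.3 kJ/mol
#>   step 2 (I->D): Ea = 308.4 kJ/mol, T* = 341.9616 K, dHcal = 0.0 kJ/mol
```

The `auto` constraint tried fixing each step's calorimetric enthalpy to
zero and kept the better dissection (`fix_dh2`: all heat in the first
step, as in the generating truth). The generating parameters
(Eₐ = 400/300 kJ/mol, T* = 337/342 K, ΔH_cal = 450 kJ/mol) are
recovered to ~1–3 % from 2 %-noise data.

```r
barrier_at(fit$params)
#>   temperature       dG1       dG2
#> 1      313.15 115.67897 113.46565
#> 2      333.15  97.80199 101.18679
#> 3      353.15  79.93499  88.91791
```

At 40 °C the first barrier dominates (rate-limiting first step); by
60 °C the order has flipped — the pattern that lets intermediates
accumulate and, if they expose aggregation-prone surface, aggregate.

```r
gp   <- gen_profiles_and_sequences(300, list(c(160, 185), c(260, 280)),
                                   seed = 7)
segs <- segment_aprs(gp$profile)          # recovers exactly 160-185, 260-280
newly_exposed <- c(162:170, 45, 118, 265) # e.g. from exposure_change()
overlap_exposed_aprs(newly_exposed, segs)
#> <overlap_report> 10 / 12 newly exposed residues in APRs (83.3%)

native_rasa <- ifelse(seq_len(300) %in% 150:200, 0.05, 0.5)
flag_cryptic_aprs(segs, newly_exposed, native_rasa)
#>   start end      peak     mean n_hits buried_majority cryptic
#> 1   160 185 0.6957036 0.615657      9            TRUE    TRUE
```

Only the natively buried segment with multiple newly exposed residues
is flagged cryptic: buried in the native state, uncovered by partial
unfolding.

A thin command-line wrapper over the same functions ships in
`inst/cli/crypticfold.R`
(`simulate`, `fit-unfolding`, `cryptic-apr`, `mutations`, `run`), and
`run_pipeline()` orchestrates all stages from a single JSON
configuration with a provenance manifest.

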