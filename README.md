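# microfa

Microscopic fractional anisotropy (μFA) mapping from b-tensor diffusion MRI,
with hippocampal subfield ROI statistics, asymmetry/lateralization indices,
and a synthetic phantom + cohort module — an end-to-end, fully tested
pipeline for temporal-lobe-epilepsy-style hippocampal microstructure
studies.

## The problem

Conventional fractional anisotropy (FA) conflates axon integrity with fibre
orientation dispersion: in crossing-fibre tissue like the hippocampus, FA is
low even when the microstructure is intact, so it is an unreliable marker of
hippocampal sclerosis. μFA separates the two by contrasting linear
tensor-encoded (LTE) and spherical tensor-encoded (STE) acquisitions. With
powder-averaged (direction-mean) signals $\bar S$ per shell, both encodings
share the cumulant expansion

$$\ln \bar S(b) = \ln S_0 - b\,d + \tfrac{b^2}{6} d^2 K_{\mathrm{enc}},$$

and the kurtosis difference isolates microscopic anisotropy:

$$\Delta\mu_2 = \tfrac{d^2}{3}\,(K_{\mathrm{LTE}} - K_{\mathrm{STE}}),
\qquad
\mu\mathrm{FA} = \sqrt{\tfrac32}\Bigl(1 + \tfrac25\,\tfrac{d^2}{\Delta\mu_2}\Bigr)^{-1/2}.$$

The package fits this jointly across encodings (shared $\ln S_0$ and $d$,
weighted linear least squares), fits MD/FA by two-pass WLLS DTI on
b ≤ 1000 s/mm² LTE data, aggregates maps over HippUnfold-style subfield
labels merged to SB / CA1 / CA2-3 / CA4-DG / full hippocampus, and runs the
cohort statistics: Mann–Whitney group tests under two Bonferroni families
(α/16 subregions, α/4 full hippocampus), Spearman correlations, ROC/AUC in
bilateral and single-hemisphere modes, Wilcoxon ipsi-vs-contra tests,
contra-minus-ipsi percentage asymmetry indices, and metric-based
lateralization of the suspected seizure focus. Rank tests come in exact
(enumeration) and corrected-asymptotic (Edgeworth-refined normal) modes.

## Worked example

Simulate a subject-level cohort from the built-in summary specification
(19 TLE patients, 15 suspected unilateral, 18 controls; the μFA cells carry
published group summaries, everything else is a documented plausible
default) and run the full analysis:

```r
library(microfa)
cohort <- sample_summary_cohort(default_cohort_spec(), seed = 42)
an <- run_full_analysis(cohort)
an
#> <mufa_analysis: 19 TLE / 18 HC (15 unilateral)>
#> significant group differences: FullHippocampus/md, FullHippocampus/ufa,
#>   SB/md, SB/ufa, CA4/DG/md, CA4/DG/ufa

dplyr::filter(an$asymmetry_stats, metric == "ufa",
              region == "CA4/DG")[, c("statistic", "p_value",
                                      "mean_asymmetry")]
#> # A tibble: 1 × 3
#>   statistic   p_value mean_asymmetry
#> 1         0 0.0000610           10.7

dplyr::filter(an$roc, metric == "ufa", region == "CA4/DG")
#> # A tibble: 2 × 5
#>   region metric direction     mode                auc
#> 1 CA4/DG ufa    lower_is_case bilateral         0.865
#> 2 CA4/DG ufa    lower_is_case single_hemisphere 0.892
```

Reading: in this simulated cohort, CA4/DG μFA separates patients from
controls (Mann–Whitney p = 1.6e-4, below the 16-way Bonferroni threshold
0.003125), the suspected-unilateral subgroup shows a mean ipsilateral μFA
reduction of ~11% (Wilcoxon W = 0, p = 6.1e-5), and bilateral CA4/DG μFA
classifies TLE vs control with AUC ≈ 0.87 — the qualitative pattern such
studies report. `autoplot(an)`, `plot_group_comparison()` and
`plot_asymmetry()` draw the standard figures.

Voxel-level work uses the phantom module:

```r
phantom <- build_hippocampus_phantom(phantom_spec())   # left CA4/DG lesion
ds <- simulate_subject_dataset(phantom, snr = 50, seed = 1)
maps <- compute_maps(ds$dwi_dti, ds$dwi_ufa, ds$mask)
subject_region_table(maps, phantom$labels_left, phantom$labels_right)
```

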