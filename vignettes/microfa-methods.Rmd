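---
title: "Microscopic fractional anisotropy mapping and hippocampal subfield statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscopic fractional anisotropy mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfa)
```

## The problem this package addresses

Fractional anisotropy (FA) from diffusion tensor imaging is widely used as a
surrogate for axon integrity, but it conflates microstructure with fibre
*orientation dispersion*: a voxel of perfectly intact but crossing or fanning
axons reads as nearly isotropic. In grey-matter structures with complex fibre
architecture — the hippocampus above all — FA is therefore a poor marker of
pathology. Microscopic fractional anisotropy (μFA) removes the orientation
confound by contrasting two diffusion encodings: conventional linear tensor
encoding (LTE), which probes one direction per acquisition, and spherical
tensor encoding (STE), which probes all directions simultaneously.

`microfa` implements a complete, testable pipeline around this idea for
hippocampal subfield studies in temporal lobe epilepsy (TLE): b-tensor signal
simulation, voxelwise estimation of MD/FA (DTI) and μFA (joint powder-average
kurtosis fit), aggregation over hippocampal subfield labels, and the
cohort-level statistics used to compare patients with controls and to
lateralize a suspected unilateral seizure focus. Because patient imaging data
of this kind are not publicly shared, the package carries a synthetic-data
module (voxel-level phantoms and summary-level cohorts) that defines the
study conditions under which every stage is validated.

## Signal model

A voxel is modelled as a mixture of non-exchanging Gaussian compartments:
compartment $i$ has diffusion tensor $D_i$ (μm²/ms) and signal fraction
$f_i$. An acquisition is a b-tensor $B$ (ms/μm²; trace $b$), and

$$S = S_0 \sum_i f_i \exp(-\langle B, D_i \rangle),$$

with $\langle B, D\rangle$ the Frobenius inner product. LTE tensors are
rank-1, $B = b\,\mathbf{u}\mathbf{u}^\top$; STE tensors are $\tfrac{b}{3}I$.
Units keep $bD$ of order one (b = 2000 s/mm² is stored as 2.0); conversion
from s/mm² happens only at the file-format boundary.

Magnitude noise is Rician: $S \mapsto \sqrt{(S+\varepsilon_1\sigma)^2 +
(\varepsilon_2\sigma)^2}$. Noise streams are seeded per volume through a
counter scheme, so appending volumes to a protocol never changes the noise
realisation of earlier volumes.

## Powder-average cumulants and μFA

Averaging the LTE signal over a uniform direction set (the *powder average*)
removes orientational information. Writing $d_i(\mathbf u) = \mathbf
u^\top D_i \mathbf u$, the powder-averaged log-signal of either encoding
expands for small $b$ as

$$\ln \bar S(b) = \ln S_0 - b\,d + \tfrac{b^2}{2}\mu_2 + O(b^3),$$

where $d$ is the mean and $\mu_2$ the variance of the apparent diffusivity
over the relevant measure: compartments *and* directions for LTE,
compartments only (isotropic means $\mathrm{tr}\,D_i/3$) for STE. The
per-encoding powder kurtosis is $K = 3\mu_2/d^2$, and the LTE–STE difference
isolates the microscopic-anisotropy variance
$\Delta\mu_2 = (K_\mathrm{LTE} - K_\mathrm{STE})\,d^2/3$, from which

$$\mu\mathrm{FA} = \sqrt{\tfrac{3}{2}}\left(1 +
\tfrac{2}{5}\,\frac{d^2}{\Delta\mu_2}\right)^{-1/2}.$$

For a single Gaussian compartment this equals the FA of the compartment
tensor — the equivalence that pins the implementation: the suite checks
$|\mu\mathrm{FA} - \mathrm{FA}|$ over random tensors, and checks that
orientation dispersion (coherent → 90°-crossing → uniformly dispersed
micro-tensors) collapses fitted FA while leaving μFA unchanged. A negative
fitted kurtosis difference (possible under noise) is clamped to μFA = 0
rather than propagating imaginary values.

All closed-form cumulants (`substrate_cumulants()`) are themselves verified
against an independent numerical oracle — Gauss–Legendre spherical
quadrature of the powder signal plus one-sided finite differences of
$\ln\bar S$ at tiny $b$ — to 10⁻³.

## Estimation

**DTI (MD, FA).** The log-linear model $\ln S = \ln S_0 - \sum b_{jk}D_{jk}$
is fitted to the LTE volumes with $b \le$ `max_b` (default 1.0 ms/μm², i.e.
1000 s/mm²; higher shells are excluded because non-Gaussian diffusion biases
the tensor representation) by two-pass weighted linear least squares: pass 1
OLS, pass 2 weighted by squared predicted signals. One reweighting pass is
used; further fixed-point iterations change results below 10⁻⁴ in tests.
Eigenvalues are clamped at 0 before FA; an all-zero clamped tensor marks the
voxel invalid.

**Joint powder kurtosis (μFA).** Shell-level powder means of both encodings
are fitted jointly to $\ln\bar S_j = \ln S_0 - b_j d + b_j^2 a_{\mathrm{enc}(j)}$
with $\ln S_0$ and $d$ *shared* across encodings and one quadratic
coefficient per encoding ($a = d^2K/6$). Sharing makes the four-unknown
model identifiable from a single positive-b LTE shell plus two STE shells —
exactly the compact clinical protocol layout (8 LTE at b = 2 plus 3/6/16 STE
at b = 0.1/1/2 ms/μm²; the low-b STE shell enters as an ordinary shell).
Weights are $n_\mathrm{dir}\,\bar S^2$ — the log-transform variance
stabiliser times the direction count that reflects the variance reduction of
powder averaging — refined once with predicted signals. A fitted $d \le 0$
marks the voxel invalid; invalid voxels are dropped from the output mask and
counted, so region means expose the difference between region size and
contributing voxels.

## Numerical choices

* **Cumulant regime for oracles.** The kurtosis representation is a
  truncation: fitted $(d, K)$ converge to the analytic cumulants only as
  $b \to 0$ (the suite asserts monotone error decay over
  $b_\max \in \{2, 1, 0.5\}$). Noise-free oracle comparisons therefore use
  `small_b_ufa_scheme(0.2)` / `small_b_dti_scheme(0.2)` (shells at
  $b_\max \cdot \{0.1, 0.5, 1\}$). At protocol-shaped b-values the
  truncation bias on hippocampus-like substrates is ≈ 0.02–0.025 in μFA —
  immaterial for group contrasts (both sides shift together) but worth
  knowing when comparing absolute values.
* **Direction sets.** Electrostatic-repulsion point sets (n = 6, 8, 36, 60)
  are shipped as frozen fixtures. The oracle-regime schemes use the n = 60
  set: the n = 36 set's residual fourth-moment anisotropy alone can bias
  μFA by up to ≈ 0.1 for unfavourably oriented, strongly anisotropic
  tensors, which would masquerade as fit error.
* **Shells.** b-values are clustered into shells within 50 s/mm²; b = 0
  volumes are treated as an LTE shell (shape is irrelevant at b = 0).
* **No Rician-floor correction** is applied in fitting. At SNR 50 (b = 0)
  the compact μFA protocol's b = 2 shells sit at local SNR ≈ 10, giving a
  cohort-level μFA bias of ≈ 0.04 on the phantom; noise-free the bias is
  the ≈ 0.025 truncation term. The suite asserts the noise-free bound and
  that error shrinks monotonically with SNR.

## Region aggregation

Subfield label volumes follow the HippUnfold dseg convention (1 = SB,
2 = CA1, 3 = CA2, 4 = CA3, 5 = CA4, 6 = DG; lookup shipped as a fixture and
overridable). Analysis regions merge CA2+CA3 (their cell loss is
inconsistent across sclerosis subtypes) and CA4+DG (jointly affected in
CA4-predominant subtypes); SB and CA1 stay separate; the full hippocampus is
the union. Region means are computed on the map's native grid — the caller
provides co-registered labels; no resampling is performed internally, which
keeps the stage testable without an interpolation model. Volumes are voxel
counts times voxel volume on the label grid. Bilateral values are
$(L+R)/2$; missing hemispheres propagate as missing values, reported.

## Statistical layer

Group differences use two-sided Mann–Whitney U tests on bilateral means,
with two separate Bonferroni families exactly as in the study design:
$\alpha/16$ (4 subregions × 4 metrics) and $\alpha/4$ (full hippocampus,
4 metrics); families are never pooled. Ipsilateral/contralateral contrasts
in the suspected-unilateral patient subgroup use Wilcoxon signed-rank tests
with the same families. Spearman correlations (mid-ranks, t approximation)
relate the full-hippocampus metrics within each cohort. ROC curves are
computed for regions flagged by a significant group difference, in bilateral
and single-hemisphere modes; AUC is the exact pairwise statistic
$P(\text{case} > \text{control}) + \tfrac12 P(=)$, which the suite verifies
equals the trapezoidal curve area. Disease direction is fixed per metric:
lower μFA/FA/volume, higher MD.

**Exact and asymptotic modes.** Every rank test exposes `exact`,
`asymptotic` and `auto`. Exact p-values come from the closed-form null
(no ties) or full enumeration (group splits / sign patterns) with ties;
`auto` enumerates whenever it is cheap (n₁+n₂ ≤ 12, pairs ≤ 15), ties
included. The asymptotic mode is a continuity-corrected normal
approximation sharpened, for tie-free samples with n ≤ 30, by an Edgeworth
expansion matched to the exact fourth and sixth null cumulants; with ties it
falls back to the standard tie-corrected normal. The Edgeworth refinement is
needed because the plain corrected normal misses exact enumeration by up to
0.036–0.088 at the smallest samples; with it, agreement is within 0.005
(Mann–Whitney) for group sizes ≥ 5 and within 0.01 (Wilcoxon) for ≥ 6
pairs — asserted exhaustively over all statistics. Below those sizes *no*
smooth approximation can track the null: at n₁ = n₂ = 3 the exact two-sided
p-values live on a lattice with spacing 0.1, so sub-0.005 agreement is
unattainable by construction; use the exact mode there (as `auto` does).

**Asymmetry and lateralization.** The signed asymmetry index is the
contra-minus-ipsi percentage difference
$a = (X_c - X_i)/(0.5(X_c + X_i)) \cdot 100$ (positive = ipsilateral
reduction for anisotropy and volume); controls, lacking a side distinction,
get the order-invariant absolute variant using the larger value as
$X_\max$ — a conservative maximisation. Lateralization predicts the
pathological side as the hemisphere with the lower μFA/FA/volume (higher
MD); exact ties are "indeterminate" and scored incorrect, and
single-hemisphere selection breaks ties toward the left hemisphere (logged
via the returned hemisphere column). An optional MR-negative-only switch
restricts the patient rows to MR-negative subjects before all analyses; the
study design it mirrors applied this filter to the asymmetry subgroup, and
applying it globally is this package's single coherent interpretation.

## The synthetic-data module

**Voxel phantoms.** `build_hippocampus_phantom()` lays two mirrored
hippocampi on a 12×12×6 grid (32 voxels per merged region per hemisphere,
1.8 mm voxels), with all six subfield codes present so the merge rules are
exercised. Each region's substrate is a set of identical axisymmetric
micro-tensors whose axial/radial diffusivities are solved in closed form
from target (MD, μFA) — defaults MD 0.8 μm²/ms, μFA ≈ 0.51–0.52, the range
reported for healthy hippocampus at 3T — with orientations following a
rule: `coherent`, `crossing-90`, or `dispersed` (60 quasi-uniform
orientations; the default, emulating hippocampal crossing/fanning fibres,
which puts ground-truth FA near 0.1 — the reported hippocampal FA range —
while μFA stays at the microscopic value). Pathology is implemented as a
microscopic-anisotropy reduction: radial diffusivity of the affected
regions' micro-tensors is scaled up (numerically, stopping at the isotropic
point) until ground-truth μFA drops by the configured amount (default 0.05
in left CA4/DG, matching the reported ipsi/contra gap); this also raises MD,
consistent with the gliosis/axon-loss interpretation of the contrast.
Region shrinkage (volume pathology) is deliberately off by default — volume
effects were null in the motivating study.

**Summary cohorts.** `default_cohort_spec()` encodes the study conditions:
19 TLE patients (15 suspected unilateral — 10 left, 5 right; 9 of the 15
MR-negative) and 18 controls, with every published μFA cell (full
hippocampus 0.49 ± 0.03 vs 0.52 ± 0.03; CA4/DG 0.47 ± 0.03 vs 0.51 ± 0.03;
unilateral ipsi/contra 0.45 ± 0.04 / 0.49 ± 0.02 and 0.48 ± 0.04 /
0.51 ± 0.02) marked `source = "reported"`. Cells never published as numbers
(MD, FA, volume, remaining subregions) carry plausible 3T defaults in the
reported disease directions, marked `source = "assumed"` — results driven
by those cells characterise the pipeline, not the study.
`sample_summary_cohort()` draws hemisphere pairs from a Gaussian copula
with within-subject correlation 0.5 — a package choice, since the
correlation is not identifiable from published marginals; bilateral-mean
cells inflate the per-hemisphere SD by $\sqrt{2/(1+\rho)}$ so the $(L+R)/2$
spread matches the published SD exactly, while unilateral cells use the
published ipsi/contra marginals directly. Draws outside physical ranges
(anisotropies outside [0, 1], non-positive MD/volume) are redrawn and
counted. Because the ipsi–contra correlation is assumed, the celebrated
15/15 lateralization accuracy of the motivating study is *not* a
reproduction target: accuracy is highly sensitive to that unpublished
parameter.

**What passing tests do and do not show.** The phantom has rectangular
geometry, no partial-volume or CSF contamination, no motion/distortion, and
region-homogeneous substrates; the cohort generator assumes normal
marginals. Green tests therefore certify the estimator and statistics
chain, not robustness to segmentation error, registration error, or
non-Gaussian biology.

## Problem sizes used by the test suite

Simulation scales are chosen to make every check sharp yet quick: 100
random tensors for the μFA = FA equivalence; three phantom recipes for the
dispersion contrast; exhaustive enumeration over all rank-test statistics at
group sizes ≤ 7 / pairs ≤ 12 plus 200 random samples; 2000 null cohorts for
the 16-way family-wise error calibration; 10 phantom-cohort replicates
(15 subjects, SNR 50) for end-to-end detection; 300–1000 cohort replicates
for the published-anchor checks. The full suite runs in a few minutes on
one CPU.

## Known limitations

* No preprocessing (denoising, Gibbs, eddy/distortion), no registration, no
  segmentation: inputs are assumed co-registered and labelled.
* Rician-floor bias (≈ 0.04 in μFA at SNR 50 with the compact protocol) is
  documented, not corrected.
* No directional kurtosis tensor — only the powder-averaged representation.
* No covariate adjustment (age/sex) or missing-data machinery in the
  statistics layer.
* Asymmetry indices are undefined for non-positive value pairs (flagged).
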