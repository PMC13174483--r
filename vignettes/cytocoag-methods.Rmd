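---
title: "Modelling cytokine-enhanced thrombin generation with cytocoag"
author: "cytocoag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cytokine-enhanced thrombin generation with cytocoag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocoag)
```

## The model

`cytocoag` simulates the bidirectional coupling between systemic
inflammation and blood coagulation: pro-inflammatory cytokines (IL-6,
IL-1β, TNF-α) raise tissue factor (TF) availability and suppress the
endogenous anticoagulants antithrombin III (ATIII) and tissue factor
pathway inhibitor (TFPI); thrombin generated by the cascade feeds back to
amplify cytokine production. The package couples three submodels:

1. **Coagulation cascade.** The TF-initiated extrinsic pathway of Hockin,
   Jones, Everse & Mann (2002, *J Biol Chem* 277:18322): 34 species and 42
   rate constants, integrated as a stiff mass-action ODE system. The rate
   table ships as `inst/extdata/coagulation_rates.csv` with per-constant
   citations; every constant can be overridden. Total thrombin is read out
   as IIa + 1.2·mIIa (the conventional meizothrombin activity weight,
   configurable), and the cumulative thrombin–antithrombin complex
   (ATIII-IIa, "TAT") serves as the net-generation biomarker.
2. **Cytokine kinetics.** Each cytokine obeys
   \(dC/dt = p\,m(E) - k_{\mathrm{deg}} C\) with
   \(k_{\mathrm{deg}} = \ln 2 / t_{1/2}\) derived from plasma half-lives
   (IL-6 and IL-1β 1 h, TNF-α 4.6 min) and production \(p\) fixed by the
   steady-state constraint \(p = k_{\mathrm{deg}} C_0\), so the
   unstimulated system holds its normal plasma concentration exactly.
   Thrombin exposure \(E\) multiplies production through a Hill law
   \(m(E) = 1 + e_{\max} E^h / (EC_{50}^h + E^h)\), applied to IL-6 and
   TNF-α (IL-1β feedback ships disabled but is configurable — reports
   differ on whether thrombin amplifies IL-1β directly).
3. **Coupling laws.** Cytokine *excess over baseline*, \(C_e = \max(C -
   C_0, 0)\), drives (i) a TF-induction rate
   \(\sum_j v_{\max,j} C_{e,j}^{h_j} / (EC_{50,j}^{h_j} + C_{e,j}^{h_j})\),
   accumulated over the inflammation phase under first-order clearance of
   the induced pool (half-life 6 h by default, so transient inflammation
   does not permanently raise TF), and (ii) suppression scales
   \(s = 1 - s_{\max} C_e^h/(EC_{50}^h + C_e^h)\) applied to the initial
   ATIII (driven by IL-6) and TFPI (driven by TNF-α) concentrations.
   Using excess rather than absolute concentration makes homeostasis
   exactly neutral: a phase at baseline cytokines reproduces the
   unmodulated coagulation run bit for bit.

### The two-phase protocol

Coagulation resolves in seconds to minutes while cytokine-driven
transcriptional modulation evolves over hours, so the two subsystems are
deliberately phase-split rather than co-integrated. One cycle =
an inflammation phase (12 h or 24 h presets) at the patient's cytokine
tone → the accumulated modulation (induced TF, ATIII/TFPI scaling) is
applied to the coagulation initial state → a 1,200 s coagulation phase at
a 5 pM TF trigger → TG metrics. Across cycles, cytokine state persists
while coagulation factors are restored to the patient's values; cycle
*k*'s inflammation phase runs under the thrombin exposure summarised from
cycle *k − 1* (the endogenous thrombin potential divided by the horizon,
i.e. time-averaged thrombin, by default; peak is selectable; cycle 1
starts cold at zero exposure, which defines a reproducible cold start).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| half-lives | IL-6, IL-1β 3600; TNF-α 276 | s | reported plasma half-lives |
| cytokine baselines | IL-6 2, IL-1β 0.2, TNF-α 2 | pg/mL | healthy-plasma values; *not* authoritative (the clinical table leaves normal cytokines blank), so every shipped analysis is relative to baseline |
| feedback | e~max~ 4 (IL-6, TNF-α), EC~50~ 100 nM, h 2 | — / M | ≈2–5-fold induction at peak physiological thrombin exposure |
| TF induction | v~max~ 3e−16 (IL-6), 2e−17 (IL-1β), 4e−17 (TNF-α) | mol/(L·s) | see calibration note below |
| induction midpoints | 100× (IL-6, h = 2), 20× (IL-1β h = 2; TNF-α h = 1) | baseline multiples of excess | see calibration note below |
| suppression | ATIII ← IL-6: s~max~ 0.5 @ 100×, h 2; TFPI ← TNF-α: s~max~ 0.2 @ 20×, h 2 | — | see calibration note below |
| induced-TF clearance | 6 | h | transient inflammation decays |
| TF trigger | 5 (scenario presets also 25) | pM | standard assay conditions |
| coagulation horizon | 1,200 | s | standard assay horizon |
| solver | lsoda, rtol 1e−8, atol 1e−12 | — / M | concentrations span pM–µM; stiff |

**Calibration note.** The quantitative coupling parameters were, in the
source line of work, fitted against cell-culture dose–response datasets
that are not redistributable; the defaults here are the package's own
calibration, chosen once so that the documented qualitative behaviours
hold simultaneously: (i) the 1× and 2× cytokine states are nearly
superimposable in final ATIII-IIa (< 5% apart); (ii) the dose scan
{0.5, 1, 2, 5, 10, 50}× is monotone with its largest increment between
10× and 50× (a hyperinflammatory tipping point); (iii) IL-6 is the
dominant positive driver among the cytokines; (iv) an SCD-like state
(tight ~30× IL-6, ~60× TNF-α, depleted factor X) shortens the lag but
leaves peak thrombin below the Normal-cohort median, while COVID-19- and
T2DM-like states raise their peaks above their own uninflamed baselines;
(v) the multi-cycle feedback loop visibly amplifies thrombin from cycle
to cycle. Mechanistically this put the IL-6 blocks at a high quadratic
midpoint (100× baseline excess: insensitive to moderate chronic
elevation, steep in the hyperinflammatory decades that the COVID-19
distribution's log-uniform tail reaches) and the TNF-α induction block at
a linear low midpoint (20×), which also gives the thrombin→TNF-α→TF loop
enough marginal gain near baseline for multi-cycle amplification. All of
these are plain configuration (`couplingParams()`), and `fitCoupling()`
performs least-squares Hill fits for users with their own digitised
dose–response measurements.

## Units and the clinical ranges table

All internal state is mol/L; conversions happen at the boundary
(`toMolar()`, with molecular weights in `molecularWeights()` — II 72,
VII/VIIa 50, IX 55, X 59, V 330, VIII 170, ATIII 58, TFPI 40 kDa, all
configurable because clinical tables print mass concentrations without
stating the weights they assume; the VIII default is the processed
circulating heterodimer, which reconciles 0.1 mg/L with the 0.7 nM
mean-plasma reference).

The disease table (`inst/extdata/disease_ranges.csv`) transcribes
published clinical ranges for COVID-19, sickle cell disease, type 2
diabetes and hemophilia A. Resolution rules, each recorded in the file's
note column:

* Percent cells ("60%–130%") follow the clinical factor-assay convention
  of percent-of-normal and resolve against the mean-plasma reference
  concentration — which makes the Normal column reproduce the mean-plasma
  state (the degenerate consistency check in the test suite).
* Mean ± SD cells become normals truncated at mean ± 3 SD, clipped at 0.
  Cells like "±26.72%" are read as one SD (the printed convention is
  ambiguous).
* "< 1%" (hemophilia A factor VIII) samples uniformly on (0, 1%] of the
  normal reference.
* Multi-decade ranges (COVID-19 IL-6 spans 1–32768 pg/mL) are sampled
  log-uniformly; ranges with a zero lower bound uniformly.
* Missing cytokine cells (Normal, hemophilia A) are point masses at the
  configured baselines.
* Two cells are internally inconsistent as printed and are documented
  unit corrections: the ATIII rows ("0.15 mg/L" where plasma antithrombin
  is ~0.15 g/L — 0.15 mg/L would abolish thrombin inhibition entirely)
  are read against the normal reference, as is the VIIa reference
  ("0.2 mg/L" is ~40× physiological free VIIa; the printed relative
  ranges are kept). The T2DM TFPI cell (197.56 pg/mL, three orders of
  magnitude below the 70 ng/mL reference) is kept as printed.

Cohorts are drawn by Latin hypercube sampling (`lhs::randomLHS`): per
parameter, exactly one sample per equal-probability stratum, mapped
through each marginal's quantile function; reproducible under a fixed
seed that is recorded in every output.

## Sensitivity analysis and calibration

`runSensitivity()` runs an LHS design over a disease spec plus a dummy
parameter (uniform, disconnected from the model) and computes partial
rank correlation coefficients per TG metric: rank-transform all columns
(average ranks on ties), residualise each parameter and the response
against all other ranked parameters by linear regression, and correlate
the residuals. The dummy's PRCC estimates the null scale; constant
columns (point-mass parameters) are reported as NA with a warning rather
than silently dropped. `calibrateCohort()` then narrows the ranges of the
top-ranked factors by bisection in the direction indicated by the PRCC
sign until a target fraction of resampled patients falls inside
user-supplied TG-metric windows — the windows themselves are user input,
since the experimental TG values they would come from are not printed in
the source literature.

## Numerical choices

* lsoda (automatic stiff/non-stiff switching BDF/Adams) with rtol 1e−8,
  atol 1e−12 M; refining tolerances 10× moves reported concentrations by
  < 0.1% (asserted in the tests).
* Reporting grids: 1 s for coagulation phases, 60 s for inflammation
  phases.
* Conservation groups (total TF, prothrombin-derived mass, total ATIII,
  total TFPI) are checked symbolically at model construction
  (\(w^T S = 0\)) and numerically after every scenario (< 1e−6 relative
  drift required).
* Induced TF accumulates by an exact exponential propagator per reporting
  interval with trapezoidal averaging of the induction rate; suppression
  scales evaluate at the trapezoidal time-average of cytokine excess.
* TG metrics: peak = curve maximum; time-to-peak = earliest argmax; ETP =
  trapezoidal integral over the simulated horizon (no extrapolation to
  infinity); lag = earliest interpolated crossing of 10% of peak (an
  absolute 2 nM rule is selectable; the operational definition is not
  standardised in the source literature, so both conventions ship). An
  all-zero curve yields NA lag/TTP with a warning, not an error.
* The ATIII-IIa transition time is the interpolated 50%-of-final
  crossing, validated to be nondecreasing up to solver noise.

## What the synthetic-data generators emulate

`makeFixture()` produces analytic thrombin curves (triangle, logistic)
whose TG metrics are known in closed form, toy reaction networks with
exact solutions for engine verification, and monotone input–output
tables for PRCC checks. The virtual-patient generator emulates
between-patient variability in plasma factor and cytokine levels only:
it does not model intra-patient dynamics of disease progression,
measurement noise in TG assays, platelet/fibrin mechanics, or the
protein C pathway (absent from the cascade model). Passing cohort tests
therefore demonstrates that the coupled model transduces documented
concentration ranges into the documented qualitative TG shifts — not
that it predicts any individual patient's assay.

## Scaled problem sizes

The reference analyses use 2,000-patient cohorts and 5,000-sample
sensitivity designs. The shipped tests and the acceptance script run the
same pipelines at 200 samples — the package's chosen desk-scale default,
which keeps every documented qualitative contrast stable across seeds —
with the full sizes available behind the same arguments (`n = 2000`,
`n = 5000`).

## Known limitations

* Fibrin formation, fibrinolysis, platelet surfaces and the protein
  C/thrombomodulin pathway are out of scope (as in the underlying cascade
  model).
* The inflammatory module covers three cytokines; mediators such as
  IL-12 or IFN-γ are not represented.
* Cytokine baselines and all coupling magnitudes are configuration, not
  measurements; conclusions should be read as relative to baseline.
* One published inventory of this model family reports 38 reactions and
  44 species; its full listing is in supplementary material that is not
  available, so this package implements the documented cascade core plus
  the three-cytokine module and accepts any inventory through its generic
  network engine (species/reaction counts are never hard-coded).
* Monocyte and endothelial TF pools are merged into a single induced-TF
  pool; whether IL-6 suppresses ATIII through reduced production or
  enhanced clearance is not resolved — initial-concentration scaling is
  agnostic between the two.
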