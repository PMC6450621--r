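---
title: "Renal transporter pharmacokinetics: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renal transporter pharmacokinetics: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalpk)
library(dplyr)
```

## The scientific problem

Many drugs are cleared by the kidney through a combination of glomerular
filtration, carrier-mediated tubular secretion and carrier-mediated
reabsorption. When a disease state downregulates the transporters involved
— here, hyperuricemia suppressing the organic cation transporters Oct2
(basolateral uptake) and Mate1 (apical efflux), and the peptide
transporters Pept1/2 (reabsorption) — the plasma profile, urinary
excretion and kidney tissue accumulation of substrate drugs all shift, and
they shift in characteristically different ways depending on which step is
rate-limiting.

`renalpk` packages the quantitative workflow for such studies:

1. **Non-compartmental analysis (NCA)** of IV-bolus plasma, urine and
   terminal kidney-tissue data.
2. The **clearance-ratio statistic** `(CL_R / fu) / CL_inulin` that
   classifies net tubular secretion (ratio > 1) versus net reabsorption
   (ratio < 1).
3. **Relative mRNA quantification** by the delta-delta-Ct method.
4. **Uptake-assay reduction** (cell-to-medium ratio, percent of control).
5. Group statistics: mean ± SEM, pooled-variance t test, Monte-Carlo
   Dunnett many-to-one comparisons.
6. A **mechanistic simulator** of renal tubular transport that generates
   synthetic two-arm studies with known ground truth, so every analysis
   stage is testable without animal data.

## The mechanistic kidney model

Amounts are tracked per kg body weight in four compartments — central
plasma, tubular cell, tubular lumen, urine — with concentrations in µM
(nmol/mL). Three bookkeeping integrals (non-renal elimination, cumulative
synthesis, plasma-concentration integral) close the mass balance and give
exact reference AUCs.

Fluxes, for a drug with unbound fraction $f_u$:

* **Filtration** $f_u \cdot \mathrm{GFR} \cdot C_p$ from systemic plasma
  into the lumen. The glomerulus sits upstream of the peritubular
  capillaries, which is why a freely filtered marker (inulin) has renal
  clearance exactly equal to GFR — the model reproduces this identity
  exactly, and we use it as a regression test.
* **Secretion** via a basolateral Michaelis–Menten uptake carrier
  (Oct2/Oat1-like) plus passive exchange, drawing on the *post-glomerular*
  plasma flow $Q' = Q - \mathrm{GFR}$ and, with restrictive protein
  binding, only on the unbound drug it carries. The local unbound
  concentration $u$ at the exchange site is solved algebraically at every
  integration step from the flow balance
  $$Q'(f_u C_p - u) = \theta_{up} \frac{V_{max,up}\, u}{K_{m,up} + u}
    + PS\, u - PS\, C_{cell},$$
  a quadratic in $u$ with a single positive root (solved in stable closed
  form; a property test cross-checks it against bisection). This caps
  secretory extraction at $Q' f_u C_p$ and hence total renal clearance at
  $f_u \mathrm{GFR} + f_u Q' = f_u Q$ for *any* carrier capacity — the
  flow-limited regime in which a drug like metformin operates.
* **Apical efflux** (Mate1-like) from cell to lumen,
  $\theta_{eff} V_{max,eff} C_{cell} / (K_{m,eff} + C_{cell})$. When this
  carrier runs near saturation, a modest loss of expression
  ($\theta_{eff} < 1$) forces a disproportionate rise in intracellular
  concentration — and hence in the kidney-to-plasma partition coefficient
  $K_p$ — while the excreted flux, and with it plasma clearance, barely
  moves. This is the signature of apical-efflux loss under flow-limited
  uptake.
* **Reabsorption** (Pept-like) from lumen back to the central compartment,
  saturable with $K_{m,reab}$. Because luminal concentrations scale with
  dose, reabsorption saturates at high dose: the clearance ratio then
  rises above 1 (net secretion), while at low dose reabsorption dominates
  and the ratio falls below 1.
* **Lumen-to-urine washout** first order at `urine_flow_k` (default
  0.05/min over a 2 mL/kg luminal volume, i.e. a 0.1 mL/min/kg urine
  flow).

Endogenous analytes (creatinine) carry a zero-order synthesis rate and no
dose; their initial state is the model steady state, found by
pre-equilibrating the synthesis-driven system with a stiff integrator to
30,000 min. A test asserts the sampled plasma concentration is then
time-invariant to 0.1% over the 240-min study window.

Integration uses `deSolve` (BDF/`vode`, rtol 1e-8, atol 1e-10); these
tight tolerances let the suite assert mass balance to a relative 1e-6
(observed defects are ~1e-12).

### Why the flow balance looks the way it does

An alternative — placing filtration *inside* the peritubular flow balance
and working in total concentrations — makes filtration itself flow-limited
and drops the inulin ratio to $Q/(Q + f_u \mathrm{GFR}) \approx 0.83$,
contradicting the defining property of a GFR marker; it also caps
clearance at $Q$ rather than $f_u Q$. The filtration-fraction structure
used here (filtration upstream at $C_p$, secretion on post-glomerular
unbound delivery) preserves both identities: the filtration-only limit is
exactly $f_u \mathrm{GFR}$, and the hard cap is exactly $f_u Q$. In the
linear carrier regime the secretory component follows the well-stirred
form $f_u Q'\, CL_{int} / (Q' + CL_{int})$, which the tests verify against
an independently coded closed form over a range of intrinsic clearances.

## Default study conditions

The simulator's defaults encode the study they emulate: IV bolus at t = 0;
plasma samples at 5, 15, 30, 60, 120, 180, 240 min; urine cumulated over
0–240 min in four intervals (the source study does not state its
collection boundaries, so these are a package choice); terminal kidney
tissue at 240 min; 3 animals per arm by default (raise `n_per_group` for
statistical property checks); GFR 6.72 mL/min/kg (control-arm inulin
clearance) against a renal plasma flow of 23 mL/min/kg; between-subject
lognormal CV 0.2 on carrier capacities and non-renal clearance (volumes
and flows fixed, which keeps the flow cap interpretable), residual assay
CV 0.1.

The three drug presets realize the three renal-handling regimes with
literature unbound fractions (metformin 0.85, cephalexin 0.82, creatinine
1.0) and carrier parameters chosen so that each regime's defining
mechanism is active:

* `drug_metformin()` — uptake intrinsic clearance 150 mL/min/kg
  ($\gg Q'$): flow-limited secretion, renal clearance just under the
  $f_u Q$ = 19.6 mL/min/kg cap; efflux near saturation so that
  $\theta_{eff} = 0.6$ roughly doubles-to-triples $K_p$ while CL$_R$ moves
  by only a few percent.
* `drug_cephalexin()` — moderate secretion plus a reabsorption carrier
  (Vmax 190 nmol/min/kg, Km 200 µM) sized so the clearance ratio sits
  near 0.33 at 1 mg/kg and near 1.3 at 10 mg/kg: the dose-dependent
  crossing of 1.
* `drug_creatinine()` — synthesis 140 nmol/min/kg giving a steady-state
  plasma concentration of ~12.8 µM and a clearance ratio of ~1.6 (net
  secretion), drifting down, not below 1, under transporter loss.

Kidney tissue concentration is reported per mL of tissue
(`a_cell / v_kidney`), i.e. per g wet weight at unit density; assay
dilution factors are regarded as handled upstream of the tidy inputs.

The hyperuricemic arm's default transporter profile is
`transporter_profile(uptake = 0.7, efflux = 0.607, reab = 0.8)`: the
efflux factor is the measured Mate1 protein reduction (60.7% of control);
uptake and reabsorption factors are round values consistent with the
measured mRNA declines of Oct2/Oat1 and Pept1.

Per-subject RNG substreams derive from the master seed by a fixed counter
(`seed + 1000003 * subject_index mod 2^31 - 1`), so the same seed
reproduces a study byte for byte and enlarging a cohort never reshuffles
existing subjects.

### What the generator does and does not emulate

It emulates: two-arm designs with lognormal between-subject and residual
variability, flow-limited secretion, saturable efflux and reabsorption,
endogenous steady state, interval urine collection, terminal tissue
sampling, Ct tables with a stable reference gene, and
expressing-versus-mock uptake assays. It does not emulate: assay
quantification limits or censoring, body-weight variation, time-varying
GFR or urine flow, transporter induction dynamics, plasma-protein-binding
kinetics beyond a constant $f_u$, or uric-acid disposition itself. Tests
passing on synthetic data therefore validate the *arithmetic and the
mechanistic logic* of the pipeline, not the biological fidelity of any
particular parameter value.

## Non-compartmental analysis choices

* **Linear trapezoid** (not log-down), as the plain reading of "the
  trapezoidal rule"; window bounds interpolate linearly between samples.
* **t = 0 anchoring**: after an IV bolus no concentration is measurable at
  t = 0. The default carries the first observed concentration back to the
  window start — it avoids inventing a distribution model, and the 0–240
  min AUC is dominated by observed points. A log-linear back-extrapolation
  of C(0) from the first two samples is available
  (`anchor = "log_backextrapolate"`), and `anchor = "none"` makes the
  window strict.
* **Terminal slope**: log-linear OLS over candidate windows (last 3, 4, …
  post-peak points), selecting the highest adjusted R², ties to fewer
  points. Flat or rising profiles raise a no-valid-fit condition; for
  endogenous steady-state analytes the extrapolated quantities are
  reported as `NA`, mirroring the "NC" entries of a PK table.
* **Group statistics** are computed per animal and then averaged
  (mean-of-ratios). Published tables built the same way agree with
  ratio-of-means recomputation only to a few percent; the dose/AUC
  consistency check therefore carries a 3% tolerance.
* **Classification band**: the secretion/reabsorption call uses a band of
  ±0.05 around ratio 1 by default (`epsilon = 0` restores the strict
  rule), since on noisy group means a hair above 1 is not evidence of
  secretion.
* Molecular weights are configuration, not constants: the metformin value
  depends on whether the free base (129.16) or the hydrochloride (165.62)
  is dosed, and this choice moves dose-based quantities by ~28%.

## Expression and uptake modules

Delta-delta-Ct uses the control-group *mean* ΔCt as baseline and a fixed
amplification efficiency of 2; technical replicates average on the Ct
scale first. Two invariances pin the arithmetic down: adding a constant to
every Ct of a sample leaves its relative expression unchanged, and the
reference gene itself always recovers expression 1. The generated Ct
tables are constructed so the estimator's group-mean ratio is consistent
for the configured fold changes (a Monte-Carlo test checks 0.6 recovers to
within 5% at n = 200).

Percent-of-control subtracts the *treatment-matched* mock-cell mean from
the expressing-cell mean before normalizing to the untreated control —
the conservative reading when background binding could vary by treatment —
and is invariant to any shared additive background and any common
rescaling. Dunnett many-to-one comparisons attach familywise-adjusted
p-values; the adjustment evaluates the null max-|t| distribution by seeded
Monte Carlo (1e5 draws; standard error of a p near 0.05 is ~0.0007), is
verified against the exact multivariate-t computation, and reduces to the
pooled t test at k = 1.

## Numerical and degenerate-input policy

Validation errors are classed conditions (`renalpk_validation_error`,
`renalpk_no_valid_fit`, `renalpk_coverage_error`, …) with addressed
messages (file/row/column for CSV input, missing spans for urine
coverage). Zero-variance groups with equal means give p = 1 with a
warning; with unequal means they raise an error. A numerically flat
terminal profile (|slope| < 1e-12) is treated as no decline. Tiny negative
integrator excursions are clamped to zero for flux evaluation only; any
state more negative than 1e-6 of the system scale aborts integration with
the parameter regime named.

## Problem sizes used in the checks

The test suite and the acceptance script run: a 21-point parameter grid
(3 drugs × 7 transporter profiles) for conservation and flow-cap checks;
30 animals per arm at 10% residual CV for parameter recovery; 50 animals
per arm for the efflux-loss pattern; n = 200 per group for the qPCR
consistency check; 100 replicates for the uptake emulation; 10,000 null
replicates against a 2e5-draw critical value for familywise error. These
sizes give Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

* The model is a single well-mixed nephron: no axial tubule geometry, no
  nephron heterogeneity, no medullary concentration gradient.
* One uptake, one efflux and one reabsorption carrier per drug; real
  disposition (e.g. cephalexin via Oat1 *and* Oat3) lumps into aggregate
  Vmax/Km.
* Unbound fraction is constant; no binding kinetics or
  concentration-dependent binding.
* The simulator's parameter values are regime-realizing choices, not
  fitted estimates; recovering a published mean beyond its qualitative
  pattern is out of scope.
* Dunnett adjustment is Monte-Carlo, so adjusted p-values carry ~1e-3
  noise; for regulatory-grade reporting use the exact multivariate-t
  computation it is tested against.
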