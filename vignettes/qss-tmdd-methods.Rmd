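---
title: "Population modelling of antibody-ligand binding with the QSS TMDD approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population modelling of antibody-ligand binding with the QSS TMDD approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsstmdd)
```

## The scientific problem

Therapeutic monoclonal antibodies that bind a circulating ligand with
high affinity do not follow linear kinetics: a meaningful fraction of
the drug is removed through binding to its target and subsequent
elimination of the drug-ligand complex, and the ligand itself is
depleted by the same interaction. This package implements a population
analysis of that situation for an anti-VEGF IgG1 antibody
(bevacizumab) binding the soluble VEGF165 isoform in serum: a
two-compartment disposition model for the antibody coupled to turnover
of the ligand, with the binding handled by the quasi-steady-state
(QSS) approximation of target-mediated drug disposition (TMDD).

Measurements come in the form routine oncology sampling produces:
sparse paired pre-/post-infusion serum samples of *total* antibody
(free plus monomeric complex, mg/L) and *free* ligand (ng/L),
collected over repeated dosing cycles, together with body weight, age,
sex and three VEGF-A promoter genotypes per patient.

## Structural model

State variables are total drug `Ctot` (nM, central), total ligand
`Rtot` (nM) and the free-drug amount in a peripheral compartment `A2`
(nmol). Free drug `C` follows algebraically from the QSS assumption as
the nonnegative root of

\[ C^2 + (R_\mathrm{tot} + K_\mathrm{ss} - C_\mathrm{tot})\,C -
   K_\mathrm{ss} C_\mathrm{tot} = 0, \]

with complex `RC = Rtot * C / (Kss + C)` and free ligand
`R = Rtot - RC`. The differential system couples a standard
two-compartment model (parameters `CL`, `V1`, `Q`, `V2`) with
zero-order ligand production `kin`, first-order ligand elimination
`kout`, and elimination of the complex with clearance `CL_RC`. Baseline
stationarity ties production to the pre-treatment ligand level:
`kin = BM0 * kout`. The binding micro-constants are collapsed into the
single steady-state constant `Kss = (kint + koff)/kon`, the in vivo
analogue of (and typically much larger than) the in vitro dissociation
constant. The sparse two-analyte design cannot separate the complex
clearance from the free-drug clearance, so `CL_RC = CL` is imposed
throughout, the same identifiability constraint the study design
forces.

Internally every concentration is molar (nM); the mass units of the
assays (mg/L, ng/L) appear only at the I/O boundary. The adopted molar
masses are 149 kDa for the antibody and 40 kDa for the ligand; the
latter is back-calculated from the reported equivalence of 212 ng/L
and 0.0053 nM rather than taken from sequence-based masses, so that
unit conversions reproduce the published arithmetic exactly.

## Parameters, units and defaults

| Parameter | Unit | Typical value | Meaning |
|-----------|------|--------------|---------|
| `CL`      | L/day | 0.18 | linear clearance of free drug |
| `V1`, `V2`| L     | 3.23, 3.1 | central and peripheral volumes |
| `Q`       | L/day | 1.38 | inter-compartmental clearance |
| `BM0`     | nM (reported ng/L) | 0.0053 (212) | baseline free ligand |
| `kout`    | /day  | 0.401 | ligand turnover rate |
| `Kss`     | nM    | 267  | QSS binding constant |

Body weight enters all clearances and volumes allometrically
(exponents 0.75 and 1, reference 70 kg, fixed rather than estimated).
Inter-individual variability is log-normal
(`P_i = P_pop * exp(eta_i)`) with diagonal variances; the final model
carries it on `CL`, `V1` and `BM0` (20 %, 22 %, 33 % CV). Residual
error is additive on the log scale per analyte (28 % and 32 %) for the
binding model, proportional (24 %) for the drug-only step. CV% for a
variance `omega2` is reported as `100*omega` below 30 % (the
convention of published parameter tables) with the exact log-normal
form available via `iiv_cv_percent(exact = TRUE)`.

## Estimation

The marginal likelihood of each subject is approximated by the Laplace
method: the joint \(-2\log\)-likelihood of observations and random
effects is minimized over `eta` by a damped Gauss-Newton iteration
whose Fisher-scoring Hessian also supplies the log-determinant
correction. The "interaction" convention is used: residual variances
are evaluated at the individual (not population) prediction, which
matters for proportional error. For any model linear in `eta` with
constant residual variance the approximation is exact; the test suite
verifies equality with the closed-form linear-mixed-model marginal
likelihood to `1e-6` relative.

The outer problem minimizes the objective function value (OFV, with
the \(2\pi\) constants included) over log-transformed typical values,
variances and residual magnitudes with a quasi-Newton optimizer. Two
numerical choices deserve note:

* the outer gradient is computed by central differences with step
  `1e-3` on the log scale. The objective carries a noise floor of
  about `1e-5` from the adaptive ODE solver and the inner
  optimization, so the much smaller default steps of a generic
  optimizer produce noise-dominated gradients and false convergence;
* log-variances are box-constrained to \(\pm 16\) so a collapsing
  variance component degrades gracefully to "no IIV" instead of
  producing degenerate arithmetic.

Estimation itself uses no random numbers; all stochasticity lives in
the synthetic-data generator and the simulation-based diagnostics,
always behind an explicit seed.

The ODE system is integrated by a compiled adaptive Dormand-Prince
RK45 scheme (relative tolerance `1e-8`, absolute `1e-10` nM) with the
integration restarted at every infusion start and stop; after the QSS
substitution the system is non-stiff on the dosing time scale, and the
integrator agrees with an independent stiff solver to six significant
digits in the tests. The QSS root is evaluated in a
cancellation-safe form because total drug exceeds total ligand by
roughly five orders of magnitude in this system. The covariance step
uses central finite differences of the OFV with step `1e-2` — large
enough that curvature of weakly identified variance components clears
the solver noise floor — and maps standard errors to the natural scale
by the delta method.

## Covariate machinery

Continuous covariates can enter linearly (centred at the population
median) or as a power function; categorical covariates enter through
indicator terms, with genotypes coded as two contrasts against the
wild type (a 2-df candidate by default). Stepwise covariate model
building adds, greedily, the candidate with the largest significant
OFV drop (threshold 3.84 for 1 df at p < 0.05) and then deletes
backwards at the stricter 6.64 (p < 0.01). The permutation-based
calibration (`randomization_test`) refits the full model on datasets
in which the covariate's subject-level values are shuffled between
individuals, and reports the empirical OFV drop required for 5 %
significance — typically larger in small cohorts than the nominal
3.84, which is exactly the inflation the procedure exists to measure.

## Synthetic cohorts

No patient-level data accompany the published analysis, so the
generator is a first-class module that emulates the study design: 19
subjects; weight median 70 kg (range 50-94) and age median 60 y
(37-73) drawn from range-rescaled Beta distributions matched to those
medians (the published summary gives only median and range, so the
distributional family is a modelling choice); 58 % male; genotype
frequencies as tabulated for the three promoter SNPs, sampled
independently per SNP because haplotype structure is unpublished; ten
subjects on 5 mg/kg every 2 weeks (one of whom receives 10 mg/kg) and
nine on 7.5 mg/kg every 3 weeks; infusions of 90 min (first dose),
60 min (second) and 30 min thereafter; paired pre-/post-infusion
samples on the scheduled cycles of each arm plus a pre-dose cycle-1
ligand-only sample; and per-arm treatment durations matched to the
reported medians and ranges, which truncate each subject's attended
cycles.

What the generator deliberately does not emulate: assay censoring
(none of the study's measurements fell below quantification limits, so
no censoring model exists to copy), haplotype linkage between SNPs,
co-medication effects, and any real between-patient correlation of
covariates. Passing recovery tests on these cohorts therefore
demonstrates that the estimation machinery inverts the generative
model under the study's design — not that the published estimates are
correct for the real patients.

### The recovery design

Parameter-recovery experiments use `recovery_skeleton()`: 30 subjects,
5 mg/kg every 2 weeks for six doses, eight paired-analyte occasions
(ends of the first two infusions, days 2 and 7 of the ligand
transient, the first trough, and three occasions out to day 84) plus
the baseline ligand sample. The occasion placement was chosen by a
Fisher-information analysis at the generating values: sampling
windows confined to the first two dosing intervals leave the
clearance on a ridge with `V2` (the terminal half-life is about 26
days, longer than such a window) and were rejected. Under the adopted
design the expected uncertainties are roughly 6 % (`CL`), 8 % (`BM0`),
10 % (`Kss`) and 14 % (`kout`). The ligand turnover rate is the least
identifiable quantity in every design variant examined — free drug
saturates the ligand throughout dosing, so `R` reflects `kout` only
weakly — and 14 % matches what the original sparse clinical design
achieved; occasional recovery runs will therefore miss `kout` by more
than 15 % even though the estimator is unbiased.

## Diagnostics

`pcvpc()` implements the prediction-corrected visual predictive
check: observations and simulated replicates are scaled by the ratio
of the bin-median population prediction to each point's own population
prediction (no censoring terms are needed here), and observed
10th/50th/90th percentiles are compared with 95 % bands from 1000
simulated datasets by default. Binning uses nominal sample times when
the design has few distinct times and time-quantile bins otherwise;
both time-since-first-dose and time-after-dose axes are supported
because published VPCs of this kind do not always state which was
used. `gof_residuals()` returns population and individual predictions
with IWRES and population weighted residuals; `typical_profiles()`
reproduces the typical-patient simulations (70 kg, zero random
effects, ten cycles by default — the published figures do not state
their horizon) from which the first-dose ligand-suppression figures of
73 % (5 mg/kg) and 80 % (7.5 mg/kg) derive. The steady-state decline
in free ligand is deliberately exposed only as a generic
`suppression_at()` query because its published definition (evaluation
time and reference) is ambiguous.

## Workflow

The two-step analysis mirrors the published procedure: `run_step1()`
fits the two-compartment model with proportional error to the
total-drug data alone; `run_step2()` then fits both analytes
simultaneously with the QSS TMDD model, additive-log errors, IIV on
`CL`, `V1` and `BM0`, and the step-1 estimates as initial values.
`run_all()` bundles the steps with optional covariate search,
randomization test, predictive check and typical profiles, writing
every artifact and an MD5 manifest under one output directory; a rerun
with the same configuration reproduces the manifest bit-for-bit.

## Problem sizes used in the tests

The shipped test suite scales simulations to what a laptop-class
single core handles comfortably: recovery experiments use the
30-subject rich design above; workflow and diagnostic tests use 6-12
subject cohorts, down-scaled permutation counts (30-60) and predictive
checks of 60-400 replicates. The pcVPC's published configuration
(1000 replicates) remains the package default.

## Known limitations

* The estimation objective is a Laplace approximation, not the exact
  FOCE-I implementation of commercial tools; objective values are not
  comparable across implementations (differences cancel in OFV
  deltas), and acceptance is judged on parameter recovery.
* Only the QSS approximation is provided — no full TMDD system, no
  quasi-equilibrium or Michaelis-Menten variants, and no multimeric
  complexes or platelet ligand uptake, which the underlying assay
  cannot see either.
* `Omega` is diagonal; no inter-occasion variability; no
  below-quantification handling.
* The inner Gauss-Newton Hessian is a Fisher approximation: exact for
  constant-variance models linear in the random effects, approximate
  under proportional error with interaction.
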