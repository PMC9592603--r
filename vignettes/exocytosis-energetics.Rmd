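---
title: "Surface-energy modelling of nanoparticle exocytosis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-energy modelling of nanoparticle exocytosis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoexo)
```

## The model

Vesicle-mediated exocytosis of a coated nanoparticle (NP) involves two
colloidal encounters: the NP against its transport vesicle, and the loaded
vesicle against the inner face of the plasma membrane.  nanoexo treats both
with extended-DLVO (XDLVO) theory: the interaction energy is the sum of a
Lifshitz–van der Waals (LW), an electrostatic double-layer (EL) and a Lewis
acid–base (AB) term, each built from van Oss–Chaudhury–Good surface
free-energy components $\gamma^{LW}, \gamma^+, \gamma^-$ of the three phases
(NP coating, cell/vesicle surface, aqueous medium).

Two scalars are extracted from the distance-resolved profiles:

* $\Delta G_{np/v}$ — the NP–vesicle interaction energy, taken as the
  maximum of the sphere–sphere profile (the contact value when the profile
  decays monotonically);
* $\Delta G^\ddagger_{v/m}$ — the barrier height of the sphere–plate
  vesicle–membrane profile, floored at zero when the profile is purely
  attractive (an activation energy cannot be negative).

Their difference, $\Delta G(d) = \Delta G^\ddagger_{v/m} - \Delta G_{np/v}$,
is the exocytosis energy change: the barrier the vesicle must climb, less
the repulsive NP–vesicle energy released when the particle detaches.  Per
cell line, measured exocytosis rate constants follow an Arrhenius-type
regression

$$\ln k_{exo} = \beta\,\Delta G(d) + \ln A,$$

with $\beta$ (mol/kJ) and the frequency factor $A$ (/s) fitted by ordinary
least squares on the $\ln$ scale.  $\beta$ is deliberately a free empirical
parameter: the naive Boltzmann slope $-1/RT = -0.388$ mol/kJ at 310 K is two
orders of magnitude steeper than fitted cell-line slopes (order
$-10^{-3}$ mol/kJ), because the generic surface description absorbs
unmodelled ligand–receptor binding, membrane deformation and cell-specific
vesicle traffic.  The Boltzmann machinery is still exposed where it is
meaningful: `vesicle_fraction()` gives the equilibrium fraction of
vesicle-bound particles $e^{-\Delta G_{np/v}/RT}$, and
`decompose_frequency()` splits the fitted $A$ into
$A_{vesicle} \cdot [NP]_{vesicle}/[NP]_{total}$ — on the log scale as well,
since the fraction underflows for realistic repulsive energies of hundreds
of kJ/mol.

## Combining rules and distance laws

At contact separation $d_0$ the per-area free energies follow the van Oss
combining rules (`contact_lw()`, `contact_ab()`):

$$\Delta G^{LW}(d_0) = 2(\sqrt{\gamma_3^{LW}} - \sqrt{\gamma_1^{LW}})
  (\sqrt{\gamma_2^{LW}} - \sqrt{\gamma_3^{LW}})$$

$$\Delta G^{AB}(d_0) = 2\big[\sqrt{\gamma_3^+}(\sqrt{\gamma_1^-} +
  \sqrt{\gamma_2^-} - \sqrt{\gamma_3^-}) + \sqrt{\gamma_3^-}
  (\sqrt{\gamma_1^+} + \sqrt{\gamma_2^+} - \sqrt{\gamma_3^+}) -
  \sqrt{\gamma_1^+\gamma_2^-} - \sqrt{\gamma_1^-\gamma_2^+}\big]$$

with subscript 3 the medium.  Distance dependence enters through the
standard Derjaguin-approximation forms, all proportional to the effective
radius $R_{eff}$ ($r_1 r_2/(r_1+r_2)$ for two spheres, $r_1$ for
sphere–plate):

| term | law | decay |
|------|-----|-------|
| LW | $2\pi R_{eff} d_0^2\, \Delta G^{LW}(d_0)/d$ | algebraic $1/d$ |
| AB | $2\pi R_{eff} \lambda\, \Delta G^{AB}(d_0)\, e^{(d_0-d)/\lambda}$ | exponential, $\lambda$ |
| EL | $\pi \varepsilon_0 \varepsilon_r R_{eff} [2\psi_1\psi_2 \ln\frac{1+e^{-\kappa d}}{1-e^{-\kappa d}} + (\psi_1^2+\psi_2^2)\ln(1-e^{-2\kappa d})]$ | screened, $1/\kappa$ |

The EL term is the constant-potential Hogg–Healy–Fuerstenau expression;
constant-charge or charge-regulated boundary conditions are not implemented.
Per-particle energies (J) are multiplied by Avogadro's number and reported
in kJ/mol, matching the units of the packaged energy table.

## Parameters that matter

| parameter | default | unit | rationale |
|-----------|---------|------|-----------|
| $d_0$ | 0.157 | nm | conventional minimum equilibrium contact distance of the van Oss framework |
| $\lambda$ | 0.6 | nm | AB correlation length of water at ambient–physiological conditions |
| $1/\kappa$ (Debye length) | 0.78 | nm | 0.154 M 1:1 electrolyte at 310 K |
| $\varepsilon_r$ | 74 | — | water at 310 K |
| $T$ | 310 | K | physiological temperature; $RT = 2.577$ kJ/mol |
| water $\gamma^{LW}$; $\gamma^+=\gamma^-$ | 21.8; 25.5 | mJ/m² | standard van Oss reference scale |
| generic cell $\gamma^{LW}, \gamma^+, \gamma^-$; $\psi_0$ | 39, 2.6, 71; −40 | mJ/m²; mV | generic membrane descriptors used for every cell line (so computed energies depend only on the NP and its size) |
| grid | $[d_0, 25]$ nm, 2000 points | — | see numerical choices |

All of these are configurable through `medium_spec()`,
`xdlvo_parameters()` and the YAML config consumed by `read_cell_config()`;
the packaged `generic_cell_config.yaml` documents the schema.

Two modelling conventions are fixed by assumption rather than data.
Vesicles share the membrane's surface chemistry (they fuse with it), and a
vesicle tightly wraps a single NP, so the default vesicle radius equals the
NP radius (an additive membrane offset is available through the vesicle
rule).  The NP–vesicle encounter is treated as an external sphere–sphere
approach — consistent with reading the profile maximum as "the" interaction
energy — not as a sphere inside a shell.

## Rate constants from time series

Measured exocytosis curves report the normalised intracellular amount
$a(t) = [NP]_t/[NP]_0$.  Two curve models are provided:

* `fit_plateau_decay()` — $a(t) = (a_0 - a_{eq})e^{-kt} + a_{eq}$, for
  experiments that approach a non-zero equilibrium amount.  The literal
  plateau formula with an additive $[NP]_{eq}$ does not evaluate to 1 at
  $t = 0$; this parameterisation does, and reduces to the same law.  $a_0$
  is fixed at the first observation rather than fitted — the initial amount
  is the normalisation reference, not a free parameter.
* `fit_first_order()` — $a(t) = a_0 e^{-kt}$ ($a_{eq} = 0$), equivalent to
  a log-linear regression through the origin when all amounts are positive.
* `two_point_rate()` — $k = \ln(a_i/a_f)/\Delta t$, for datasets reporting
  only initial and final amounts.  On a two-point series this equals the
  first-order fit exactly.

The nonlinear fit runs in per-hour units internally (a per-second $k$
against times of order $10^5$ s makes the Jacobian badly scaled) and
reports /s.  Bounds are $k \in (0, 1]$ /s and $a_{eq} \in [0,1]$; starting
values come from a log-linear fit of the plateau-subtracted amounts.  A
series whose relative range is below $10^{-6}$ is rejected as an
unidentifiable rate rather than fitted.

## Intervals

`predict_k_exo()` reports the standard OLS mean-response (confidence)
interval, computed on the $\ln$ scale with $t$ quantiles on $n-2$ df and
exponentiated:

$$\widehat{\ln k} \pm t_{1-\alpha/2,\,n-2}\; s\,
\sqrt{\tfrac 1n + \tfrac{(\Delta G - \overline{\Delta G})^2}{SS_{\Delta G}}}.$$

The width therefore grows with the distance from the training mean, and
predictions outside the training $\Delta G$ range carry an explicit
extrapolation flag.  Published interval bars around regressions of this
kind are sometimes prediction intervals instead; since that choice is
ambiguous, a prediction-interval variant (adding the residual variance
under the root) is available via `interval = "prediction"`.  Slope p-values
are two-sided with no multiple-testing correction — models are fitted and
reported per cell line.  Degenerate but historically fitted designs (e.g. a
cell line mixing hydrodynamic- and TEM-sized particles) are fitted anyway;
the dataset validator raises the mixing flag so the user can decide.

## Numerical choices

* Grid: 2000 uniform points on $[d_0, d_{max}]$.  $d_{max}$ defaults to
  25 nm, chosen so that the slowest-decaying term — the $1/d$ LW tail of
  the largest supported particles ($R_{eff} = 50$ nm) — is below 1 kJ/mol
  at the grid edge; doubling the grid changes barrier heights by well under
  0.1 %.
* Ties at equal profile maxima resolve to the smallest separation,
  deterministically.
* A vesicle–membrane profile that never exceeds zero yields barrier 0 with
  a `no_barrier` flag rather than a negative activation term.
* Surface potentials are accepted in mV and converted to V inside the EL
  term; all $\gamma$ stay in mJ/m² at the interface and are converted to
  SI internally.
* Zeta-to-surface-potential conversion is the identity: $\psi_0$ columns
  are taken as given.  Slipping-plane corrections belong upstream of the
  property table.

## Synthetic data: what it emulates and what it does not

`synthetic_spec()` and its generators exist so that every stage — energies,
curve fits, regression, intervals — is testable end-to-end with known
ground truth.  Default property ranges mimic the materials the model
targets: $\gamma^{LW}$ 20–45, $\gamma^+$ 0–6, $\gamma^-$ 10–75 mJ/m²,
diameters 8–100 nm, neutral coatings.  Rate constants are generated from
the Arrhenius law itself with Gaussian noise on $\ln k$ (the error
structure of the measured rates is unknown; log-normal is the natural
choice for a positive rate), and curves get additive Gaussian noise on the
normalised amounts (default SD 0.02), floored at zero.

Because the generative law is the fitted law, synthetic tests demonstrate
*recovery* — correct implementation of the estimators, their intervals and
their coverage — not external validity.  They cannot reveal model
misspecification in real data: aggregation, protein corona formation,
lysosomal surface modification of charged coatings, or cell lines whose
surfaces deviate from the generic descriptors all fall outside the
generator (and outside the model).

The measured per-particle rate tables behind the published cell-line
regressions are supplementary material not redistributed here.
`synthetic_kexo_standin()` therefore generates labelled synthetic
stand-ins: it pairs each cell line's $\Delta G(d)$ values from the packaged
energy table with rates drawn from the reference slope and intercept for
that cell line, with the ln-scale noise SD set to
$|\beta|\,\mathrm{sd}(\Delta G)\sqrt{1/R^2 - 1}$ so the expected $R^2$
matches the reference value.  Reference coefficients reported for the six
cell lines are used as-is ($\beta$ from $-0.0010$ to $-0.0024$ mol/kJ for
STO, U937, Hela and SNB19; $\ln A$ $-7.3$ for Hela, $-12.8$ for C166,
$\ln(6.3\times10^{-6})$ for U937; $R^2$ 0.06–0.98).  Where a coefficient
was never reported numerically, this package fixes a value once as part of
the stand-in configuration: $\beta_{C166} = +0.0010$ (only the positive
sign and $R^2 = 0.61$ are reported), $\beta_{RAW} = -0.0005$ with
$R^2 = 0.06$ (a deliberately near-flat, noise-dominated design),
$\ln A = -10.5$, $-10.0$ and $-11.0$ for STO, SNB19 and RAW 264.7 (inside
the reported $2.9\times10^{-6}$–$7.0\times10^{-4}$ /s range), and
$R^2_{U937} = 0.85$.  For the four-point Hela set the three smallest
transferrin sizes plus the D-penicillamine row form the training set.
Fitting a stand-in recovers its generating coefficients — a check of the
regression machinery and of the fixture's $\Delta G$ values, not a
re-derivation of the published fits.

## Problem sizes

The test suite and examples use deliberately small, fixed problem sizes
chosen as representative rather than exhaustive: panels of 6–25 synthetic
particles, 2000-point energy grids, 200 Monte-Carlo seeds for noisy curve
recovery, 500 replicates for estimator bias and 1000 replicates for
interval coverage.  All generators are seeded and bit-reproducible, and
restore the caller's RNG state.

## Known limitations

* The generic cell surface makes computed energies identical across cell
  lines; all cell-line specificity lives in the fitted $\beta$ and
  $\ln A$.
* Only neutral-coating physics is calibrated; charged particles bring
  lysosomal surface modification and aggregation that the energy model
  ignores.
* No retardation correction to LW, no charge regulation in EL, no
  membrane-deformation or ligand–receptor binding energies.
* Single-particle vesicles only: aggregated or multi-particle transport
  changes both the geometry and the effective surface chemistry.
* The packaged energy table stores size ranks, not absolute sizes, for the
  multi-size series whose diameters were never published in the main text.
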