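---
title: "Models and methods: surface-confined voltammetry, reduction thermodynamics, pKa titrations and ET kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfv)
```

`pfv` analyzes cyclic voltammetry of redox proteins adsorbed on
SAM-modified electrodes. This vignette records the models, the numerical
choices, and the reasoning behind the design decisions, in enough detail
that a maintainer can judge what each result does and does not show.

## The surface-confined voltammetry model

An adsorbed one-electron couple at total coverage $\Gamma_T$ (mol
cm$^{-2}$) has no mass transport; its state is the oxidized fraction
$x(t)$, governed by Butler–Volmer kinetics

$$\frac{dx}{dt} = k_{ox}(1-x) - k_{red}\,x, \qquad
k_{ox} = k_s e^{(1-\alpha) f (E - E^{\circ\prime})}, \quad
k_{red} = k_s e^{-\alpha f (E - E^{\circ\prime})},$$

with $f = F/RT$, the standard rate constant $k_s$ (s$^{-1}$) and
transfer coefficient $\alpha \in (0,1)$. The applied potential is a
triangular program at scan rate $\nu$; the faradaic current is
$i = nFA\Gamma_T\,dx/dt$ with the IUPAC sign convention (anodic
positive — the literature this package serves does not state a
convention, and only peak positions, charges and their differences
matter downstream). A rectangular capacitive current
$C_{dl} A\,dE/dt$ and additive i.i.d. Gaussian noise complete the
synthetic signal.

**Assumptions.** A single adsorbed population with one $E^{\circ\prime}$
and no lateral interactions (ideal Langmuir film), potential-independent
$\alpha$ and $C_{dl}$, no uncompensated resistance, no catalytic
turnover. Real films violate these in recognizable ways — peak widths
above 90.6 mV/n, asymmetric quasi-reversibility, sloping backgrounds —
so the processing functions make no ideality assumption beyond a
locally linear baseline.

### Integration: why an exponential update

The ODE is linear in $x$ with rate sum $b = k_{ox} + k_{red}$ that grows
like $k_s e^{\alpha f |E - E^{\circ\prime}|}$: in the reversible limit
the equation is arbitrarily stiff and explicit integrators need
$\Delta t \ll 1/b$. Instead, each sub-step freezes the rates at the
sub-step's midpoint potential and applies the *exact* solution of the
frozen equation,

$$x \leftarrow x_{ss} + (x - x_{ss})e^{-b\Delta t}, \qquad
x_{ss} = k_{ox}/b,$$

which is unconditionally stable and relaxes to the Nernst equilibrium
$x_{ss}$ — the physically correct reversible limit — when
$b\Delta t \to \infty$. Output is on a fixed potential grid
(`potential_step`, default 0.1 mV) with 4 internal sub-steps per output
step; the reported current is the discrete $nFA\Gamma_T\,\Delta
x/\Delta t$ over each output step, assigned to the step midpoint.
Evaluating the rate law at grid nodes instead would amplify the $O(h^2)$
state error by the factor $b$ in the stiff regime; the finite-difference
form is immune to that and conserves charge exactly by telescoping
(the test suite checks $\int i\,dt = nFA\Gamma_T$ to 0.1%). The initial
condition is the Nernst fraction at the start potential, which avoids a
relaxation transient at the first points. Peak positions move by less
than 0.2 mV when the step is halved.

Sweep windows that fail to bracket $E^{\circ\prime}$ by at least 150 mV
truncate the wave; the simulator raises a warning and records the flag
in the ground truth attached to every synthetic dataset.

## CV processing

Baselines are least-squares lines through the two flanking windows of a
sweep segment (each 10% of the segment by default, capped at 25%); a
peak falling inside a flank triggers a warning suggesting a smaller
flank fraction. Peaks are extrema of the baseline-corrected current; a
peak must exceed 3×MAD of the corrected flanks, otherwise a no-peak
error is raised rather than returning noise. Sub-grid refinement fits a
least-squares parabola over a window around the raw extremum (rather
than the minimal 3-point parabola, which under noise divides by a
near-zero curvature estimate and can throw the vertex far away). Peak
charges integrate the corrected current between its zero crossings,
falling back to a fixed ±150 mV window when a crossing is missing, and
divide by the scan rate; the *cathodic* charge is the coverage
estimator $\Gamma_0 = Q_c/(nFA)$ — the choice used in practice when the
anodic side sits on a less reliable background — while the anodic
charge is kept for the $Q_a/Q_c \approx 1$ diagnostic.

The voltammogram file dialect is deliberately minimal: UTF-8 CSV with
`# key: value` headers (`scan_rate_V_per_s` and `temperature_K`
mandatory, `temperature_C` accepted), a `potential_V,current_A` column
header, and point-decimal numbers only — comma decimals are rejected
with an explicit message rather than silently misparsed. Unknown header
keys round-trip verbatim, and simulation ground truth rides along in
`gt_*` keys. The SCE→SHE offset is fixed at +0.2412 V: in a
non-isothermal cell the reference electrode is thermostatted, so a
temperature-dependent offset would be wrong more often than right.

## Reduction thermodynamics

With the reference electrode held at constant temperature, the measured
$dE^{\circ\prime}/dT$ is the reaction-entropy slope:
$\Delta S^{\circ\prime}_{rc} = nF (dE^{\circ\prime}/dT)$, assumed
constant over the 5–45 °C working range. The enthalpy comes from the
Gibbs–Helmholtz form — regress $E^{\circ\prime}/T$ on $1/T$ and take
$\Delta H^{\circ\prime}_{rc} = -nF \times$ slope. Both are ordinary
least squares with propagated standard errors; a Wald–Wolfowitz runs
test on the residual signs warns when the linearity assumption is
visibly violated. For noiseless linear input the identities
$\Delta G = \Delta H - T\Delta S = -nFE^{\circ\prime}(T)$ hold to
machine precision at every grid point, and `thermo_summary()` reports
both routes to $\Delta G^{\circ\prime}_{rc}$ so disagreement is visible
rather than hidden. Kelvin is used everywhere internally; Celsius only
exists at file I/O under an explicit key.

**Compensation analysis.** Across conditions (SAM composition, pH),
enthalpy and entropy changes that track each other signal
reduction-induced solvent reorganization; conditions where something
else changed stand off the line. Flagging uses studentized residuals
with cutoff 2.5 — but a pair of gross outliers can *mask* each other in
a single OLS pass (each inflates the residual scale used to judge the
other; on a constructed 6-collinear + 2-displaced fixture a single pass
flags only one of the two). Candidates are therefore screened against a
resistant Theil–Sen line first, then refined by backward peeling (drop
the single worst point above the cutoff, refit, repeat). The reported
statistics are relative to the final clean-subset fit, externally
studentized for the excluded points, and the clean-subset refit is
reported alongside the all-points line, never silently substituted.

## The E°′(pH) titration model

Redox-linked protonation with up to three acid–base pairs gives

$$E^{\circ\prime}(\mathrm{pH}) = E^{\circ\prime}_{low\,pH} +
c \sum_{i} \log_{10}
\frac{K_{a,i}^{red} + [\mathrm{H^+}]}{K_{a,i}^{ox} + [\mathrm{H^+}]}.$$

**Ratio orientation.** The package deliberately places the
reduced-state constant in the numerator. With reduction-induced proton
uptake ($pK_a^{red} > pK_a^{ox}$, i.e. $K_a^{red} < K_a^{ox}$) each
term is then $\le 0$ and $E^{\circ\prime}$ *decreases* monotonically
with pH from the acid-limit plateau, by exactly
$c\sum_i (pK_{a,i}^{red} - pK_{a,i}^{ox})$ in total — the behaviour
observed in such titrations. The opposite orientation, with the same
constants, would predict an increasing profile. The analytic slope is
$-c\sum_i (f_i^{red} - f_i^{ox})$ with $f = [\mathrm{H^+}]/(K_a +
[\mathrm{H^+}])$ the protonated fraction, cross-checked against central
differences to $10^{-9}$ V/pH; the apparent proton uptake is
$-\mathrm{slope}/c$, bounded by the number of equilibria.

The Nernst coefficient defaults to the conventional rounded
0.059 V/decade; $2.303RT/F$ at the working temperature (0.0582 V at
293 K) can be set explicitly. The default is the value practitioners
quote with these models, and fitted pKa's shift by well under their
standard errors between the two.

**Fitting.** Bounded Levenberg–Marquardt (via `minpack.lm`) on
parameters $(E_0, pK_{a,i}^{ox}, \delta_i)$ with
$pK_a^{red} = pK_a^{ox} + e^{\delta}$, which enforces the pair ordering
smoothly; pKa box bounds [2, 13] (outside which a titration over
pH 4–12 carries no information); 50 multi-starts with $pK_a^{ox}$ drawn
uniformly in [3, 12] and sorted. Ties break to the lowest objective,
then the lowest first $pK_a^{ox}$, making the fit reproducible under a
seed. Points are weighted equally — per-point uncertainties are rarely
available for such titrations. Standard errors are Gauss–Newton
($\sigma^2 (J^TJ)^{-1}$ with a pseudoinverse when equilibria overlap
and $J^TJ$ is near-singular), with the delta method for $pK_a^{red}$;
an optional residual bootstrap gives honest SEs for the overlapping
pair — with generating pairs 8.4/10.9 and 8.9/11.3 the two reduced
constants are close to unidentifiable individually (their sum is what
the total span pins down), and the reported uncertainties say so
rather than suppressing it. Model size can be chosen by small-sample
AICc across 1–3 equilibria; overlap legitimately makes the 2-equilibria
model competitive with the generating 3-equilibria one, which is why
the selection reports all three fits.

## ET kinetics

**Working curve.** For a surface couple, $\Delta E_p$ depends on scan
rate only through $m^{-1} = (F/RT)\,\nu/k_s$. The curve mapping
$m^{-1} \mapsto \Delta E_p \cdot F/RT$ per $\alpha$ is generated by the
package's own simulator (noiseless, capacitance-free) on a 36-point
log grid over $m^{-1} \in [0.05, 300]$ and cached per session; its
large-$m^{-1}$ branches reproduce the irreversible closed form
$E_{pc} - E^{\circ\prime} = -(RT/\alpha F)\ln(\alpha m^{-1})$.
Regenerating it at half the simulation step moves inverted $k_s$ by
under 2%.

**Extraction.** The default route inverts the curve per trumpet row and
aggregates by geometric mean (rate constants are positive and
log-normally spread), with the SE from the spread of per-row values;
rows below the curve's range are reversible and carry no kinetic
information, and if *every* row has $\Delta E_p < 5$ mV only a lower
bound on $k_s$ is reported. $\alpha$ is taken as 0.5 in this mode —
the field's default when no $\alpha$ is reported — and is *fitted* only
in the irreversible-branch mode, where both branch slopes vs $\ln\nu$
estimate it and $k_s$ follows from the intercept condition
$E_p = E^{\circ\prime}$. When both routes apply they are cross-checked
and a >25% disagreement warns.

**Arrhenius, Marcus, distances.** $\Delta H^\ddagger = -R \times$ slope
of $\ln k_s$ vs $1/T$, identifying the Arrhenius energy with
$\Delta H^\ddagger$ directly — the activation entropy is treated as
negligible, and the $E_a = \Delta H^\ddagger + RT$ correction is
deliberately *not* applied, matching how these systems are analyzed;
at 293 K the correction (2.4 kJ mol$^{-1}$) is comparable to typical
fit SEs. $\lambda = 4\Delta H^\ddagger$ is the zero-driving-force
Marcus inversion. The tunneling distance inverts
$\ln k_s = \ln\nu_0 - \beta(r - r_0) - \Delta H^\ddagger/RT$ with
defaults $\nu_0 = kT/h$ (≈ 6×10¹² s⁻¹ near room temperature),
$\beta = 1$ Å$^{-1}$, $r_0 \in [0, 3]$ Å, and a through-SAM distance of
19 Å for an MUA monolayer — all overridable. Because $r_0$ is only
bounded, the SAM-surface-to-center distance is an *interval* whose
width equals the $r_0$ range exactly; negative distances are floored at
zero with a warning, since a redox center inside the monolayer is
unphysical.

## What the synthetic data do and do not show

The generators emulate: quasi-reversible one-electron surface waves
($k_s$ 0.1–10 s$^{-1}$, $\Gamma_0$ 10$^{-12}$–10$^{-10}$ mol
cm$^{-2}$), capacitive baselines, Gaussian current noise, linear
$E^{\circ\prime}(T)$ series over 5–45 °C, titration-shaped
$E^{\circ\prime}$(pH) series, and trumpet datasets over the
0.02–0.5 V s$^{-1}$ window. They do not emulate: uncompensated-
resistance distortion, coverage dispersion (a distribution of
$E^{\circ\prime}$ or $k_s$ across sites, which broadens real peaks
beyond 90.6/n mV), film loss over cycles, catalytic O₂-reduction
currents, or drifting baselines. Passing tests therefore demonstrate
that the *estimators* are correct and stable under the stated noise
model — not that real films satisfy the ideal model; the diagnostics
(FWHM, $Q_a/Q_c$, linearity of $i_p$ in $\nu$) are what decides that on
real data.

Default noise levels in the shipped checks are the reproducibility
levels such measurements quote: 1–2 mV on potentials and 1% of peak
current, with effect sizes (entropy ≈ −50 to −100 J mol$^{-1}$
K$^{-1}$, $k_s \approx 1$ s$^{-1}$, pKa spans of several units) in the
range reported for SAM-immobilized blue copper proteins.

## Problem sizes and runtime choices

Simulations use a 0.1 mV output grid (10,000 points per 0.5 V sweep
pair); titration fits use 33-point pH grids (pH 4–12, step 0.25) with
50 multi-starts; Monte-Carlo checks of estimator coverage use 1000
replicates of 9-point temperature series; trumpet analyses use 6–8
scan rates. These sizes keep every fit comfortably identified while the
whole suite runs in well under a minute on one core.

## Known limitations

- One adsorbed state: no dispersion in $E^{\circ\prime}$ or $k_s$.
- The working-curve route fixes $\alpha$; a wrong assumed $\alpha$
  biases $k_s$ when the trumpet is strongly asymmetric.
- The pH model fixes the Nernst coefficient rather than fitting it;
  freeing it would trade pKa identifiability for slope flexibility.
- Overlapping pKa pairs are reported with their honest (large)
  uncertainties rather than regularized apart.
- The tunneling analysis inherits every uncertainty of $\beta$, $\nu_0$
  and the through-SAM distance; its output is an interval, not a
  point estimate, by design.
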