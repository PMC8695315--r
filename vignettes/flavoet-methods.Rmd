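---
title: "Rate model, law fitting and peak equivalence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate model, law fitting and peak equivalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoet)
library(dplyr)
```

## The physical problem

In many flavoproteins the fluorescence of the flavin cofactor is quenched on
the picosecond scale by electron transfer from a nearby tryptophan (or
tyrosine) to the photoexcited isoalloxazine ring, Iso\*:

$$\mathrm{Iso}^* + \mathrm{Trp} \longrightarrow \mathrm{Iso}^- +
\mathrm{Trp}^+, \qquad \Delta G^0.$$

Two empirical regularities organise these rates. The **energy gap law**
(SEGL): the logarithmic rate is a downward parabola in the driving force
$-\Delta G^0$, peaking at $X_m(\mathrm{ES})$. The **Dutton law**: for slower
transfers, $\ln k$ falls linearly with the donor–acceptor distance $R_c$;
for ultrafast donors the same plot bends into a parabola with an interior
peak $X_m(R_c)$ — an "extended" Dutton law (EXDL) whose short-distance
branch (rates *decreasing* as the pair approaches) is the distance-axis
inverted region. Because the driving force itself declines roughly linearly
with distance (the **ESRC** relation $-\Delta G^0 = B_3 R_c + C_3$), the
two inverted regions are two views of the same Marcus physics: mapping the
distance peak through the ESRC line, $X_m(\mathrm{ESRc}) = B_3
X_m(R_c) + C_3$, should land on the energy-axis peak $X_m(\mathrm{ES})$.
Quantifying that equivalence — on published fit coefficients and on
synthetic trajectories — is what this package does.

## The rate model

The per-snapshot rate is the Marcus–Kakitani–Mataga (MKM) form,

$$k(t) = \frac{\nu_0}{1 + \exp[\beta\,(R_c(t) - R_0)]}\;
\exp\!\left[-\frac{\{\Delta G^0(t) + \lambda(t)\}^2}
{4\lambda(t) k_B T}\right] \quad (\mathrm{ps}^{-1}),$$

a sigmoidal adiabatic/nonadiabatic distance gate times a classical Marcus
Franck–Condon factor. We deliberately omit a
$(4\pi\lambda k_B T)^{-1/2}$ normalisation in front of the exponential: it
only rescales the prefactor by a slowly varying factor, the package treats
$\nu_0$ as an effective empirical frequency, and with it the activationless
rate at $R_c = R_0$ is exactly $\nu_0/2$ — a convenient anchor that the
tests exploit. `ln_et_rate()` evaluates the logarithm directly (via
`log1p`) so deep-inverted snapshots underflow gracefully.

The solvent reorganization energy is the two-sphere dielectric continuum
expression

$$\lambda(R_c) = C_e\left(\frac{1}{2a_D} + \frac{1}{2a_A} -
\frac{1}{R_c}\right)\left(\frac{1}{\epsilon_\infty} -
\frac{1}{\epsilon_0}\right),$$

with $C_e = e^2/4\pi\epsilon_{vac} = 1.439964$ eV nm, monotone increasing
in distance. The free-energy gap decomposes as

$$\Delta G^0 = (E_{IP} - E_{EA}) - \frac{C_e}{\epsilon_0^{DA} R_c} +
E_{net},$$

where the middle term is the ion-pair Coulomb stabilisation and $E_{net}$
sums the screened interactions of each charged protein residue with the
acceptor anion ($-1$) and donor cation ($+1$)
(`net_electrostatic_energy()`). The point-charge sum is a generic
continuum-screened reading of the ion-pair/protein electrostatics; no
attempt is made to reproduce any particular force field.

### Parameters, units, defaults

Everything internal is eV / nm / ps. The `et_params()` defaults are
illustrative placeholders for a generic ultrafast donor, **not** values
fitted to any protein:

| parameter | default | why |
|---|---|---|
| $\nu_0$ | 1000 ps$^{-1}$ | sub-ps activationless transfer at contact |
| $\beta$ | 14 nm$^{-1}$ | mid-range of protein tunnelling decay constants |
| $R_0$ | 1.0 nm | see below |
| $a_D = a_A$ | 0.25 nm | aromatic-ring effective radii |
| $\epsilon_\infty,\ \epsilon_0$ | 2, 5 | protein interior optical/static screening |
| $\epsilon_0^{DA}$ | 2 | low-polarity donor–acceptor gap |
| $T$ | 298 K | ambient; $k_BT = 0.0256797$ eV |

$R_0$ deserves a note. With $R_0$ well below the sampled distances the
sigmoid gate sits on its steep exponential flank and its slope $-\beta$
overwhelms the gentle Franck–Condon curvature, so a sub-nanometre donor
could never show the parabolic distance profile that ultrafast donors
actually display. Placing $R_0 = 1.0$ nm puts the 0.6–0.85 nm donors near
the adiabatic plateau (effective gate slope $\sim 0.3$ nm$^{-1}$), which is
exactly the regime in which the distance-axis inverted region, and the
peak equivalence, emerge from the model. Users studying the classical
linear Dutton regime should move $R_0$ below their sampled range.

## The synthetic-trajectory generator

Real molecular-dynamics snapshot series for these systems are not publicly
deposited, so `simulate_trajectory()` emulates their statistical structure:

* $R_c(t)$ is a stationary AR(1) Gaussian process (mean 0.72 nm, marginal
  SD 0.03 nm, lag-1 correlation 0.8 by default, clipped below at 0.3 nm) —
  the simplest stationary process with tunable autocorrelation, matching
  the ~0.64–0.83 nm excursions of fast donors.
* $-\Delta G^0(t)$ is drawn from the linear ESRC model,
  $C + B\,R_c(t) + \mathcal{N}(0, \sigma)$, with slope $-0.5$ eV/nm
  (mid-range of observed ESRC slopes, which span roughly $-0.3$ to $-1.7$
  eV/nm) and scatter $\sigma = 0.02$ eV, comparable to the width of
  observed driving-force windows. Generating the driving force directly
  from the line, rather than from explicit charges, gives the generator
  exact ground truth (`true_values`); charge-based exercises remain
  available through `build_charge_environment()` and `free_energy_gap()`.
* the window centre `neg_sfeg_mean_ev` defaults to $\lambda(\bar R_c)$,
  i.e. the series straddles the energy-gap-law vertex as ultrafast donors
  do; placing it well below the vertex reproduces normal-region donors
  with linear distance profiles.
* $\lambda(t)$ comes from the continuum expression, and $\ln k(t)$ from the
  MKM rate. Seeds are mandatory and all randomness is local — the global
  RNG state is never touched, and equal seeds give byte-identical series.

The generator reproduces the *statistical shape* of snapshot data — ranges,
autocorrelation, linear distance–energy coupling, noise level — not real
force-field energetics, hydrogen-bond dynamics, conformational
sub-states, or wavelength-dependent acceptor shifts. Passing
parameter-recovery and equivalence tests on this generator therefore
validates the analysis pipeline and the internal consistency of the model,
not the molecular-dynamics provenance of any real dataset.

Default problem sizes — 500 snapshots for recovery checks, 1000 for
equivalence checks — were chosen as the smallest ensembles at which the
least-squares standard errors are comfortably inside the assertion bands.

## Law fitting and classification

All fits are unweighted ordinary least squares (`stats::lm`); the published
analyses state no weighting scheme. `fit_parabola()` reports the vertex
$-b/2a$ only for a downward parabola; upward fits carry a flag instead of a
peak. $R^2$ is $1 - SS_{res}/SS_{tot}$, reported unclamped (negative for
fits worse than the mean — documented, not hidden).

Distance profiles are classified by `classify_relationship()` as
*parabolic* / *linear* / *none*. Published classifications are
by inspection; our reproducible stand-in is: parabolic requires a
significant quadratic term (partial F-test, $\alpha = 0.05$), downward
curvature, and a vertex inside the observed range extended by half its
width on either side (a vertex far outside the data is a numerically
unstable extrapolation, not an observed peak); otherwise linear requires
line $R^2 \ge 0.2$; otherwise none. Both thresholds are exposed as
arguments.

Region bookkeeping (`region_partition()`): on the energy axis the inverted
region is $-\Delta G^0 > X_m(\mathrm{ES})$; on the distance axis it is
$R_c < X_m(R_c)$. Values exactly at the threshold count as *normal* — the
boundary case is undefined in the source analyses, so we fixed one
convention and froze it.

## Peak equivalence and rounding discipline

`donor_equivalence_report()` runs the full three-law analysis per donor.
For a parabolic distance profile, $X_m(R_c)$ is the fitted vertex and
$X_m(\mathrm{ESRc})$ its image under the ESRC line; for a linear profile
the line is inverted at the (unrounded) energy-axis vertex to back-evaluate
the distance at which the rate *would* peak, flagged `extrapolated` when it
falls below the sampled range. **No intermediate quantity is ever
rounded**: the published back-evaluated distance peaks are reproducible
only from the full-precision vertex (e.g. a vertex of 1.6869 eV inverts to
0.54 nm, while the displayed 1.69 eV does not), and a fixture test pins
this down. Display rounding to two decimals exists only in report columns.

Agreement between $X_m(\mathrm{ES})$ and $X_m(\mathrm{ESRc})$ uses a
default tolerance of 0.10 eV — our quantification of the verbal
"quite close" standard; at that tolerance exactly one published donor
(FBP Trp32A, 0.77 vs 0.91 eV) disagrees, which is also the one exception
the source analysis itself singles out. An optional per-donor `rc_max`
cutoff supports donors with two distance conformations, where the line is
fitted to the short-distance population only.

## The coefficient fixtures

The published parabola/line coefficients for the four proteins ship as CSV
fixtures (`load_fixtures()`), and every derived peak column is recomputed
by pure arithmetic (`recompute_derived_columns()`) and compared at the
tables' two-decimal display precision. Three bookkeeping rules, fixed after
checking every row by hand:

* where running text and table disagree on a coefficient, the **table**
  value is canonical, because it is the one that reproduces the printed
  derived cell; the text variant is kept as a row note.
* three energy-axis peaks (FBP Trp32B/Trp106A/Trp106B) cannot be obtained
  from their own printed coefficients and instead coincide with the
  distance-axis peaks — flagged as annotated mismatches, not "fixed".
* two mapped peaks (FBP Trp106A, MCAD Trp166B) are off by exactly one
  display ulp; also annotated.

`verify_against_printed()` passes in lenient mode iff no *unannotated*
mismatch exists; strict mode fails on any, naming the rows.

## Known limitations

* No confidence intervals on peak locations, no robust/weighted
  regression, no outlier handling — the source analyses use none.
* The model is classical: no Marcus–Jortner quantum modes, no
  temperature-dependent gating, and no molecular-orbital treatment of the
  short-distance region.
* $R_c$ is accepted as a given per-snapshot scalar; the aromatic-atom-pair
  averaging that defines it requires atomic coordinates and is out of
  scope.
* Generator realism is statistical only (see above).

## A compact end-to-end example

```{r pipeline, eval = FALSE}
p <- et_params()
sim <- simulate_trajectory(trajectory_spec(n_snapshots = 1000, seed = 1), p)
rep <- donor_equivalence_report(sim$snapshots)
rep[, c("exdl_class", "xm_es", "xm_rc", "xm_esrc", "abs_diff", "agrees")]
verify_against_printed()
```
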