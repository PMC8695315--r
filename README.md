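# flavoet

Analysis of ultrafast photoinduced electron transfer (ET) from aromatic
amino-acid donors to the photoexcited isoalloxazine ring (Iso\*) of flavin
cofactors — the process that quenches flavoprotein fluorescence on the
picosecond scale. The package is for photophysicists and computational
biophysicists who work with per-snapshot ET observables (donor–acceptor
distance, driving force, rate) from molecular-dynamics-based analyses.

## The model and the three laws

Per snapshot, the Marcus–Kakitani–Mataga rate is

$$k = \frac{\nu_0}{1+\exp[\beta(R_c-R_0)]}\,
\exp\!\left[-\frac{(\Delta G^0+\lambda)^2}{4\lambda k_BT}\right]
\quad (\mathrm{ps}^{-1}),$$

with the two-sphere continuum reorganization energy
$\lambda(R_c) = C_e(1/2a_D + 1/2a_A - 1/R_c)(1/\epsilon_\infty -
1/\epsilon_0)$ and the gap decomposition
$\Delta G^0 = (E_{IP}-E_{EA}) - C_e/(\epsilon_0^{DA}R_c) + E_{net}$.

Three empirical laws organise snapshot ensembles:

* **SEGL** (energy gap law): $\ln k$ is a downward parabola in
  $-\Delta G^0$ with vertex $X_m(\mathrm{ES})$; driving forces above the
  vertex are the *E-inverted* region.
* **EXDL** (extended Dutton law): $\ln k$ vs $R_c$ — parabolic for
  ultrafast donors (vertex $X_m(R_c)$; shorter distances are the
  *Rc-inverted* region), linear for slower ones (the classical Dutton
  decay with slope $-\beta$).
* **ESRC**: the approximately linear decline of $-\Delta G^0$ with $R_c$,
  $-\Delta G^0 = B_3 R_c + C_3$.

The ESRC line maps the distance peak onto the energy axis,
$X_m(\mathrm{ESRc}) = B_3 X_m(R_c) + C_3$; agreement with
$X_m(\mathrm{ES})$ demonstrates that the two inverted regions are
equivalent. The package fits the laws, extracts and maps peaks, classifies
profiles, partitions snapshots into inverted/normal regions, generates
seeded synthetic snapshot trajectories, and ships the published fit
coefficients for four flavoproteins (FMN-binding protein, wild-type and
T169S pyranose 2-oxidase, medium-chain acyl-CoA dehydrogenase) as
arithmetic-checked fixtures.

## Worked example

```r
library(flavoet)
p <- et_params()                       # illustrative defaults, eV/nm/ps
sim <- simulate_trajectory(trajectory_spec(n_snapshots = 1000, seed = 1), p)
sim
#> <synthetic_dataset> 1000 snapshots
#>   rc: mean 0.720 nm (sd 0.030, lag-1 0.80); -SFEG line: 1.488 -0.500 * rc (noise sd 0.020 eV)
#>   lambda(rc_mean) = 1.1280 eV (= true energy-gap-law vertex)

donor_equivalence_report(sim$snapshots)[, c("exdl_class", "xm_es", "xm_rc",
                                            "xm_esrc", "abs_diff", "agrees")]
#>   exdl_class    xm_es     xm_rc xm_esrc    abs_diff agrees
#> 1  parabolic 1.130709 0.7137456 1.13225 0.001541161   TRUE
```

The distance profile is classified parabolic; the energy-gap-law vertex
(1.1307 eV) and the distance-axis vertex mapped through the fitted ESRC
line (1.1322 eV) agree to 0.0015 eV — both recover the generator's true
vertex $\lambda(\bar R_c) = 1.1280$ eV, the model-level statement that the
energy- and distance-axis inverted regions are the same physics.

The published coefficient tables recompute cleanly:

```r
verify_against_printed()
#> <fixture_report> 29/34 rows arithmetic-consistent; PASS
#>   flagged rows:
#>    T1 FBP Trp32B: printed 0.82 vs recomputed 0.74 [annotated]
#>    T1 FBP Trp106A: printed 0.90 vs recomputed 0.85 [annotated]
#>    T1 FBP Trp106B: printed 0.94 vs recomputed 0.85 [annotated]
#>    T2 FBP Trp106A: printed 0.92 vs recomputed 0.93 [annotated]
#>    T2 MCAD Trp166B: printed 2.46 vs recomputed 2.47 [annotated]
```

Every flagged row is a documented internal inconsistency of the printed
tables (see the fixture notes), not a computational discrepancy.

`plot_segl()`, `plot_exdl()`, `plot_esrc()` and `autoplot()` methods
draw the law panels; `tidy()`/`glance()` expose fit coefficients and
summaries as tibbles.

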