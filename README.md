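# pullwork

Free-energy bounds for ligand unbinding from nonequilibrium steered-pull
work.

When a ligand is extracted from its receptor by a harmonic spring whose free
end moves at constant velocity, each pull performs an irreversible mechanical
work $W_i$. The Jarzynski equality,

$$\langle e^{-W/k_BT}\rangle = e^{-\Delta G/k_BT},$$

ties the distribution of those works to the equilibrium free-energy
difference. From a finite set of $N_s$ pulls, two upper bounds on
$\Delta G$ are available:

$$W^a = \frac{1}{N_s}\sum_{i=1}^{N_s} W_i, \qquad
  W^x = -k_BT\,\ln\Big[\frac{1}{N_s}\sum_{i=1}^{N_s} e^{-W_i/k_BT}\Big],$$

with $\Delta G \le \langle\langle W^x\rangle\rangle \le \langle\langle
W^a\rangle\rangle$ and $W^x \le W^a$ exactly for every sample. Part of the
measured work is solvent drag, not binding: repeating the identical protocol
with the receptor absent measures this "viscous work", and subtracting its
$W^x$ (errors in quadrature) yields the corrected bound. Free energies from
experimental affinity constants, $\Delta G = k_BT\ln(K_a c^\circ)$, close
the loop with experiment.

The package is written for people who analyse steered-MD pulling data: it
reads and writes GROMACS-pull-style XVG force/position files, integrates
per-replica work (spring-end or center-of-mass convention), computes $W^a$
and $W^x$ with bootstrap errors, applies the viscous correction, locates the
convergence point where the bound system's force profile becomes
indistinguishable from the control (error-bar crossing, doubled into a
production cutoff), partitions the path at the binding-pocket threshold
plane, and summarises the work populations. A steered overdamped-Langevin
generator with an exact quadrature free-energy oracle
(`analytic_delta_g_spring()`) validates the entire chain against a known
answer.

## Worked example

The reference scenario mirrors a 30-replica constant-velocity protocol in
reduced units ($k_BT = 1$): spring constant 400, pull rate 0.01 over 500
time units (travel 5), drag 400, and a 35 $k_BT$ Gaussian binding well. The
receptor-free control is generated automatically.

```r
library(pullwork)
report <- run_pipeline(run_config(bound = pull_config(seed = 1L),
                                  B = 1000L, seed = 501L, Ka = 18.79e3))
print(report)
#> <pull_report>
#>   production cutoff: 1.55 (error-bar crossing at 0.775, doubled)
#> <estimator_result> [bound] N_s = 30, T = 1 (reduced units)
#>   Wa = 41.9 +/- 0.5
#>   Wx = 39 +/- 0.5
#> <estimator_result> [viscous] N_s = 30, T = 1 (reduced units)
#>   Wa = 6.5 +/- 0.5
#>   Wx = 4.1 +/- 0.4
#>   corrected Wx = 34.96 +/- 0.645 (display: 35 +/- 0.6)
#>   analytic dG (0 -> cutoff): 34.66 (34.66 kBT)
#> <ordering_report> dG <= Wx <= Wa: PASS
#>   dG = 34.66, Wx = 39.04, Wa = 41.88
#>   margin Wx - dG = 4.38 kBT (ok), margin Wa - Wx = 2.84 kBT (ok)
#>   experimental dG from Ka: 4.076e-20 J
#> <region_partition> boundary 1.47 of 5 (interior 29.4% of the pull)
#>   interior work 41.59 +/- 0.57 (n = 30)
#> <work_histogram_summary> 20 bins over [2.016, 49.47]
#>   bound:   mean 41.88, sd 3.069 (n = 30)
#>   viscous: mean 6.483, sd 2.874 (n = 30)
#>   standardized mean difference 11.9; overlap coefficient 3.2e-09
```

Reading the output: the bound pulls dissipate heavily ($W^a = 41.9\,k_BT$),
the Jarzynski estimator tightens the bound to $39.0\,k_BT$, and subtracting
the viscous control's $W^x$ lands at $35.0 \pm 0.6\,k_BT$ — statistically on
top of the exact quadrature free energy of this synthetic system
($34.66\,k_BT$). Both inequalities of the ordering hold, the interior
(in-pocket) region is 29.4% of the pull, and the bound and control work
populations are ~12 pooled SDs apart, i.e. cleanly distinguishable. The
experimental field converts the affinity constant $K_a = 18.79\times10^3\,
\mathrm{M}^{-1}$ at 300 K into $4.08\times10^{-20}$ J.

## Analysis workflow

The `analysis/` scripts run the same study stepwise, writing tables under
`results/`:

1. `01_simulate.R` — generate 30 bound + 30 control replicas, write XVG
   force/position pairs.
2. `02_integrate_work.R` — read the XVG pairs, integrate cumulative work per
   replica (`results/work_series.csv`).
3. `03_profiles_and_cutoff.R` — replica-averaged force profiles, error-bar
   crossing, production cutoff (`results/force_profile.csv`,
   `results/cutoff.json`).
4. `04_estimate_free_energy.R` — work samples at the cutoff, $W^a$/$W^x$
   with bootstrap errors, viscous correction, ordering against the exact
   oracle, region partition, histogram summary
   (`results/estimates.json`).

Published MD work values that cannot be recomputed at desk scale (they
require all-atom simulations of the aspirin–albumin complex) enter only as
printed inputs to the correction arithmetic, never as recomputed outputs.

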