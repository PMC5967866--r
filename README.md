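# vesiflux

Quantitative analysis of radiotracer flux assays in reconstituted
proteoliposomes: from counts on a filter to a channel-versus-transporter
phenotype call.

## The problem

Uptake assays with purified membrane proteins reconstituted into lipid
vesicles measure *amounts* of accumulated substrate. Deciding whether the
protein merely equilibrates its substrate (channel, uniporter, facilitated
diffusion) or concentrates it by coupling to an ion gradient (symport)
requires the *internal* concentration — and therefore the total aqueous
volume enclosed by all vesicles in the assay, which is never measured
directly. `vesiflux` computes it from vesicle geometry:

- lipids per unilamellar vesicle:
  `N_tot = (4πr² + 4π(r−m)²) / a`
  with external radius `r`, bilayer thickness `m`, headgroup area `a`;
- vesicle count: molar lipid concentration × Avogadro constant / `N_tot`;
- intraliposomal volume: `V_PL = (4/3)π(r−m)³ × N_PL`.

Accumulated moles divided by `V_PL` give the internal concentration; the
ratio to the external concentration is the **fold accumulation**, ~1 at
equilibrium for passive flux and ≫1 for coupled transport, on which the
phenotype call is made.

Around that core, the package provides Michaelis–Menten fitting (Km,
Vmax), turnover numbers (`kcat = Vmax·M/60000`), four-parameter
log-logistic EC50/IC50 fits for displacement and inhibition isotherms,
Nernst diffusion potentials for ionophore-clamp experiments, ohmic
single-channel conductance estimation, and seeded simulators for all of
these data types.

## Worked example

A 100-nm vesicle assay (0.02 mg lipid in 100 µL, 0.5 mM external
substrate) with a peak of 0.1869 nmol at 15 s and a 120-s plateau of
0.1145 nmol:

```r
library(vesiflux)
cfg <- pipeline_config(liposome_spec(), assay_spec(0.02, 100, 0.5),
                       plateau_n = 1)
tc <- uptake_time_course(c(0, 5, 15, 60, 120),
                         c(0, 0.09, 0.1869, 0.13, 0.1145))
run_pipeline(cfg, tc)
#> Proteoliposome flux report (v1.0)
#>   lipids/vesicle   : 82866.24
#>   vesicles/L       : 1.838e+15
#>   V_internal       : 0.07493 uL
#>   peak             : 0.1869 nmol at 15 s -> 2.494 mM
#>   plateau          : 0.1145 nmol -> 1.528 mM
#> Transport phenotype report
#>   internal conc (peak)    : 2.494 mM
#>   internal conc (plateau) : 1.528 mM
#>   fold at peak            : 4.988 (~5)
#>   fold at plateau         : 3.056 (~3)
#>   passive baseline        : 1
#>   thresholds              : channel <= 10, concentrative >= 50
#>   call                    : channel-like
```

The 82,866 lipids/vesicle and 0.0749 µL internal volume are the geometric
chain; 2.49 mM inside against 0.5 mM outside is a ~5-fold peak excess
decaying to ~3-fold — far below what coupled transport achieves, hence the
channel-like call. For comparison, an ion-coupled transporter accumulating
2.78 × 10⁻¹¹ mol of substrate against 2.5 µM external in the same vesicle
preparation sits at ~150-fold and is called concentrative.

Kinetics on simulated rate data:

```r
d <- simulate_mm_rates(8.69, 100.4, cfg = sim_config(seed = 42))
fit_michaelis_menten(d, protomer_mass = 27730)
#> Michaelis-Menten fit: Km = 9.311 +/- 0.5 mM, Vmax = 103.6 +/- 2 umol/mg/min
#>   kcat = 47.88 s^-1
#>   converged: TRUE, residual SS = 118
```

And the potential a valinomycin clamp imposes at a 1:100 K⁺ gradient:

```r
nernst_potential(k_in = 1, k_out = 100)
#> [1] 118.3187
```

See the vignette (`vignettes/proteoliposome-flux.Rmd`) for the model,
its assumptions, and all numerical choices.

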