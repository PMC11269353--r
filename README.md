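# stdbind

Quantitative analysis of small-molecule binding to human serum albumin
(HSA) from ligand-observed NMR and equilibrium separation experiments.

`stdbind` was built around the characterization of the synthetic
cathinones 3- and 4-chloromethcathinone (3-/4-CMC), but every stage is
generic: it applies to any ligand whose binding is probed by saturation
transfer difference (STD) NMR, WaterLOGSY, competition with Sudlow-site
probes, and equilibrium dialysis (ED) or ultrafiltration (UF).

## What it computes

**STD build-up and epitope maps.** For each ligand proton *i*, the STD
amplification factor at saturation time *t* is

    eta_i(t) = (I0 - I_STD) / I0 * epsilon

with `I0`/`I_STD` the off-/on-resonance intensities and `epsilon` the
ligand:protein concentration ratio. Build-up curves are fitted by
nonlinear least squares to the saturating mono-exponential

    eta_i(t) = STD_max * (1 - exp(-k_sat * t))

and the initial growth rate **STD0 = STD_max * k_sat** — the transfer
measure insensitive to per-proton relaxation and spin-diffusion
differences — is normalized per ligand to its maximum (= 100 %) to give
the epitope-binding map: the larger a proton's normalized STD0, the
closer its contact with the protein.

**Binding-site assignment.** Competition with site-selective probes
(warfarin for Sudlow site I, diazepam for site II) attenuates STD0; the
per-proton ratio `100 * STD0_with_probe / STD0` is aggregated per probe
(median), and the probe with the smaller median marks the main binding
site. WaterLOGSY responses are classified from sign inversion
(binder / weak-or-ambiguous / non-binder).

**Binding degree and equilibria.** From ED/UF concentrations the bound
percentage is `100 * (D_t - D_f) / D_t`. Mass-action solvers cover the
1:1 equilibrium (closed form) and competitive two-site systems
(log-scale root finding), and binding free energies interconvert with
dissociation constants via `Kd = exp(dG / RT)` (1 M standard state).

**Synthetic data.** A generator simulates build-up series, competition
pairs (occupancy-driven amplitude scaling) and dialysis replicates with
multiplicative noise and embedded ground truth, so the whole chain is
validated by recovery tests.

## Worked example

```r
library(stdbind)

# fit one noiseless synthetic build-up curve
ds <- generate_buildup_dataset(template_3cmc(), noise = noise_model(0, 0),
                               seed = 1)
fit_buildup(ds$series[["H2"]])
#> Build-up fit 3-CMC/H2 (7.99 ppm)
#>   STD_max = 21.82 +/- 4.2e-15, k_sat = 0.55 +/- 2.4e-16 1/s
#>   STD0 = 12 +/- 3.3e-15 1/s (rss = 2.84e-29, n = 8)

# assign binding sites from the bundled competition ratios
assign_sites(cmc_attenuation_entries("3-CMC"))
#> Binding-site assignment
#>   diazepam   (site_II): median ratio 37.5%
#>   warfarin   (site_I): median ratio 76.0%
#>   main site: site_II
#>   secondary site: site_I
#>   margin: 38.5 percentage points

# full simulated pipeline: fits, epitope map, competition, binding degree
run_pipeline(list(seed = 7, simulate = list(ligand = "3-CMC"),
                  dialysis = list(simulate = list(n_replicates = 5))))
#> stdbind analysis report (seed 7 )
#>   NMR: 7 fitted protons
#>   main site: site_II (margin 52.5 pp)
#>   binding degree (ED): 79.0 +/- 0.1 % (n = 5)
#>   binding degree (UF): 79.1 +/- 0.4 % (n = 5)
```

The fitted STD_max/k_sat equal the planted truth to floating precision;
diazepam attenuates STD0 far more than warfarin, so Sudlow site II is
the main binding site with site I secondary; and the simulated plasma
system is ~79 % protein-bound by both separation methods.

A command-line wrapper over the same functions ships in
`inst/scripts/stdbind-cli.R` (subcommands `run`, `simulate`,
`fit-buildup`, `epitope-map`, `assign-sites`, `binding-degree`); the
configuration keys are documented in `inst/extdata/config-reference.yaml`.

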