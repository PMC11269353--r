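---
title: "Models and methods behind stdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stdbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`stdbind` implements the quantitative chain used to characterize the
binding of small ligands — its built-in templates describe the synthetic
cathinones 3- and 4-chloromethcathinone (CMC) — to human serum albumin
(HSA): STD-NMR build-up analysis and epitope mapping, competition-probe
binding-site assignment, WaterLOGSY classification, binding-degree
computation from equilibrium dialysis (ED) or ultrafiltration (UF), and
the mass-action equilibria that tie these observations together. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the validation does and does not show.

## The STD build-up model

STD NMR saturates protein resonances selectively; the saturation
transfers by NOE to ligand protons in contact with the protein and
attenuates their signals. For proton $i$ the amplification factor is

$$\eta_i(t) = \frac{I_0 - I_\mathrm{STD}}{I_0}\,\varepsilon,$$

where $\varepsilon$ is the ligand:protein concentration ratio
(default 40, matching 800 µM ligand over 20 µM HSA) and $t$ the
saturation time. The build-up is modelled as a saturating
mono-exponential,

$$\eta_i(t) = \mathrm{STD}_{max}\left(1 - e^{-k_{sat} t}\right),$$

whose initial slope $\mathrm{STD}_0 = \mathrm{STD}_{max}\,k_{sat}$ is
used for epitope mapping: unlike any single-time STD intensity, the
initial rate is insensitive to differences in longitudinal relaxation
and intra-ligand spin diffusion between protons. Epitope maps normalize
$\mathrm{STD}_0$ per ligand to the largest value (100 %); ties at the
maximum break to the lowest chemical shift so the reference proton is
deterministic.

### Fitting and uncertainties

The fit is unweighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), initialized at $\mathrm{STD}_{max}^0 = \max\eta$ and
$k_{sat}^0 = \eta(t_1)/(\mathrm{STD}_{max}^0 t_1)$ clipped to
$[10^{-3}, 10]$ s$^{-1}$, with bounds
$\mathrm{STD}_{max}\in(0,\varepsilon]$ (the amplification factor cannot
exceed $\varepsilon$ while $I_\mathrm{STD}\ge 0$) and
$k_{sat}\in(0,100]$ s$^{-1}$. Negative $\eta$ values (possible under
noise) are retained — clipping them would bias the fit — and flagged
with a warning. Three numerical honesty rules apply:

* a fit whose parameters land on the box bounds is flagged
  non-converged: a pinned estimate is not a usable optimum, and
  downstream stages treat the proton as undetermined;
* a series whose $\eta$ never exceeds a configurable floor
  (default 0.05) raises a no-transfer error instead of fitting noise;
* an overlap-flagged series raises an overlap error, which competition
  tables report as an explicit undetermined marker.

Standard errors come from an HC3-type sandwich covariance rather than
the homoscedastic least-squares formula. The measurement noise is
multiplicative on intensities, so the $\eta$ errors scale with the
residual signal ($\propto I_\mathrm{STD}/I_0$) and are heteroscedastic
across the schedule; in simulation the sandwich brings the empirical
coverage of $\pm 2\,\mathrm{se}$ intervals for $\mathrm{STD}_0$ to
0.91–0.95, where the homoscedastic covariance sat at the edge of 0.90.
The $\mathrm{STD}_0$ error is propagated to first order,
$\mathrm{var}(\hat m\hat k) \approx k^2 V_{mm} + m^2 V_{kk} + 2mkV_{mk}$.

### Competition refits share the build-up rate

Competition with a site-selective probe reduces the ligand occupancy of
the probed site and with it the transfer amplitude; in the
fast-exchange regime the build-up *rate* is a property of the
saturation and relaxation dynamics and is essentially unchanged. The
package therefore refits with-probe series with $k_{sat}$ fixed at the
reference fit's estimate (`fit_buildup(k_fixed = )`,
`fit_buildup_set(reference_fits = )`, pipeline key
`constrain_rate: true`). This makes the amplitude a linear parameter
and the attenuation ratio
$100\times\mathrm{STD}_{0,\mathrm{probe}}/\mathrm{STD}_0$ well
conditioned even for strongly attenuated signals, where a fully free
refit can wander to steep-rate/low-amplitude optima whose
$\mathrm{STD}_0$ is off by factors of 2–3. Free refits remain available
(`constrain_rate: false`) for data where the rate may genuinely change.

## Site assignment

Per-probe ratios are aggregated by the median over determined protons —
robust to the single-proton outliers these tables typically show — with
the mean offered as an option. The probe with the smaller median marks
the **main** site; another probe's site is **secondary** if its median
shows real competition (below 100 − 10 points); the verdict is
**ambiguous** if the two smallest medians differ by fewer than 10
percentage points. The 10-point default leaves the bundled CMC
competition tables (separations ≥ 17 points) unambiguous while
absorbing the ~3–5-point scatter of median ratios at the default noise
level. Ratios above 100 % are retained with a warning; they never
support a binding verdict. The probe→site mapping is configuration
(defaults: warfarin → site I, diazepam → site II), not hard-coded
chemistry.

WaterLOGSY observations are classified per proton: sign inversion
between the free and with-protein spectra → binder; same sign but
attenuated → weak or ambiguous; same sign, unattenuated → non-binder.

## Binding degree and equilibria

From a dialysis/ultrafiltration pair the bound percentage is

$$100\,\frac{D_t - D_f}{D_t},$$

with $D_t$ the total and $D_f$ the free concentration. This quantity is
sometimes labelled with the free-fraction symbol $F_u\%$ in the
applied literature even though the formula yields the *bound*
percentage; the package follows the formula and names the output
`binding_degree` / bound percent throughout. $D_f > D_t$ is an error,
not clipped — silent clipping would mask analytical failures. The
measure is scale invariant, so µg/mL and µM tables give identical
degrees (a molar mass converts units when mixing them).

The 1:1 equilibrium uses the numerically stable closed form of the
mass-action quadratic. The competitive two-site model treats the two
Sudlow sites as independent (no cooperativity — consistent with
sequential filling of a primary then a secondary site; cooperativity is
out of scope), each present at the protein concentration, with the
probe competing at exactly one site. Free concentrations are found by
nested Brent root-finding **on the log-concentration scale**, because
under tight binding the free concentration can sit hundreds of orders
of magnitude below the total and a linear bracket cannot resolve it;
solutions are accepted only if every mass balance closes to $10^{-9}$
relative. Free energies and dissociation constants interconvert as
$K_d = \exp(\Delta G / RT)$ with $R = 1.9872\times10^{-3}$
kcal mol$^{-1}$ K$^{-1}$, temperature default 298 K, 1 M standard state
(the docking convention), recorded in output metadata.

## What the synthetic generator emulates

The generator is first-class, tested code and defines the study
conditions:

* **Build-up series** — the eight-point schedule {0.5, 1, 1.5, 2, 3, 4,
  5, 6} s, $\varepsilon = 40$, and per-proton mono-exponential truth.
  The bundled templates carry the CMC proton sets (aromatic, methine,
  N- and C-methyl protons with their chemical shifts as labels); the
  planted $\mathrm{STD}_{max}, k_{sat}$ values are synthetic, chosen so
  the normalized-$\mathrm{STD}_0$ pattern reproduces the expected
  epitope ordering (aromatics ≈ 100–70 %, methyls ≈ 30–45 %) and the
  plateau on-resonance attenuation spans 13–55 % — a strongly
  saturating, well-measurable STD response.
* **Noise** — multiplicative Gaussian with coefficient of variation
  0.02 on each intensity (off- and on-resonance drawn independently per
  time point, so recomputed $\eta$ carries both errors), 0.01 on
  dialysis concentrations. Multiplicative noise is the natural model
  for scale-dependent spectral intensities.
* **Competition** — each proton's amplitude is scaled by the ratio of
  its site-weight-weighted bound-ligand concentration with versus
  without probe, computed by the two-site solver; $k_{sat}$ is left
  unchanged (the same fast-exchange assumption the analysis makes). The
  default system uses ligand dissociation constants of 150 µM (site II)
  and 450 µM (site I) — micromolar, site II main — and an 800 µM probe
  with $K_d = 5$ µM, the warfarin/diazepam class.
* **Dialysis** — replicate $(D_t, D_f)$ pairs around the model
  equilibrium of a plasma-like system: 600 µM albumin, 85 µM drug
  (≈ 20 µg/mL of a ~235 g/mol salt), $K_d = 140$ µM, giving a model
  bound fraction near 79 %, representative of a drug that is ~80 %
  protein-bound with micromolar affinity.

One top-level integer seed drives a single generator stream; the
caller's RNG state is saved and restored, and identical seeds give
byte-identical datasets.

The generator does **not** simulate free-induction decays, lineshapes,
peak overlap (overlap is an input flag, not an emergent phenomenon),
relaxation-matrix (CORCEMA-style) saturation transfer, dialysis
kinetics, nonspecific membrane binding, or multi-protein plasma.
Passing recovery tests therefore demonstrates the correctness and
calibration of the *estimators under the stated statistical model* —
not robustness to spectral artifacts, baseline errors or peak-picking
mistakes, which never enter the simulated tables.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle:
re-coded formulas for $\eta$ and the ratios, plain bisection (linear
bracket, 120–200 halvings) for both equilibrium solvers, delta-method
propagation for the simulated $\eta$ scatter, and the generator's
planted truth for end-to-end recovery. Headline checks, re-run by
`scripts/acceptance.R` from scratch at a caller-chosen seed:

* noiseless round trip: 100 random $(\mathrm{STD}_{max}, k_{sat})$
  draws recovered to ≤ 10⁻⁶ relative (observed ~10⁻¹⁴);
* estimator calibration: 500 replicates at cv = 0.02 for the
  reference (largest-$\mathrm{STD}_0$) proton — median relative
  $\mathrm{STD}_0$ error ≈ 4–4.7 %, $\pm2$ se coverage 0.91–0.93.
  Precision is quoted for the reference proton because it sets the
  epitope scale; weaker protons carry proportionally larger errors;
* the bundled CMC attenuation tables: site II main, site I secondary,
  margins 38.5 (3-CMC) and 17 (4-CMC) points, unambiguous at the
  10-point threshold;
* 100 random competition systems: whenever the planted median-ratio
  separation exceeds the 10-point threshold and a verdict is issued,
  the main site is recovered correctly (100 % across seeds with the
  shared-rate refit; intrinsically ambiguous systems are excluded by
  the planted margin, and near-threshold systems may still be reported
  ambiguous rather than forced);
* solver cross-checks: 1,000 (1:1) and 50 (two-site) random instances
  against bisection to 10⁻⁸ relative, mass balances to 10⁻⁹;
* the docking free-energy window [−6.67, −5.07] kcal/mol maps to
  $K_d \in$ [12.8, 191] µM — micromolar throughout — with the
  $\Delta G \leftrightarrow K_d$ round trip exact to 10⁻¹².

These sizes keep the full suite near twenty seconds on one CPU while
leaving the Monte-Carlo margins comfortable.

## Known limitations

* $\mathrm{STD}_0$ precision degrades roughly inversely with the
  plateau attenuation; for signals attenuated to a few percent of the
  off-resonance intensity the per-proton ratio uncertainty reaches tens
  of percent, and only the median over several protons remains
  informative.
* The shared-rate competition refit assumes fast exchange; slowly
  exchanging systems where competition changes the apparent build-up
  rate need `constrain_rate: false` and more protons (or replicates)
  to reach the same verdict confidence.
* The independent-sites equilibrium ignores cooperativity and any
  third site; the dialysis model ignores binding to proteins other
  than albumin.
* Attenuation magnitudes are used ordinally (which probe competes
  more); no ligand or probe $K_d$ is estimated from them.
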