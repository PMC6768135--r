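# ligex

Determination of metal:ligand mole ratios of coordination complexes from
spectrophotometric data, for analytical and pharmaceutical chemists working
with ligands that lack a usable chromophore (the motivating case:
bisphosphonate drugs chelating Fe(III)).

Three estimators are implemented behind one set of data structures:

* **Ligand-exchange (displacement) method** — increasing amounts of the test
  ligand L are added to a fixed amount of a colored indicator complex MX;
  the absorbance attenuation line is overlaid on the MX calibration line.
  With δ the absorbance of their intersection, the abscissa segments
  α = δ/s_direct and β = δ/|s_inverse| give the combining ratio: α/β
  estimates metal-per-ligand, and its reciprocal β/α = s_direct/|s_inverse|
  is the ligand-per-metal stoichiometry n of MLn. Only straight lines are
  fitted, so the method stays objective where weak binding bends the
  classical plots.
* **Job's method of continuous variations** — apex of absorbance vs metal
  mole fraction at constant total; x_max = 1/(1+n); deterministic
  branch-tangent or quadratic-vertex locator.
* **Mole-ratio (Yoe–Jones) tangent method** — rising line / plateau break
  found by exhaustive SSE-minimizing two-segment regression.

A competitive-equilibrium speciation solver (damped Newton in log
concentration space, with an independent nested-bisection cross-check)
simulates all the underlying experimental designs under mass action
([MX] = β_MX[M][X], [MLn] = β_MLn[M][L]^n) with additive Gaussian
photometric noise, enabling parameter-recovery validation and bias
comparison of the three estimators across binding-strength regimes.

## Worked example

Simulate the bench ligand-exchange design (indicator complex 0.3 mM, test
ligand 0.02–0.18 mM, noise 0.002 AU) and estimate the stoichiometry:

```r
library(ligex)
sys <- demo_system("exchange")            # illustrative Fe(III)-salicylate-like system
cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 11)
ex  <- simulate_exchange_design(sys,  noise_sd = 0.002, seed = 12)
res <- estimate_n_exchange(cal, ex)
res
#> <stoichiometry_result> method = ligand_exchange
#>   n_hat (ligand per metal) = 0.9993  -> metal:ligand 1:1
#>   bootstrap 95% CI: [0.9791, 1.0170]
res$geometry
#> <exchange_geometry>
#>   intersection (0.000150682, 0.237837), delta = 0.237837 AU
#>   alpha = 0.000148972, beta = 0.000148869, alpha/beta = 1.00069 (metal per ligand)
```

The calibration and attenuation lines intersect at 0.151 mM / 0.238 AU;
the abscissa segments are equal within noise (α/β ≈ 1.00), so the complex
combines 1:1 and the bootstrap interval comfortably covers n = 1.

The classical comparators, on their own bench designs (Job: nine mixtures
totalling 1 mM; mole ratio: ligand fixed at 0.5 mM, metal 0.04–3 mM):

```r
cl <- demo_system("classical")
job_analysis(simulate_job_design(cl, noise_sd = 0.002, seed = 21))
#> <job_result> apex at metal mole fraction 0.5003 (tangent locator)
#>   n_hat (ligand per metal) = 0.9990 -> metal:ligand 1:1
moleratio_analysis(simulate_moleratio_design(cl, noise_sd = 0.002, seed = 22))
#> <moleratio_result> tangents intersect at metal/ligand ratio 0.9972
#>   n_hat (ligand per metal) = 1.0028, split after point 6, SSE = 3.03e-05
```

All three agree: apex at mole fraction 0.5 and break at ratio 1 are the
signatures of a 1:1 complex. `compare_methods()` repeats such matched runs
across a grid of formation constants to quantify how the tangent-based
methods lose accuracy for weak complexes while the exchange estimator does
not (see the methods vignette for the computed table and its
interpretation).

A thin command-line interface wraps the same functions
(`inst/cli/ligex simulate --preset paper_exchange --noise-sd 0.002 --seed 1 ...`);
series travel as `x,absorbance` CSV files with a JSON metadata sidecar, and
every report is a pure function of configuration and seed.

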