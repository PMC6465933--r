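# idpbiophys

Quantitative biophysics of intrinsically disordered proteins (IDPs) and
their complexes with folded domains, in R. The package grew out of the
characterization of the C-terminal region of L-periaxin (PRX-C, an
extended ~348-residue disordered chain implicated in the demyelinating
neuropathy CMT4F) bound 1:1 with micromolar affinity to the third
fibronectin-III domain of β4-integrin, and it implements that study's
analysis chain as reusable, tested components:

* **Polymer scaling theory** — random-chain reference dimensions
  `Rg = R0·N^ν` (denatured: R0 = 1.98 Å, ν = 0.602; IDP: R0 = 2.54 Å,
  ν = 0.522) and `⟨L²⟩ = L0·N` (L0 = 81.8 Å) as a theoretical Dmax
  proxy, plus the Rg/Rh compactness ratio.
* **Conformer generators** — freely jointed and self-avoiding Cα-bead
  chains (pivot-equilibrated), uniform-ball globule mimics for folded
  domains, tethered chain–domain complexes; CA-only PDB I/O.
* **SAXS analysis** — exact Debye-sum forward scattering (Rcpp),
  Guinier fits, the Debye-formalism (Calmettes) coil estimator
  `Rg = (a/0.359b)^0.453` from the `1/I` vs `s^2.206` plot,
  dimensionless Kratky transforms, and direct pair-distance
  distributions P(r).
* **Ensemble optimization** — genetic-algorithm selection of conformer
  sub-ensembles whose average curve fits a target, reporting selected vs
  pool Rg/Dmax distributions.
* **One-site ITC** — titration simulation under the overfilled-cell
  displacement model and Levenberg–Marquardt recovery of (n, Kd, ΔH),
  with ΔG/ΔS derivation.
* **Thermal melts** — two-state van't Hoff melt simulation (fine
  fluorescence-ratio and coarse CD-style grids) and Tm extraction from
  the Savitzky–Golay first-derivative peak.
* **Mass bookkeeping** — sequence masses, additive complex masses, and
  the "% of expected" statistic for mass/size report tables.

Raw instrument data for such studies are typically not deposited, so
every analysis is paired with a seeded synthetic-data generator and the
estimators are validated by generator/fitter round trips and
property-based tests.

## Worked example

```r
library(idpbiophys)

## theoretical dimensions of a 348-residue disordered chain
predict_chain_dimensions(348, "idp")
#> Theoretical chain dimensions (N = 348, model 'idp'):
#>   Rg          =   53.9 Å = 5.39 nm
#>   sqrt(<L^2>) =  168.7 Å = 16.9 nm

## one-site ITC: simulate the study geometry, then refit
p <- titration_protocol()          # 680 µM into 350 µl of 68 µM, 38 × 1 µl
heats <- simulate_titration(p, one_site_params(1, 1.7e-6, -6.2))
fit <- fit_one_site(heats, p, init = one_site_params(0.7, 5e-6, -3))
fit
#> One-site fit: n = 1.000 (±3.59e-15), Kd = 1.7e-06 M (±9.8e-20), dH = -6.200 kcal/mol (±3.1e-14)
#>   Wiseman c = 40
derived_thermo(fit$params)
#> dG = -7.87 kcal/mol, dS = 5.60 cal/(mol K) at 298.15 K

## melting temperature from a synthetic fluorescence-ratio melt
melt <- simulate_melt(melt_model(69.8), seq(20, 95, by = 0.1))
tm_from_derivative(melt)
#> Tm = 69.80 °C (derivative_peak, window 11 points)
```

The noise-free round trip recovers the generating truth exactly: a
dissociation constant of 1.7 µM at stoichiometry 1.00 with |ΔH| =
6.2 kcal/mol (Wiseman c = 40, inside the reliable 1–1000 window), and
the derivative-peak method returns the planted 69.8 °C midpoint. A
mass/size summary table joins measured and theoretical values per
species:

```r
build_report(list(
  species_summary("PRX-C",   41.00, 35.87, rg_guinier_nm = 5.68,
                  rg_theory_nm = round(angstrom_to_nm(predict_rg(348, "idp")), 2)),
  species_summary("Complex", 48.27, complex_theoretical_mass(c(35.87, 12.76)))))
#>   species measured_kda theoretical_kda percent_of_expected ...
#> 1   PRX-C        41.00           35.87                 114
#> 2 Complex        48.27           48.63                  99
```

## Documentation

The methods vignette (`vignettes/idp-complex-biophysics.Rmd`) documents
the models, their assumptions, the numerical choices (window policies,
iteration caps, smoothing), what the synthetic generators do and do not
emulate, and known limitations.
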