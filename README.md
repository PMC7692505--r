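# hemopore

Pore-structure and protein-fouling analysis for hemoconcentration
(hollow-fibre ultrafiltration) membranes.

Hemoconcentrators remove excess water from blood during cardiopulmonary
bypass. Their usefulness hinges on nanometre-scale pore structure: pores must
be large enough for high pure water permeability (L<sub>p</sub>) but the
surface must foul gracefully so that albumin is retained and the device never
fails mid-surgery. `hemopore` is for membrane scientists and biomedical
engineers who characterise such membranes from two independent directions and
need them to agree:

* **Transport**: the *tortuous pore diffusion (TPD) model* infers an
  equivalent pore radius from measured permeability. Treating the wall
  (thickness Δx, water content H, tortuosity τ) as a bundle of tortuous
  cylindrical pores in Hagen–Poiseuille flow:

  L<sub>P</sub> = r<sub>P</sub>² H / (8 μ τ² Δx)  ⇔  r<sub>P</sub> = √(8 μ τ² Δx · L<sub>P</sub> / H)

  with solute permeability P<sub>m</sub> = D<sub>O</sub> f(q) S<sub>D</sub> A<sub>K</sub> / (τ Δx),
  surface porosity A<sub>K</sub> = H/τ, steric factor S<sub>D</sub> = (1−q)²
  and the Verniory wall-friction factor f(q).
* **Imaging**: a scanning-probe-microscopy (SPM) pipeline — plane flattening,
  robust height-threshold segmentation, Feret-diameter "line analysis",
  ellipse-area-equivalent diameters √(major·minor), and pore-size
  distributions.
* **Fouling**: before/after blood-contact comparison — permeability
  retention, per-condition TPD diameters, paired t-tests, albumin sieving
  coefficient SC = 2C<sub>F</sub>/(C<sub>B,in</sub>+C<sub>B,out</sub>).
* **Synthetic truth**: a seeded generator of realistic rough surfaces with
  elliptical nanopores and a protein-adsorption fouling transform, so the
  whole measurement pipeline is validated by parameter recovery.

See `vignettes/hemopore-methods.Rmd` for the full model description,
assumptions and numerical conventions.

## Worked example

Reference parameters for two commercial polyethersulfone hemoconcentration
membranes (PUREMA A and B) ship with the package. A full fouling comparison
from their permeability record:

```r
library(hemopore)
pm <- purema_membranes()
st <- purema_study()
fouling_report(pm[["PUREMA A"]], st[["PUREMA A"]]$lp, sc = 0.01)
#> Fouling comparison: PUREMA A
#>        condition n lp_mean lp_sd retention tpd_diameter_nm
#>           before 1     207    NA     1.000            30.5
#>  after_high_load 1     180    NA     0.870            28.5
#>   after_low_load 1     194    NA     0.937            29.6
#> t-test skipped for: after_high_load, after_low_load (summary means only; replicate vectors required)
#> Albumin sieving coefficient: 0.01
```

Reading: blood contact under high filtration load cost 13% of the pure water
permeability, which the TPD model reads as a shrink of the equivalent pore
diameter from 30.5 to 28.5 nm (diameter ratios track √retention exactly);
albumin is almost fully retained (SC = 0.01). t-tests appear automatically
when replicate vectors rather than means are supplied.

The imaging pipeline, validated against synthetic ground truth:

```r
s <- synthetic_spec(seed = 1)        # 512 px, 2000 nm field, 15 pores
g <- generate_surface(s)
pa <- analyze_topography(g$topography)
pa
#> Pore analysis of synthetic scan (2000 x 2000 nm): 15 pore(s), 0 at the border
#>   interior pores: major 29.5 +/- 9.8 nm, minor 18.4 +/- 3.0 nm
rm <- recovery_metrics(g$truth, pa$measurements, s$pixel_size_nm)
rm$precision; rm$recall; rm$major_bias_rel
#> [1] 1
#> [1] 1
#> [1] 0.01920223
```

All 15 planted pores are found with no false detections and a 1.9% mean
major-axis bias. `apply_fouling()` occludes a seeded fraction of pores with a
protein-layer transform; at full coverage the pipeline stops detecting them,
emulating the post-blood-contact scans.

A command-line wrapper is installed as `exec/hemopore`:

```sh
hemopore tpd diameter --lp 207 --water-content 0.79
hemopore spm synth --seed 4 --out grid.csv --truth truth.csv
hemopore spm analyze grid.csv --out pores.csv --hist hist.csv
hemopore study compare --config study.json --out report.json
```

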