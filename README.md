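# rhizosim

Single-root exudation gradients in depth-dependent peat soil.

`rhizosim` simulates the radial accumulation gradient of root exudates
(sugars, amino acids, organic acids) around a cylindrical root segment
in saturated peat, and how it changes with soil depth. It is built for
rhizosphere and peatland-carbon researchers who want to explore how
vertical gradients in peat properties — compaction, porosity,
tortuosity, temperature, microbial biomass — regulate net exudation and
the size of the rhizosphere, and hence the labile carbon reaching the
anoxic zone.

## The model

A Barber–Cushman-style single-root representation: the root (radius
r0, constant internal concentration) is wrapped in 500 concentric soil
annuli of 0.2 mm. Each 1 s step couples

* **efflux** — passive permeation `E = A P (Ccyto − Csoil)` for
  uncharged solutes, or a Goldman-type flux
  `A P u (Ccyto e^u − Csoil)/(e^u − 1)`, `u = Z Em F / (R T)`, for
  charged organic acids (which have no influx pathway);
* **influx** — Michaelis–Menten recapture
  `I = Imax Csoil / (KI + Csoil)`;
* **radial diffusion** — Fick's law with effective diffusivity
  `De = D∞ ε / (τ² R)`, where porosity ε, Archie tortuosity τ = ε^−m,
  and the Langmuir retardation factor R all derive from depth-dependent
  peat laws;
* **sorption** — an explicit solid-phase pool in instantaneous Langmuir
  equilibrium, `S(C) = Smax Ks C / (1 + Ks C)`;
* **mineralization** — first-order removal at `kd · f_mb(d) · f_T(d)`,
  with an exponential microbial-biomass depth modifier and a Q10
  temperature factor.

Runs iterate to equilibrium (relative change per step < 1e-7) and
report the rhizoplane concentration, rhizosphere extent at the
0.01 nmol cm⁻³ threshold, gross efflux/influx, net exudation, recapture
efficiency, and pool budgets. A Sobol-sequence sensitivity design and
partial rank correlation coefficients (PRCC) summarise which parameters
control the outputs. See `vignettes/exudation-model.Rmd` for the full
model account.

## Worked example

Calibrate the glucose fixture to its three published 10 cm equilibrium
anchors (gross efflux 2.07320 and influx 1.431 nmol cm⁻¹ hr⁻¹,
rhizosphere extent 7.16 mm), then sweep depth with the identical
solute:

```r
library(rhizosim)

cal <- calibrate_glucose()     # resolves r0, Imax, kd from the anchors
sw  <- depth_sweep(cal$solute, depths = seq(10, 80, 10), root = cal$root)
sw[, c("depth", "rhizoplane_C", "extent_mm", "influx", "net_exudation")]
#>   depth rhizoplane_C extent_mm influx net_exudation
#> 1    10        5.930     7.160  1.431        0.6419
#> 2    20        6.254     8.187  1.505        0.5679
#> 3    30        6.504     9.200  1.562        0.5110
#> 4    40        6.715    10.272  1.609        0.4634
#> 5    50        6.897    11.438  1.651        0.4223
#> 6    60        7.058    12.710  1.687        0.3862
#> 7    70        7.201    14.111  1.719        0.3541
#> 8    80        7.329    15.656  1.747        0.3254
```

Reading the table: between 10 and 80 cm the rhizoplane concentration
rises by a factor ~1.24 and the rhizosphere more than doubles
(7.2 → 15.7 mm), because deeper peat diffuses, sorbs and — above all —
mineralizes exudates more slowly. The accumulated exudate feeds back on
the root: influx (recapture) climbs from 1.431 to 1.747 nmol cm⁻¹ hr⁻¹
while gross efflux is essentially unchanged, halving net exudation
(0.642 → 0.325 nmol cm⁻¹ hr⁻¹). Extent is nearly linear in depth
(R² ≈ 0.99). `autoplot()` methods draw the radial profiles, depth
responses and PRCC rankings; `tidy()`/`glance()` return tibbles.

A thin command-line front-end wraps the same functions:

```sh
exec/rhizosim profile --depths 1:100 --out profile.csv
exec/rhizosim sweep-depth --solute glucose --depths 10,20,40,80 --out glc
exec/rhizosim sensitivity --n 1000 --out sens
```

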