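# pttherm

Thermal kinetics analysis for infrared thermography of plasmonic
photothermal therapy (PTT).

In nanoparticle-assisted PTT, a near-infrared laser heats a tumor loaded
with gold nanorods while a thermographic camera records the skin surface.
`pttherm` turns such recordings into the quantities that characterize a
treatment: it extracts a hotspot region-of-interest (ROI) temperature trace
from the thermograph stack, fits the step response of a first-order thermal
system

    T(t) = (T0 − T∞) · exp(−t/τ) + T∞

to estimate the thermal time constant τ (with 95% CI, R², RMSE), and
derives per-group treatment metrics:

- **Tmax** and **ΔT = Tmax − T(0)** per animal and group;
- **effective temperature enhancement** T̃enh = 100·(Tᵢ − T_PBS,ᵢ)/T_PBS,ᵢ,
  the percent excess of the nanorod arm's group-mean Tmax over the saline
  control at the same wavelength;
- **heating efficiency** HE = ΔT_GNR / ΔT_saline;
- **normalized heating curves** T̃ = (T − Tmin)/(Tmax − Tmin);
- two-tailed pooled-variance **Student t-tests** comparing arms on Tmax and τ.

A synthetic thermograph generator reproduces the eight-group study design
(808/940/975/1064 nm × {GNR, saline}, n = 4/group, 6 frames/s, 90 s
exposure) with a realistic camera noise model, so the entire pipeline is
testable without raw thermal video. See the vignette
(`vignettes/thermal-kinetics.Rmd`) for the model, parameter defaults and
design choices.

## Worked example

```r
library(pttherm)

report <- run_thermal_pipeline(run_config(seed = 1), outdir = NULL)
report
#> <run_report> 32 animals, 8 groups, 8 t-tests, 0 warning(s)
#> enhancement metrics:
#>   wavelength t_gnr t_pbs dt_gnr dt_saline  t_enh    he
#> 1        808 69.88 53.57  40.51     23.94 30.450 1.692
#> 2        940 67.63 63.55  38.20     32.21  6.427 1.186
#> 3        975 84.17 81.31  55.14     52.51  3.514 1.050
#> 4       1064 71.38 56.53  43.63     27.01 26.286 1.615
```

One simulated cohort at the default parameters: the 808 nm and 1064 nm
arms show a large nanorod benefit (enhancement ≈ 30% and 26%, heating
efficiency ≈ 1.7 and 1.6), while at 940/975 nm the intrinsic tissue
absorption already heats the controls, leaving little headroom
(enhancement < 10%). The t-test table shows the same contrast:

```r
report$tests[report$tests$comparison == "tmax", ]
#>   wavelength comparison t_stat df  p_value significant
#> 1        808       tmax 11.114  6 3.16e-05        TRUE
#> 3        940       tmax  2.620  6 3.96e-02        TRUE
#> 5        975       tmax  0.713  6 5.03e-01       FALSE
#> 7       1064       tmax  9.108  6 9.84e-05        TRUE
```

Working from thermograph stacks instead of traces:

```r
st  <- read_stack("recording.tif")        # float32 °C, or uint16 + JSON sidecar
roi <- locate_roi(st, diameter = 30)      # hotspot circle, 30 px
tr  <- roi_trace(st, roi)                 # per-frame ROI mean ± SD
fit <- fit_first_order(tr, exposure_s = 90)
fit$tau_hat; fit$ci95["tau", ]
```

A thin CLI wraps the same functions
(`inst/cli/pttherm.R simulate|extract|fit|run-all`); an example
configuration is at `inst/extdata/run_default.yaml`.

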