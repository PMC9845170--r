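# ebossflux

Flying-insect biomass density from bistatic optical sensor signals.

Entomological bistatic optical sensors (eBoss-type instruments) monitor a
long, expanded laser beam with a photodetector. A flying insect crossing
the beam leaves a Gaussian-like dip in the recorded voltage, overlaid
with sharp periodic amplitude drops at its wingbeat frequency; passive
targets (leaves, pollen) leave the dip without the periodicity. From the
dip depth the insect's **body extinction cross section** follows under
the flat-top beam approximation,

    sigma_B = sigma_pv * (I0 - IB) / I0          [mm^2]

its **mass** from the power-law calibration

    m = eta * sigma_B^(3/2)                       [mg]
    (eta_wet = 0.157, eta_dry = 0.075 mg/mm^3)

and the **volumetric biomass density** over a window t_tot from the
transit-time-weighted sum

    rho_b = sum_n (dt_n / t_tot) * m_n / dV       [mg/m^3]

where dV is the probed air volume (0.1466 m^3 for the reference 72 mm x
36 m beam). `ebossflux` implements this chain for ecologists and
instrument developers: band-pass filtering and adaptive sliding-threshold
detection, harmonic-series insect classification and wingbeat estimation,
extinction photometry (baseline, body minimum, transit time, kurtosis),
Levenberg–Marquardt mass calibration, and density aggregation (daily
series, rolling averages, diel profiles). A synthetic session generator
with ground-truth ledgers makes every stage testable without instrument
data.

## Worked example

Simulate a 32 s session containing three insects and one passive target,
then run the full chain:

```r
library(ebossflux)

led <- rbind(
  event_truth(5.00, 0.12, 0.050, 136, 0.040),
  event_truth(12.0, 0.30, 0.020, 250, 0.015),
  event_truth(20.0, 0.06, 0.080, 450, 0.060),
  event_truth(26.0, 0.40, 0.010, 0, 0, kind = "non_insect"))
ses <- simulate_session(32, truths = led, seed = 42)

res <- run_pipeline(ses$record)
res
#> <pipeline_result> 171 regions -> 3 insect events -> 3 after cut-off
#>   density: 1 bins of 60 s, mean rho_b = 14.41 mg/m^3

subset(res$events, is_insect,
       c(transit_time_s, sigma_b_mm2, wingbeat_hz, kurtosis, mass_dry_mg))
#>    transit_time_s sigma_b_mm2 wingbeat_hz kurtosis mass_dry_mg
#> 2           0.220         205         136     3.06       219.4
#> 28          0.552          82         250     3.62        55.7
#> 56          0.109         324         450     2.84       438.4
```

Reading the output: 171 regions crossed the adaptive threshold (mostly
noise), the harmonic test kept exactly the three true insects and
rejected the passive target. Measured cross sections (205, 82,
324 mm^2) recover the simulated body extinctions (5%, 2% and 8% of the
4071.5 mm^2 beam = 203.6, 81.4 and 325.7 mm^2) within about 1%; the
wingbeat fundamentals are exact; kurtosis near 3 reflects the Gaussian
transit shape. Transit times are the full width at 10% of peak, 1.823x
the simulated FWHM. Masses follow the dry-basis power law, and the
single 60 s density bin sums their transit-weighted contributions.

Event summaries apply the field analysis' hard 10 ms transit cut-off:

```r
summarize_events(res$events)
#> <event_summary> 171 events, 3 insect, 3 after 10 ms cut-off
#>   dry mass         mean 237.8 mg | median 219.4 mg
#>   transit time     mean 0.2937 s | median 0.2203 s
#>   wingbeat         mean 278.7 Hz | median 250 Hz
#>   kurtosis         mean 3.172  | median 3.059
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/ebossflux simulate --duration 600 --rate 0.05 \
    --seed 42 --out session.ebs --truth truth.csv
Rscript inst/scripts/ebossflux run-all --input session.ebs --outdir results/
```

See `vignettes/ebossflux-methods.Rmd` for the model, the tunable
parameters and the design decisions.

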