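# capnovol

Per-breath volumetric capnography for small-animal ventilation studies:
from synchronized airflow and sidestream CO2 signals to capnogram shape
factors and dead-space fractions, with a fully synthetic recording
generator so every estimator is testable against known ground truth.

## The problem and who it is for

Comparing ventilation strategies — for example positive-pressure
ventilation (PPV) against negative-pressure "iron-lung"-style ventilation
(NPV) at matched tidal volumes — requires quantifying how well ventilation
matches perfusion. Volumetric capnography does this non-invasively from
two signals a rodent physiology rig already records: tracheal airflow
(pneumotachograph) and expired CO2 (sidestream capnometer). The catch is
that the raw signals need careful handling — capnometer transport delay,
flow integration and drift, breath segmentation, and a capnogram
reconstruction robust to the mode-dependent expiratory flow pattern —
before the physiology-bearing indices can be read off. `capnovol`
implements that chain for R users in respiratory physiology labs.

## The quantities at its core

For each expiration, CO2 partial pressure is remapped onto cumulative
expired volume. From that curve:

- **S2V** — slope at the phase-2 inflection (mmHg/ml); **Sn2V** = S2V/ETCO2.
- **S3V** — ordinary least squares slope over the middle third of the
  alveolar plateau (phase 3); **Sn3V** = S3V/ETCO2.
- **ETCO2** — mean CO2 over the final 5% of expired volume.
- **VDF** (Fowler) — volume expired up to the phase-2 inflection minus
  instrumental dead space; anatomical dead space.
- **VDB/VT** (Bohr) — `(PACO2 − PĒCO2)/PACO2`, with PACO2 the phase-3
  midpoint value and PĒCO2 = ∫PCO2 dV / VT.
- **VDE/VT** (Enghoff) — `(PaCO2 − PĒCO2)/PaCO2` from the arterial blood
  gas; includes intrapulmonary shunt.
- **Shunt indices** — `VDE/VT − VDB/VT` and the arterial–alveolar gradient
  `PaCO2 − PACO2`.
- **VCO2** — expired CO2 volume per breath, `∫ PCO2/(Pbar − 47) dV`.

A paired-scenario driver (`run_pipeline()`) simulates subjects ventilated
with both modes across end-expiratory pressure levels and summarizes
NPV − PPV contrasts with a percentile bootstrap over subjects.

## Worked example

Synthesize a 20-breath PPV recording of a healthy ~300 g rat (tidal
volume 3 ml, airway dead space 0.6 ml, plateau 40 mmHg with slope
2 mmHg/ml, 3 mmHg arterial–alveolar shunt offset) through a sidestream
sensor with a 0.58 s transport delay and measurement noise; correct the
delay and analyze:

```r
library(capnovol)

params <- expirogram_params()        # the rat above
sensor <- sensor_model(transport_delay = 0.58, smoothing_tau = 0,
                       pco2_noise_sd = 0.5, flow_noise_sd = 0.02)
rec <- synthesize_recording(params, flow_pattern("PPV"), sensor,
                            n_breaths = 20, seed = 42)

ser <- apply_delay_correction(rec$series, rec$series$meta$transport_delay)
res <- analyze_recording(ser)
round(res$summary, 4)
#>        s2v        s3v       sn2v       sn3v      etco2        vdf   vdf_frac
#>   100.0872     2.1979     2.3909     0.0525    41.8566     0.5930     0.1978
#>   vdb_frac   vde_frac  paco2_alv     pe_co2         vt       vco2   pa_a_co2
#>     0.2137     0.2654    40.2353    31.6344     2.9973     0.1330     2.8282
#> shunt_frac  v_inflect
#>     0.0517     0.5930
```

Reading the output against the generator's ground truth
(`rec$truth$oracle`): the breath-averaged phase-3 slope 2.20 mmHg/ml
recovers the clean-profile value 2.00 within its 10% noise tolerance;
Fowler dead space 0.593 ml matches the oracle 0.602 ml (the true airway
dead space is 0.6 ml, so VDF/VT ≈ 0.20 of the 3 ml breath); the Bohr
fraction 0.214 sits on the oracle 0.210; and the recovered
arterial–alveolar gradient 2.83 mmHg reflects the injected 3 mmHg shunt
offset. ETCO2 ≈ 41.9 mmHg and PĒCO2 ≈ 31.6 mmHg are the end-tidal and
mixed-expired pressures the dead-space formulas consume. With the
realistic sensor smoothing enabled (`smoothing_tau = 0.05`) the
early-phase indices (S2V, VDF) shift substantially — the known sidestream
bias in small animals — while phase-3 and Bohr/Enghoff quantities remain
stable.

A whole simulated study, written to disk with condition summaries,
paired NPV − PPV differences, and a reproducibility log:

```r
res <- run_pipeline(NULL, out_dir = "capnovol_run")   # defaults: 9 subjects,
names(res)                                            # 2 modes x 4 EEP levels
#> [1] "per_breath" "recording_summary" "condition_summary"
#> [4] "paired_differences" "config" "errors"
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/capnovol.R` (subcommands `simulate`, `analyze`, `run`).

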