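# pfnavector

Analysis and simulation of **invertible vector coding by PFNa neurons** in the
*Drosophila* central complex, for computational neuroscientists studying
population phasor codes.

PFNa neurons receive the fly's allocentric heading (H) in the protocerebral
bridge and the egocentric airflow direction (W) in the noduli. Each bridge
half's population expresses a sinusoidal activity profile — a *phasor* whose
amplitude is vector length and whose spatial phase is vector angle. The phasor
is *invertible*: depolarized cells fire sodium spikes and the population bump
aligns with the EPG heading bump; hyperpolarized cells fire
T-type-channel-mediated 2–6 Hz calcium spikes and the bump sits ~180° away,
negating the encoded vector. The core model is:

* membrane potential: `Vm = a0 + aH·cos(H) + aW·cos(W ± 45°)`
  (+ for left-bridge, − for right-bridge cells)
* sodium-spike rate: `r = [bH·cos(H) + bW·cos(W ± 45°)]₊²`
* 2–6 Hz oscillation power: `p = c0 + [cH·cos(H) + cW·cos(W ± 45°)]₋²`

Summing the combined (unrectified quadratic) outputs of a matched left/right
pair after their ±45° anatomical shifts into the fan-shaped body collapses, by
trigonometric identity, to

```
bH² + bW² + 2·bH·bW·cos(W + H)
```

— a function of `W + H` alone, the airflow direction in **allocentric**
coordinates. The package's decoder reads this out from phase-nulled bridge
profiles, scaling phase-inverted (calcium-spike) components by a conversion
factor κ = 0.2 before the vector sum.

## What the package provides

* **`simulate_experiment()`** — a full in-silico experiment: pseudorandomized
  12-direction air-puff protocol (30° steps, 4 s pulses, 5 s intervals),
  closed-loop heading behavior, 10 kHz Vm traces with sodium spikes and
  hyperpolarization-gated oscillations, and sector-resolved imaging matrices
  (18 bridge glomeruli, 16 ellipsoid-body wedges, 2 noduli).
* **Electrophysiology**: `condition_vm()` (1 kHz + 40 ms median filter),
  `detect_sodium_spikes()` (150–1000 Hz band, 6.66 ms refractory rule),
  `spike_rate()` (1 s Hann kernel), `band_power_2_6()` (4 s / 20 ms
  spectrogram), `pulse_conditioned_power()`, `baseline_vm()`.
* **Imaging**: `normalize_sectors()` (ΔF/F, range, z-score),
  `epg_phase_bridge()` (period-8 Fourier phase), `pva_phase()`,
  `phase_null()` (cubic-spline, 1/10-glomerulus resolution),
  `phase_offset_stats()`.
* **Tuning**: `heading_tuning()` (10° bins, 2 s occupancy, 0.5 mm/s gate),
  `airflow_tuning()`, `conjunctive_map()` (18×12 = 216 cells, 0.5 s rule),
  `preferred_heading()`, `pool_cells()`.
* **Model fitting**: `fit_vm()`, `fit_rate()`, `fit_osc()`,
  `fit_quadratic_io()`, with broom-style `tidy()`/`glance()`.
* **Decoding**: `pair_output()`, `closed_form_output()`,
  `decode_allocentric()`, `decode_protocol()`.
* **Orchestration**: `run_pipeline()` with YAML configs
  (`read_run_config()`), deterministic under one seed, CSV/JSON artifacts.

## Worked example

```r
library(pfnavector)

ds <- simulate_experiment(n_blocks = 3, seed = 1, n_ephys_cells = 0)
dec <- decode_protocol(ds)          # matched kappa = 0.2
dplyr::select(dec, airflow_direction, decoded_rel_deg, inverted_left, inverted_right)
#> # A tibble: 12 × 4
#>    airflow_direction decoded_rel_deg inverted_left inverted_right
#>                <dbl>           <dbl> <lgl>         <lgl>
#>  1              -150       -141.     TRUE          TRUE
#>  2              -120       -134.     FALSE         TRUE
#>  3               -90       -107.     FALSE         TRUE
#>  4               -60        -54.4    FALSE         TRUE
#>  5               -30        -43.5    FALSE         FALSE
#>  6                 0          0.0706 FALSE         FALSE
#>  7                30         43.7    FALSE         FALSE
#>  8                60         54.6    TRUE          FALSE
#>  9                90        107.     TRUE          FALSE
#> 10               120        134.     TRUE          FALSE
#> 11               150        141.     TRUE          TRUE
#> 12               180       -180.     TRUE          TRUE
decode_error_summary(dec)
#> [1] 11.24057
```

Reading the table: front puffs leave both bridge populations aligned with the
heading bump; rear puffs invert both; side puffs invert exactly the
contralateral population — and the decoded egocentric direction tracks the
true puff direction with a median circular error of ~11°. Setting
`decoder_config(kappa = 0)` (no calcium-spike read-out) collapses all rear
and side decodes into the frontal ±45–55° sector, the behavior expected when
only sodium-spike phasors reach the downstream population.

`plot_decode(dec)`, `plot_nulled_profiles()`, and `autoplot()` on tuning
curves, conjunctive maps and quadratic fits produce the standard figures.

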