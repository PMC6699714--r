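# cilialoss

Classification of primary cilium loss events from live-cell length
trajectories.

Most animal cells disassemble their primary cilium before dividing.
Live imaging of a ciliary membrane marker (e.g. SSTR3::GFP in IMCD3
cells) turns each cilium into a length-versus-time trajectory sampled
every 30–90 s for up to 12 h, and each terminal loss event is one of
three dynamic behaviours:

* **Gradual** — continuous resorption to zero (rates ~10⁻²–10⁻¹ µm/min);
* **Instant** — whole-cilium shedding within one imaging frame
  (minimum rates of µm/min and above);
* **Combined** — a gradual phase ending in a single-frame loss.

`cilialoss` is for researchers quantifying organelle disassembly
kinetics from such traces. It implements the full analysis chain:

1. **Calibration** (`estimate_baseline`): from non-disassembling control
   cilia, the mean background slope of length vs. time (≈ −0.005 µm/min)
   and the per-cilium SD of consecutive length differences
   (≈ 1.53 µm = σ√2 for per-measurement noise σ), which proxies
   measurement error and sets the *instant threshold*.
2. **Event detection** (`analyze_trajectory`): the completion point is
   the first observed zero length that never recovers (T_final); the
   event start is found by scanning backwards from it until the length
   derivative is no different in magnitude from the control slope
   (|d| ≤ |mean slope|, with optional kernel smoothing of the pre-drop
   derivatives and an optional noise band).
3. **Classification**: with T_start the detected start, T_final−1 the
   penultimate frame and L_final−1 its observed length,

   | rule | class |
   |---|---|
   | T_start < T_final−1 and L_final−1 > threshold | Combined |
   | T_start = T_final−1 and L_final−1 > threshold | Instant |
   | T_start < T_final−1 and L_final−1 ≤ threshold | Gradual |

   with the degenerate fourth cell assigned Gradual and flagged.
4. **Metrics and cohort statistics**: per-phase rates (the instant rate
   is a lower bound: lost length over one frame), phase fractions of
   maximum length, curves normalized to 1,000 time units and unit
   maximum length, class frequencies and the instant-terminal fraction,
   hourly event-timing histograms, and normality-gated two-sample
   comparisons (Shapiro–Wilk, Kolmogorov–Smirnov, D'Agostino–Pearson at
   α = 0.05 gating unpaired t vs. Mann–Whitney U).
5. **Synthetic cohorts** (`simulate_cohort`): labelled trajectories with
   the stated measurement structure (90-s frames, Gaussian measurement
   noise, −0.005 µm/min drift, asynchronous onsets peaking at 1–3 h,
   class-specific kinetics) so every stage is testable by parameter
   recovery without any external data.

## Worked example

Simulate a 69-event cohort at the reference composition (11 gradual,
32 instant, 26 combined, plus 10 controls) with 0.3 µm measurement
noise, then analyse it:

```r
library(cilialoss)

cfg <- default_config()
cfg$sim$n_control <- 10; cfg$sim$n_gradual <- 11
cfg$sim$n_instant <- 32; cfg$sim$n_combined <- 26
cfg$sim$noise_sd <- 0.3

cmd_simulate("demo_cohort", config = cfg, seed = 42)
#> simulated 79 trajectories (69 events) into demo_cohort
res <- cmd_analyze("demo_cohort", "demo_out", config = cfg)
#> classified 69 events (0 censored) into demo_out

res$baseline
#> <control_baseline> mean slope -0.004974 um/min, diff SD 0.433 um
#>   (max 0.4625), instant threshold 0.433 um, n = 10

fr <- class_frequencies(res$events)
sprintf("instant-terminal: %.1f%% of %d events", 100 * fr$instant_terminal, fr$n)
#> "instant-terminal: 88.4% of 69 events"

rate_statistics(res$events)$summary
#>                    group  n   mean     sd
#> 1           gradual_only  8 0.0543 0.0514
#> 2           instant_only  1 3.3517     NA
#> 3 combined_gradual_phase 60 0.0242 0.0860
#> 4 combined_instant_phase 60 2.6913 1.0490
```

Reading the output: the calibrated baseline recovers the generating
drift (−0.005 µm/min) and noise dispersion (0.3·√2 ≈ 0.42 µm, which
becomes the instant threshold). The instant-terminal fraction lands near
the generating 84% — a few points high because gradual events whose
noisy penultimate length exceeds the threshold are promoted, an effect
inherent to the classification rule at this noise level. At σ = 0.3 µm
most individual Instant events are labelled Combined (their flat
pre-drop phase is noise-dominated, so the detected start precedes the
drop), which is why `instant_only` is nearly empty while the terminal
split — the statistic the analysis rests on — is stable; the noiseless
limit classifies all three classes exactly (see the vignette and test
suite). `demo_out/` also contains the per-event table (`events.csv`),
the cohort summary (`summary.json`), timing histogram and rate tables,
plots, and a run record.

A command-line wrapper with the same subcommands ships at
`inst/cli/cilialoss`:

```sh
Rscript inst/cli/cilialoss simulate --out demo_cohort --seed 42
Rscript inst/cli/cilialoss analyze --data demo_cohort --out demo_out
Rscript inst/cli/cilialoss summarize --events a/events.csv b/events.csv --out cmp
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's recovery quantities from
scratch: it simulates cohorts at the reported operating point (class
mixes 11/32/26 and 1/25/24 at σ = 0.3 µm; 26-event combined cohorts
with instant fraction 0.726; 10-control calibration cohorts at
σ = 1.082 µm and drift −0.005 µm/min; 32-event instant cohorts with
penultimate lengths ~ N(5.82, 1) µm), runs the simulate→analyze
pipeline, and writes the recovered instant-terminal fractions, combined
instant share, baseline dispersion and slope, and mean minimum instant
rate as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run takes about half a minute.
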