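# pupildyn

Analysis toolkit for the dynamics of the mouse pupillary light response
(PLR). The PLR has two phases — a **transient** constriction within 30 s of
light onset and a **sustained** steady state reached after about an hour —
and the two phases have different photoreceptor and neurotransmitter inputs.
`pupildyn` implements the computational half of dissecting them:

- **Baseline normalization** — pupil area during the stimulus divided by
  the dark-baseline area gives the relative pupil area (RPA; 1 = fully
  open); the transient endpoint is the minimum RPA at 5 s or 30 s.
- **Intensity-response fitting** — the constrained variable-slope sigmoid

  ```
  RPA(I) = bottom + (top − bottom) / (1 + 10^((log10 EC50 − log10 I) · h))
  ```

  with top fixed at 1.0 and bottom in [0, 0.10] (released automatically
  for weak constrictors), and EC50 statistics on the log scale (EC50 is
  log-normally distributed across animals).
- **Kinetics** — one-phase association/decay
  `Y(t) = Plateau + (Y0 − Plateau)·e^(−K t)` (half-life = ln 2 / K), a
  signed bi-exponential for non-monotone traces, and a sigmoidal model of
  the sustained decay rate versus intensity constrained to the rates
  measured at 1 and 100 lux.
- **Negative-feedback simulation** — pupil constriction attenuates retinal
  illuminance (`retinal lux = RPA × environmental lux`). A per-second
  packet recursion with a pulse-chase temporal weighting ω (peak
  constriction 6 s after a 1-s pulse) and a zero-summation rule (the pupil
  adopts the single deepest constriction on offer, never a sum) gives an
  upper bound on how much of the PLR decay feedback alone can explain.
- **Contribution heat maps** — model-generated time × intensity pupil
  matrices per genotype (one-phase association cells), from which
  `necessity = RPA_KO − RPA_WT`, `sufficiency = 1 − RPA_only`, and
  `contribution = max(necessity, sufficiency)` are computed cellwise and
  composed into RGB images (rod red, cone green, melanopsin blue).
- **Synthetic data** — a seeded, genotype-parameterized trace generator
  (wild type plus eight mutant lines) so the full pipeline is testable
  end to end without animal data.

## Worked example

Generate a wild-type cohort (6 mice × 8 intensities, noise SD 0.03), fit
each mouse's transient intensity-response curve, and summarize EC50 on the
log scale:

```r
library(pupildyn)
lib <- default_genotype_library()

co <- generate_cohort(lib$wildtype, intensities = 10^seq(-2, 5),
                      n_per_genotype = 6, base_seed = 20)
fits <- lapply(split(co, co$mouse_id), function(d)
  fit_intensity_response(d$intensity_lux, d$transient_rpa))
fits[[1]]
#> Variable-slope intensity-response fit
#>   top        1
#>  bottom     0.05606  (constrained to [0, 0.10])
#>  log10 EC50 -0.2233  (EC50 = 0.598 lux)
#>  Hill slope -1.056
#>  RSS 0.00196 over n = 8 points

s <- group_ec50_summary(fits)
sprintf("Transient EC50 (geometric mean, n = %d): %.2f lux", s$n, s$geo_mean_ec50)
#> "Transient EC50 (geometric mean, n = 6): 0.55 lux"
```

The geometric-mean EC50 (0.55 lux here) recovers the generator's default
transient EC50 of 0.53 lux. Kinetics of the same genotype at 1000 lux:

```r
tr <- generate_trace(lib$wildtype, 1000, duration = 30, dt = 0.1, noise_sd = 0)
fit_one_phase(relative_trace(tr))
#> One-phase exponential fit
#>   y0 1, plateau 0.0505, k 0.6301 /s (half-life 1.1 s)
```

How much PLR decay could the pupil's own negative feedback produce at
10 lux?

```r
om  <- omega_from_pulse_chase(generate_pulse_chase(lib$wildtype, noise_sd = 0))
sim <- simulate_feedback(fits[[1]], om, env_lux = 10)
sim
#> Negative-feedback simulation at 10 lux over 956 s
#>   open-loop plateau 0.102, min rpa 0.102, end rpa 0.2357
#>   feedback-driven decay magnitude 0.1337
```

So even under the feedback-maximizing zero-summation assumption, feedback
relaxes the pupil by only ~0.13 RPA units at 10 lux — an upper bound on
its contribution to PLR decay.

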