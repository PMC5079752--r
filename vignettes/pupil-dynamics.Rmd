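---
title: "Modelling transient and sustained pupil dynamics with pupildyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transient and sustained pupil dynamics with pupildyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupildyn)
```

## The measurement model

The pupillary light response (PLR) is quantified as **relative pupil area**
(RPA): pupil area during stimulation divided by the dark-baseline area, so
1 means fully open and smaller values mean constriction. `relative_trace()`
uses the *mean* area over all pre-onset samples as the baseline. When a
recording has a single dark frame this reduces to dividing by that frame;
with several frames the mean damps frame-to-frame measurement noise, which
otherwise propagates multiplicatively into every RPA value of the trace.

The PLR has two phases. The **transient** endpoint is the minimum RPA at
either 5 s or 30 s after onset (`transient_endpoint()`); taking the
minimum accommodates genotypes that are still constricting at 5 s and
genotypes whose constriction has already begun to decay by 30 s. Because
video frame times are irregular, the 5-s and 30-s samples are matched by
nearest neighbour within ±0.5 s. The **sustained** endpoint is the RPA
after 60 min of continuous light.

## Intensity-response curves and EC50

`fit_intensity_response()` fits the variable-slope logistic in log10 dose,

$$\mathrm{RPA}(I) = b + \frac{\mathrm{top} - b}
 {1 + 10^{(\log_{10}EC_{50} - \log_{10} I)\,h}},$$

with the top fixed at 1.0 (a dark-adapted pupil is fully open by
definition of RPA) and the bottom $b$ constrained to $[0, 0.10]$, so that
EC50 values are comparable across genotypes that constrict to similar
floors. Genotypes that never approach a 0.10 floor would have their EC50
distorted by the constraint; if the constrained bottom pins at 0.10 while
the data never fall below it, the fit is automatically redone with the
bottom free in $[0, 1]$ (`auto_fallback`), and the returned object records
which regime applied. Zero-lux samples cannot enter a log-dose model and
are excluded from fitting; they serve only as baseline checks.

Numerically the fit is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) started from a data-driven heuristic (the
log-intensity where the response crosses halfway between its extremes,
Hill slope −1) plus a small multistart over Hill slopes {−0.5, −1, −2} and
midpoints; the best residual sum of squares wins, and iteration stops
early when a start reproduces the data to machine precision. The Hill
slope is free in sign; constriction data yield negative slopes. The box
bounds keep $\log_{10}EC_{50}$ within 3 decades of the sampled range —
outside that range the data cannot localize a midpoint and the fit error
asks for better intensity coverage rather than returning an arbitrary
number.

EC50 is log-normally distributed across animals, so `group_ec50_summary()`
averages $\log_{10}EC_{50}$ and reports the geometric mean
$10^{\overline{\log_{10}EC_{50}}}$. Per-genotype curves default to
per-mouse fits aggregated on the log scale; pooling all mice into one fit
is possible by concatenating their endpoint tables, but the log-scale
per-mouse route is what the EC50 statistics use.

## Constriction and decay kinetics

`fit_one_phase()` fits the one-phase association/decay

$$Y(t) = \mathrm{Plateau} + (Y_0 - \mathrm{Plateau})\,e^{-K (t - t_0)},$$

with $Y = Y_0$ before the onset offset $t_0$. The offset (default 0)
exists for responses that lag light onset — a melanopsin-only response is
conventionally fitted with $t_0 = 3$ s. Half-life is $\ln 2 / K$ and
carries the time unit of $1/K$: transient constriction rates are per
second (half-lives of order 1 s), sustained decay rates per minute
(half-lives of order minutes). A constant trace has no identifiable rate
and raises a degenerate-fit error; a rate pinned at the box bound is
flagged on the returned object rather than silently reported.

`fit_two_phase()` fits the signed bi-exponential
$Y(t) = \mathrm{Plateau} + A_1 e^{-K_1 t} + A_2 e^{-K_2 t}$. The spans are
deliberately unconstrained in sign so the model can express constriction
followed by re-dilation within the recording window, which is how a
cone-only response behaves. Because the one-phase model is nested inside
the two-phase model, the extra phase is accepted only if it improves the
RSS by more than a relative tolerance (1%, `rel_tol`); otherwise the
one-phase fit is returned flagged `reduced_from_two_phase`, which keeps
noiseless one-phase inputs from acquiring spurious second phases.

The sustained decay rate changes with intensity.
`fit_decay_rate_vs_intensity()` passes a sigmoid in log10 lux through
rates measured at 1, 10 and 100 lux, with top and bottom *fixed* to the
1-lux and 100-lux rates; only the midpoint and slope are fitted (to the
10-lux rate). With two free parameters and effectively one informative
point the curve is weakly identified between the plateaus — that is
acceptable because evaluation is only ever needed across the measured
decade and is **clamped** outside 1–100 lux to the respective plateau
rate. Clamping rather than extrapolating mirrors the constrained
top/bottom: there is no evidence about decay rates outside the measured
range, so the nearest measured rate is used.

## The negative-feedback model

Pupil constriction reduces retinal illuminance
($\mathrm{lux}_{ret} = \mathrm{RPA} \times \mathrm{lux}_{env}$), which
reduces the drive to constrict — a negative feedback that could, in
principle, explain the decay of the PLR under constant light. The model
bounds that contribution from above.

Light is discretized into 1-s packets. Two measured ingredients enter:

1. the wild-type intensity-response curve $\alpha(\mathrm{lux})$, giving
   the constriction driven by an illuminance from a fully open start, and
2. the temporal weighting $\omega(\ell)$, $\ell = 0..30$ s: the
   constriction profile after a 1-s pulse to a dark-adapted eye,
   normalized to its maximum (empirically at the 6-s lag), with negative
   constriction clipped to zero before normalizing
   (`omega_from_pulse_chase()`).

The recursion (`simulate_feedback()`): the packet arriving at second $s$
carries constriction depth $d_s = 1 - \alpha(\mathrm{lux}_s)$ and offers
depth $d_s\,\omega(t - s)$ at later seconds $t$. Retinal illuminance at
$t$ is the environmental level attenuated by the *deepest* offer from any
earlier packet, and the reported pupil size at $t$ is
$1 - \max_{s \le t} d_s\,\omega(t-s)$. Taking the maximum rather than any
sum is the **zero-summation assumption**: packets do not add, so the
pupil is always as constricted as the single strongest packet demands.
This deliberately overstates feedback (each packet acts as if alone at
full strength), which is what makes the simulated decay an upper bound.

One modelling decision deserves a note. Read literally, a formulation
that weights an RPA *value* by $\omega$ and takes a maximum over stored
RPA values would make small weights imply deep constriction. The package
instead weights constriction *depth* ($1 - \mathrm{RPA}$) and modulates
intensity by the most-constricted (minimum-RPA) state — the reading under
which "maximum constriction" sets the new retinal intensity and the model
is genuinely feedback-maximizing. The recursion is implemented directly
in $O(\mathrm{horizon} \times L)$ time; the packet-by-time matrix view is
available for inspection via `feedback_packet_matrix()`, whose column
minima reproduce the simulated trace exactly.

Defaults: a 956-s horizon and, for `feedback_intensity_sweep()`, the
nine-step intensity ladder $10^{-4}..10^{4}$ lux. A wider ladder (up to
$10^5$ lux) can be passed explicitly; the sweep also refits EC50 to the
early minimum and to the horizon-end pupil size, and the end-of-horizon
EC50 is never below the early one — feedback can only make the system
look less sensitive over time. The module is fully deterministic.

## Heat-map matrices and contribution maps

Time × intensity pupil matrices are model-generated, not interpolated
from raw traces. The transient matrix uses the one-phase association with
$Y_0 = 1$ at every intensity, a single rapid rate $K_{rapid}$ (extracted
from rapid constriction kinetics at 100 lux), and the transient
intensity-response fit as the plateau at each intensity. The sustained
matrix starts at 30 s from the transient plateau ($Y_0^{sust} =
\mathrm{Plateau}^{rapid}$ at each intensity) and relaxes toward the
sustained plateau at the intensity-dependent decay rate. The 30-s column
of the sustained matrix therefore equals the transient plateau exactly,
and differs from the transient matrix's 30-s row by at most
$e^{-30 K_{rapid}}$.

Default grids: time in 1-s steps over 0–30 s (transient) and 5-s steps
over 30 s–3600 s (sustained); intensity in 0.25 log10 steps over
0.001–100,000 lux. All are configurable.

Component attribution, cellwise on these matrices:

- **necessity** $= \mathrm{RPA}_{KO} - \mathrm{RPA}_{WT}$ (wild-type
  constriction minus knockout constriction). The subtraction is oriented
  so that more-required components score higher; it also normalizes
  against the wild-type response, so a component that is fully necessary
  at an intensity where wild type barely constricts receives a small
  value. Replicate knockout lines for the same component are pooled with
  `average_matrices()` before subtraction.
- **sufficiency** $= 1 - \mathrm{RPA}_{only}$, the absolute constriction
  of the corresponding "-only" line. It is not renormalized to wild type;
  sufficiency answers "how much constriction can this component drive
  alone", which is an absolute quantity.
- **contribution** $= \max(\mathrm{necessity}, \mathrm{sufficiency})$.
  For the neurotransmitter panel no "-only" lines exist, so contribution
  is necessity alone (`contribution_map(n)`), flagged on the object.

Negative differences and values above 1 are clamped to $[0, 1]$: a
knockout that constricts *more* than wild type somewhere carries no
evidence that the component drives constriction there.

Cone-driven constriction is not maintained, so the cone-only matrix gets
a decay adjustment (`apply_cone_decay_adjustment()`): after each
intensity row's constriction minimum, the depth is multiplied by
$e^{-K_{cone}(t - t_{min})}$ with the single rate taken from the
cone-only transient response at 100 lux, applied at every intensity. The
multiplicative-relaxation form was chosen over replacing the row's rate
constant because it leaves the pre-minimum time course untouched, reduces
to the unadjusted matrix as the rate goes to 0, and can never push a cell
below the row's unadjusted minimum. Since a pure one-phase row is
monotone (its minimum sits at the window edge), the relaxation start can
also be set explicitly via `t_start`.

RGB composites assign one component per channel (rod red, cone green,
melanopsin blue; glutamate green and PACAP blue in the neurotransmitter
panel), channel value $\mathrm{round}(255 \times \mathrm{contribution})$,
unassigned channels 0 — black means no contribution. No per-channel
rescaling is applied, so channel intensities are comparable across
panels.

## The synthetic-data generator

Animal traces are not redistributable, so the generator stands in for
them with the statistical structure the analyses assume: one-phase
association to an intensity-dependent transient plateau, a decay from
30 s onward toward an intensity-dependent sustained plateau at an
intensity-dependent rate, additive Gaussian noise on RPA, and a
pulse-chase profile peaking 6 s after a 1-s pulse. The 30-s start of the
sustained decay matches the heat-map model's phase boundary.

Wild-type defaults are anchored to measured values: transient EC50
0.53 lux with a 1.1-s constriction half-life; sustained EC50 7.9 lux with
decay half-lives of 2 min at 1 lux and 5 min at 100 lux (slower decay
under brighter light). The ipRGC-glutamate knockout's transient half-life
is 4.8 s and the ipRGC-PACAP knockout's 1.1 s. The remaining genotypes
are encoded qualitatively from their phenotypes — rod knockout: ~2-decade
transient sensitivity loss; cone knockout: wild-type-like; melanopsin
knockout: wild-type transient but no sustained constriction, lost with a
~4-min half-life; cone-only: insensitive, re-dilating within 30 s
(multiplicative re-dilation at 0.08 /s); melanopsin-only: slow
constriction (5-s half-life) with a 3-s onset delay; glutamate-knockout
sustained dynamics pulsatile, approximated by sinusoidal modulation of
constriction depth (amplitude 0.15, period 300 s) — an illustrative
stand-in, since no quantitative description of the pulsatility exists.
These qualitative parameter choices are the package's own and are not
measured values.

Noise is additive Gaussian on RPA with SD 0.03 by default — no noise
model is published, and 0.03 produces scatter comparable to the reported
standard deviations — with generated RPA floored at 0.02 (a pupil is
never measured at zero area). All randomness flows from one user seed
through a deterministic per-mouse counter stream, so identical seeds give
bit-identical datasets. `generate_cohort()` evaluates the same response
model at the protocol time points (three baseline samples, 5 s and 30 s
for the transient protocol; 3600 s for the sustained one) and pushes them
through the real extraction path (`relative_trace()`,
`transient_endpoint()`).

What passing recovery tests show — and what they do not. The test suite
demonstrates that the estimators are unbiased and precise *under the
generator's assumptions*: exact one-phase kinetics, a true logistic
dose-response, homoscedastic Gaussian noise, no within-mouse correlation
across intensities, no blinks, drift or tracking artifacts. Real
pupillometry violates several of these (irregular frame times, occasional
occlusion, mouse-to-mouse parameter variation), so recovery percentages
here are best-case statements about the code, not about any animal
dataset.

## Problem sizes and numerical choices

The recovery studies in the test suite use 6 mice × 8 log-spaced
intensities ($10^{-2}..10^{5}$ lux) with noise SD 0.03; 100 replicates
for single-curve EC50 recovery, 50 for the full endpoint-to-EC50
pipeline, and 200 noisy traces (1 Hz, 30 s) for kinetic recovery — sizes
chosen to estimate medians and 95%-rates stably while keeping the default
test run fast. The feedback oracle comparison runs a 60-s horizon over
the nine-step ladder, where the brute-force nested-loop reference is
cheap and agreement is required to $10^{-12}$.

All fitters stop early on machine-precision residuals and otherwise take
the best of their multistarts; ties in `which.min`/`which.max`
(tie-breaks in endpoint matching, argmin of a matrix row) resolve to the
earliest index, R's convention. Degenerate inputs fail loudly: constant
traces, missing baselines, non-positive areas, fewer than four distinct
intensities, rates at bounds.

## Limitations

- The feedback model is an upper bound by construction; it is not fitted
  to data and has no free parameters beyond its two measured inputs.
- Heat-map matrices inherit every simplification of the one-phase model:
  a single rapid rate across intensities and no transient overshoot.
- The generator's mutant parameterizations are qualitative; analyses that
  depend on a mutant's exact EC50 or rate should treat those defaults as
  placeholders and supply their own `genotype_spec()`.
- Group hypothesis testing (ANOVA, post-tests) is out of scope; the
  package stops at descriptive log-scale summaries of EC50.
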