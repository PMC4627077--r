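---
title: "Modeling EF-Tu dynamics during PRE complex formation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling EF-Tu dynamics during PRE complex formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The kinetic scheme and its assumptions

`tufret` models ternary complex (TC = aa-tRNA·EF-Tu·GTP) interaction with
the 70S initiation complex (70SIC) as a small branched mass-action network:

* **Binding, lumped.** Initial codon-independent association and
  codon-recognition/GTP-hydrolysis are not resolved by stopped-flow data,
  so the conversion of free ribosome + TC to Complex B is treated as a
  single reversible step with rate constants `k12` (s⁻¹μM⁻¹) and `k_m12`
  (s⁻¹). Complex A is deliberately not a model species.
* **Step 3 grouped.** P\_i release, tRNA accommodation and EF-Tu–L11
  separation proceed nearly simultaneously and are represented by the
  single irreversible rate `k3` forming Complex C. Dipeptide formation is
  assumed fast after accommodation and is not a separate step.
* **The branch point (full mode).** From Complex C, EF-Tu can leave
  irreversibly as EF-Tu·GDP (`k4`, concomitant with its large GTP→GDP
  conformational change) or reversibly as the metastable, GTP-like
  EF-Tu·GDP\* (`k4A` out, `k_m4A` back). In *collapsed* mode the branch is
  absent and `k4` is the single exit: this is the parameterization under
  which global-fit constants are reported, because ensemble data cannot fix
  the position of the 4A equilibrium (Complex C is assumed dominant, making
  the fitted `k4` a lower limit).
* **EF-G capture.** When `k_efg > 0`, EF-G·GTP converts the PRE complex to
  POST at the pseudo-first-order rate `k_efg · [EF-G]`; POST cannot rebind
  EF-Tu·GDP\*. EF-G is treated as a constant, catalytic concentration — it
  is present in large excess over ribosomes in the experiments emulated and
  it does not participate in either conservation relation.
* **Phosphate sensing.** The C-PBP reporter is premixed in excess with a
  phosphate mop, so P\_i binding is treated as instantaneous and
  stoichiometric: cumulative P\_i equals the accommodated pool
  `C + PRE + POST` exactly, because each (irreversible) Step-3 transition
  releases one P\_i.
* **EF-Tu·GDP\* relaxation.** Solution conversion of GDP\* to GDP is off by
  default (`k_conv = 0`); the species only needs to persist transiently.
  The parameter exists for exploration.

Units are fixed package-wide (s, μM); `temperature_scale` multiplies every
rate constant uniformly, and 0.5 is used to emulate 21 °C single-molecule
conditions relative to the 25 °C ensemble reference, consistent with the
roughly two-fold longer single-molecule occupancy lifetimes.

No independent estimates of `k4A` and `k_m4A` exist; only the inequality
`k4A ≥ k4` and a Complex-C lifetime bound of ≲10–20 ms constrain them. The
package's single-molecule defaults therefore set `k4A = k4` (the smallest
value compatible with the inequality) and default `k_m4A` to `k12` when a
full-mode network is built without one — a message flags this whenever it
happens. Both are assumptions, not measurements.

## Observables

Each reporter channel is an affine map `F(t) = F0 + a · pool(t)`:

* `L11_Cy3`: quench while EF-Tu sits against the GTPase-associated center —
  Complex B only. The trace dips and recovers (biphasic, fit with the
  double exponential).
* `tRNA_Cy3`: donor and quencher ride inside the TC, so free TC, Complex B
  and Complex C are all FRET-quenched; fluorescence recovers only when
  EF-Tu separates completely from the tRNA. The rising signal is therefore
  proportional to `PRE + POST`. (A map quenching only B and C would make
  this channel biphasic, which is not what the experiment shows — the
  channel rises monotonically and is fit with a single exponential.)
* `prf` and `PBP`: both proportional to the accommodated pool
  `C + PRE + POST` (decreasing and increasing respectively); they are
  identical up to an affine transform, which is enforced by construction
  and tested.

Because the accommodated pool obeys `d(C+PRE+POST)/dt = k3·B`, its
trajectory — and hence the apparent accommodation rate `k'_acc` — is
rigorously independent of everything downstream of Step 3. This is why
EF-G leaves `k'_acc` untouched while pulling the EF-Tu:tRNA separation rate
`k'_tRNA` up toward it: saturating capture of PRE makes the 4A branch
effectively irreversible, draining Complex C.

## Fitting machinery

**Exponential fits.** Amplitudes enter linearly, so they are profiled out
by ordinary least squares at every candidate rate (variable projection);
only the rates are optimized, from a deterministic log-spaced multi-start.
The biexponential is optimized in the reparameterization
`k1 = m·r, k2 = m/r, r = 1 + exp(w)` (geometric mean and separation),
which enforces the `k1app ≥ k2app` labeling convention by construction and
stays smooth as the two rates coalesce; fits with rates within 5% are
flagged degenerate rather than reported silently.

**Global fit.** All traces share one set of rate constants; every trace
keeps its own baseline and amplitude, solved linearly per iteration. The
free rates are optimized on the log scale with a Levenberg–Marquardt
trust-region solver (`minpack.lm::nls.lm`), box-bounded to
[1e-4, 1e5] in natural units, from ≥8 deterministic log-spaced starts
(objective evaluated at all, the best three refined, with early exit once
the objective falls below 1e-12 of the total signal energy — reached
routinely on noiseless self-generated data). No randomness: repeated fits
are bit-identical.

Before fitting, the residual sensitivity to each free log-rate is measured
by finite differences (10% perturbations, far above solver noise, rtol
1e-8). A parameter with zero sensitivity in every trace — for example `k4`
when only accommodation-pool channels are present — is refused with a
diagnostic; a nearly collinear combination produces a warning that
confidence intervals will be wide. Freeing `k12`/`k_m12` without a
binding-sensitive (L11) channel also warns: the series-2 style fit is
numerically identifiable but only weakly, which is why its association
constant carries a large uncertainty. Confidence intervals, when wanted,
come from a seeded parametric bootstrap (`global_fit_ci()`); the choice of
a bootstrap is the package's own, as the original ± values do not state
their method.

**Numerical integration.** `deSolve::lsoda` with rtol 1e-8 / atol 1e-12,
dense output on the requested grid. Ribosome and EF-Tu conservation hold to
better than 1e-6 μM on all tested inputs, and the deterministic solution
agrees with an independent matrix-exponential solution of the linearized
chain to <1e-6 μM in the pseudo-first-order limit.

## The single-molecule simulator

Each immobilized ribosome is an exact continuous-time Markov chain. TC
arrival is pseudo-first-order (`k12·[TC]`, with [TC] = 5–10 nM); the bound
phase is the two-stage chain `B → C → off`, with exit rate `k4 + k4A`
(at nanomolar concentrations rebinding of dissociated EF-Tu·GDP\* is
negligible, so both exit branches are effectively irreversible). The mean
bound time is therefore `1/k3 + 1/(k4 + k4A)`, which at the 21 °C-scaled
series-2 constants with `k4A = k4` gives 151.5 ms — inside the observed
150–160 ms band.

Two deliberate modeling choices deserve emphasis:

* **Committed entry.** Complex B lies after GTP hydrolysis, so reversing
  the lumped binding step cannot regenerate an intact TC; at camera
  resolution the rapid pre-hydrolysis sampling events are invisible. The
  simulator therefore treats entry into B as committed by default.
  `committed = FALSE` restores the `B → empty` branch at `k_m12` and makes
  the stochastic model the exact counterpart of the ensemble ODE network,
  which is how the Gillespie-versus-ODE consistency checks are run.
* **Recycling.** After EF-Tu departs, the default (`recycle = TRUE`) lets
  the site accept a new TC, so one trace holds repeated binding events —
  an idealization that multiplies event statistics without changing dwell
  times. EF-G capture acts on the EF-Tu-free PRE state *between* events,
  so simulated dwell times are invariant to EF-G by construction, matching
  the experimental observation.

**Rendering.** Bound frames emit `I_Cy5 = E·I_tot`, `I_Cy3 = (1−E)·I_tot`
(defaults: E = 0.90 for the EF-Tu:L11 pair, 0.69 for the intra-TC pair;
I\_tot = 1000 counts/frame), unbound frames emit 0; a frame containing a
jump gets the time-weighted mixture of the two levels, and i.i.d. Gaussian
noise (default σ = 50 counts) is added per channel. The FRET ratio
`I_Cy5/(I_Cy5+I_Cy3)` is scale-invariant, so partially occupied boundary
frames still read the true efficiency. Recording starts 5 s before the
injection that defines t = 0; frames are 11 ms and 0-indexed, events are
half-open frame intervals. Photobleaching and blinking are *not* modeled
(the emulated experiments suppress them chemically), and frame noise is
additive Gaussian rather than shot noise — both are known departures from
raw camera data.

**Detection.** A frame is in-event when its total intensity reaches 50% of
the bound-state reference; runs of ≥2 frames form events and FRET is
reported as 0 elsewhere. The reference is estimated per trace as the
median total intensity above a two-class isodata split (iterated midpoint
of class means), which is robust to the small bound fraction of a typical
trace; a separation test (class means closer than three pooled standard
deviations) declares all-background traces event-free. The estimator is
the package's own choice — the 50% rule's reference is not otherwise
specified — and can be overridden with a known intensity.

**Dwell fitting.** Durations shorter than two frames are censored (events
that short are unreliably detected; the censoring is the package's
resolution of an unstated choice). A single exponential `A·exp(−t/τ)` is
fit to the empirical survival curve, with each point weighted by the
number of events still at risk there — the natural precision weighting,
since a survival value at time t is an average over that many events. On
exponential dwells the estimator is unbiased; on the two-stage chain, whose
dwell distribution is hypoexponential, the weighting keeps the fitted τ
within a few percent of the true mean occupancy, whereas an unweighted fit
is dragged ~12% low by the sparse far tail. `k_dissoc = 1/τ` by
definition.

**Density plots and synchronized averages.** Probability density maps
histogram the below-threshold-zeroed FRET series of every trace, aligned at
the first (or last) time point of its FRET events, normalized per time
column. Synchronized averages align per-event FRET series at the event
start (pre) or end (post) and extend each series with its last (first)
in-event value so all events span the longest extent before averaging —
the hand-computable two-event fixtures in the test suite pin this down
exactly.

## The synthetic-data module and what passing tests mean

`gen_ensemble_dataset()` regenerates multi-channel stopped-flow experiments
from generating constants: by default the series-1 constants (k12 = 36
s⁻¹μM⁻¹, Kd 0.10 μM, k3 = 15.4 s⁻¹, k4 = 19.6 s⁻¹) over the TC grid
0.2–1.2 μM at 0.1 μM 70SIC, or the series-2 constants (k12 = 100, Kd 1.2,
k3 = 19.9, k4 = 19.6) over a 70SIC grid at 0.1 μM TC. Ensemble noise
defaults to 1.5% of each trace's dynamic range (realistic for averaged
stopped-flow traces; the emulated studies do not report their noise
levels). The default output grid samples densely (0.5 ms) out to 50 ms and
progressively coarser to 2 s, mimicking logarithmic instrument sampling. No
mixing dead time is applied: generator and fitter share one clock, so a
constant offset would cancel in every recovery study; real instruments lose
the first millisecond or two.

`gen_smfret_dataset()` regenerates the single-molecule experiments: 60 s
recordings at 11 ms/frame, 10 nM TC injected at t = 0 after 5 s of
baseline, series-2 constants halved with `k4A = k4`. Everything is
deterministic given the config seed (R's default Mersenne-Twister;
per-molecule seeds are drawn once from the config stream), and every
manifest carries the complete ground truth, so recovery tests never
hard-code expected values.

Parameter recovery on these synthetic data shows that the estimation
machinery is correct and well-conditioned under the stated model — it
cannot show that the model is right for any particular real dataset, nor
that detection survives photophysics (bleaching, blinking, spectral
crosstalk) that the generator does not emulate.

## Problem sizes and numerical conventions

The shipped test-suite and benchmark sizes are chosen to give comfortable
statistical margins on a single CPU: global-fit recoveries use 10–18 traces
of ~400 points; stochastic checks use 2 000–4 000 molecules (≳5 000
events) against 3-standard-error bands; the mean-FRET benchmark uses ~800
events where ±0.01 corresponds to many standard errors. Tie-breaks and
degenerate inputs are handled explicitly: biexponential label switching by
the `k1 ≥ k2` convention, coalescing rates and flat traces by degeneracy
flags, all-identical dwell durations by a flagged degenerate fit, and
all-background traces by empty (not erroneous) event tables.

## Known limitations

* Codon-recognition substeps, GTPase activation and GDPNP-type analogue
  intermediates are out of scope, as are mRNA sequence effects.
* The full-model branch rates are assumptions pinned only by an inequality;
  fits in full mode say so loudly.
* No Bayesian inference or model selection; the scheme is fixed.
* The smFRET analyzer starts from extracted intensity traces — no image
  processing, spot finding or drift correction — and does not use HMMs:
  the emulated data show a single FRET state, so thresholding suffices.
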