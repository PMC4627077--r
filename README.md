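# tufret

Kinetic analysis of EF-Tu dynamics during pretranslocation (PRE) complex
formation on the bacterial ribosome.

During each elongation cycle, EF-Tu delivers aminoacyl-tRNA to the 70S
initiation complex (70SIC) as part of a ternary complex (TC =
aa-tRNA·EF-Tu·GTP). Binding is followed by codon recognition, GTP
hydrolysis, P\_i release, tRNA accommodation into the A site, and finally
EF-Tu·GDP departure, producing the PRE complex. `tufret` implements the
branched mass-action scheme used to describe this process quantitatively,
together with the complete analysis toolchain for the two kinds of
experiments that constrain it: multi-channel stopped-flow fluorescence
(ensemble) and camera-frame Cy3/Cy5 single-molecule FRET (smFRET) of TC
binding to surface-immobilized ribosomes.

## The model

Species: free 70SIC (R), free TC (T), Complex B (codon-recognized,
GTP-hydrolyzed), Complex C (accommodated, with the metastable EF-Tu·GDP\*
still bound), the EF-Tu-free PRE complex, and free EF-Tu species.

```
R + T  <=>[k12 / k-12]  B  -->[k3]  C  -->[k4]   PRE + EF-Tu·GDP     (collapsed)
                                    C  <=>[k4A / k-4A] PRE + EF-Tu·GDP*   (full)
                               PRE + EF-G·GTP -->[kefg] POST
```

Initial binding and codon recognition/GTP hydrolysis are lumped into the
single reversible k12/k−12 step (stopped-flow data do not resolve them);
step 3 groups the nearly simultaneous P\_i release, accommodation, and
EF-Tu–L11 separation. In the full model, Complex C is a branch point:
EF-Tu·GDP\* can leave reversibly (k4A/k−4A) before the large GTP→GDP
conformational change, or EF-Tu·GDP leaves irreversibly (k4) with it.
Units package-wide: time s, concentration μM, bimolecular rates s⁻¹μM⁻¹.

Four fluorescence observables are projected from the species trajectories:

| channel    | reporter                        | depends on    |
|------------|---------------------------------|---------------|
| `L11_Cy3`  | Cy3-L11 quenched by label on EF-Tu | B (biphasic dip/recovery) |
| `tRNA_Cy3` | Cy3-tRNA quenched inside the TC | PRE + POST (rise on EF-Tu departure) |
| `prf`      | proflavin on P-site tRNA        | C + PRE + POST (accommodation) |
| `PBP`      | coumarin-PBP phosphate sensor   | C + PRE + POST (cumulative P_i) |

Apparent rates come from mono-/biexponential fits
(`F = F0 + F1·e^(−k1app·t) + F2·e^(−k2app·t)`, with
`k_ov = k1app·k2app/(k1app+k2app)`), concentration dependences from linear
and Michaelis–Menten fits, and the microscopic constants from a global
multi-trace variable-projection fit (`global_fit()`). The smFRET side
simulates per-molecule continuous-time Markov trajectories
(`simulate_molecule()`), renders them as noisy camera frames
(`render_trace()`), and analyzes traces exactly as in practice:
50%-threshold event detection, dwell-time survival fits, postsynchronized
FRET probability density plots, and synchronized average traces.

## Worked example

Recover the microscopic rate constants of the quencher-EF-Tu / Cy3-L11
reaction series from a synthetically regenerated experiment (three
channels, six TC concentrations, 1.5% noise):

```r
library(tufret)

cfg <- ensemble_config(seed = 7, rates = reference_rates(1),
                       channels = c("L11_Cy3", "prf", "PBP"),
                       conc_70SIC = 0.1,
                       conc_TC = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2))
ds  <- gen_ensemble_dataset(cfg)
fit <- global_fit(ds, free = c("k12", "k_m12", "k3"), fixed = c(k4 = 19.6))
fit
#> <global_fit> collapsed mode | 18 traces, 7128 points | objective 0.04668
#>   free: k12, k_m12, k3
#>   fixed: k4 = 19.6
#>   k12    = 35.768
#>   k_m12  = 3.5282
#>   k3     = 15.494
#>   Kd(B)  = 0.09864 uM
```

The generating constants were k12 = 36 s⁻¹μM⁻¹, k−12 = 3.6 s⁻¹
(Kd 0.10 μM), k3 = 15.4 s⁻¹: all are recovered within ~1% despite the
noise, with k4 held fixed as in the reported fit. `tidy(fit)` and
`glance(fit)` give broom-style summaries; `autoplot()` methods draw
traces, trajectories, density plots, and dwell fits.

The single-molecule side, end to end (simulate → render → detect → fit):

```r
sm     <- smfret_config(seed = 7, n_molecules = 40)   # 10 nM TC, 21 °C, E = 0.90
events <- pooled_events(gen_smfret_dataset(sm, collect = "events"))
fit_dwell_distribution(events)
#> <dwell_fit> t_dissoc = 0.1404 s (k_dissoc = 7.125 s^-1), n = 1057 events (censored below 0.022 s)
mean_event_fret(events)
#> [1] 0.902
```

The fitted occupancy lifetime sits within 10% of the analytic mean
`1/k3' + 1/(k4' + k4A')` = 0.1515 s of the branched exit at the halved
(21 °C) rates, and the mean event FRET reproduces the generating 0.90
efficiency to 0.01.

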