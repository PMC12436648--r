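# smtrack

Single-molecule analysis of protein recruitment to individual mRNAs in
living cells — and a ground-truthed simulator of the experiments that
produce such data.

## The problem

To understand how the ribosome-quality-control ligase ZNF598 finds
collided ribosomes, recent live-cell experiments tether reporter mRNAs
to the plasma membrane, image them by TIRF microscopy together with a
HaloTag-labeled protein and a SunTag translation-site channel, and ask:
what fraction of mRNAs ever recruit the protein, how long does a single
binder stay, how many binders are present, and how fast do ribosomes
clear the message after translation initiation is blocked? Answering
those questions takes a pipeline: spot detection with sub-pixel
Gaussian fitting, particle tracking, two-channel track colocalization,
change-point segmentation of binding traces, Kaplan–Meier survival
analysis of ribosome-runoff clearance times, and smFISH-IF
nascent-peptide counting. `smtrack` implements that pipeline in R, for
researchers analyzing such movies and for anyone who wants estimators
for frame-sampled dwell times with known-answer validation.

## The core quantities

* **Engagement fraction** — per cell, the fraction of mRNAs with at
  least one colocalization event (≥ 5 consecutive frames within 1.5 px
  at 2-s frames; ≥ 2 frames for runoff/UV assays).
* **Residence time** — for a binder sampled every Δt seconds, the run
  length of bound frames is geometric with ratio q = exp(−Δt/τ). The
  package inverts this (and, in the `markov` policy, the full sampled
  two-state chain, which also corrects unbind/rebind events hidden
  between frames) to recover the true mean on-time τ; the naive mean
  of detected durations is biased upward by the missed sub-frame
  episodes.
* **Stoichiometry** — bound-spot intensity divided by the mean
  single-binder (1× binding site) intensity.
* **Clearance time** — time from the translation-site maximum to the
  first frame below 10 % of it; cohort curves are Kaplan–Meier
  estimates with Greenwood variance,
  Var(S) = S² Σ dᵢ/(nᵢ(nᵢ−dᵢ)).
* **NAP count** — translation-site intensity normalized by the same
  cell's mean single-protein intensity in fixed-cell smFISH-IF stacks.

Every stage is validated against a synthetic generator
(`simulate_binding_cohort()`, `simulate_runoff_cohort()`,
`render_movie()`, `simulate_smfish_field()`) whose defaults encode the
published study conditions, so the pipeline's numbers are
parameter-recovery checks with exact ground truth.

## Worked example

```r
library(smtrack)

## a 300-mRNA cohort with one binding site per mRNA, 2-s frames, 5 min
co  <- simulate_binding_cohort(preset_kinetic("pbs_1x"),
                               n_mrna = 300, seed = 42)

## dwell times through change-point segmentation
seg <- segment_binding_cohort(co, min_bound_s = 0)
rts <- residence_time_stats(seg$segments, co$dt_s, policy = "markov",
                            total_frames = seg$total_frames,
                            n_traces = seg$n_traces)
rts$mean_s
#> [1] 3.74      # true mean on-time: 3.6 s, n = 1719 bound runs

## engagement fraction through the colocalization rules
ana <- analyze_binding_cohort(co, link_rules("steady_state"), seed = 42)
ana$grand_mean_frac
#> [1] 0.53      # preset engagement probability: 0.5
```

The first number is the mean residence time of single binders
recovered from the noisy traces (the generator drew exponential
on-times with mean 3.6 s); the second is the fraction of mRNAs showing
a qualifying colocalization, which recovers the preset's engagement
probability of 0.5.

A YAML-driven end-to-end run (any of the modes `steady_state`,
`runoff`, `smfish`, `simulate`) writes the standard CSV contracts
(`tracks.csv`, `linked.csv`, `cells.csv`, `segments.csv`,
`clearance.csv`, `survival.csv`, `tls.csv`, ...) plus a `run_info.json`
with the resolved configuration and its hash:

```sh
Rscript inst/scripts/smtrack.R run --config my_run.yaml
```

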