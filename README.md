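# nicodyn

Craving dynamics and driver-node analysis for intranasal nicotine
microdosing experiments.

## What this is for

In MRI-compatible nicotine self-administration experiments, an abstinent
smoker receives small nebulized doses ("puffs", 0.1 mg nicotine each, ten
puffs to a cigarette) on a fixed interval or on request, while reporting
craving continuously on a Likert scale and, in imaging sessions, while a
23-region reward-circuit BOLD series is recorded. Two questions follow from
such a session:

1. **How does craving respond to dosing?** Under rapid fixed-interval
   dosing craving relaxes as

   `craving(t) = A + B · exp(−(t − t₀)/τ)`

   and, because blood nicotine rises linearly (a fixed increment `c_inc`
   per puff, one puff per ITI), craving is also exponential in
   concentration with decay constant `c₀ = c_inc · τ / ITI`:

   `craving(c) = A + B · exp(−c / c₀)`.

2. **Where would neuromodulation act?** Sliding 38-TR windows of the
   ROI series are summarised by nodal connectivity strength (row sums of the
   windowed Pearson correlation matrix), windows are clustered into
   *brain-connectivity states* by their strength profiles, each state's
   Fisher-averaged connectivity is binarized at 0.65, and every **minimum
   dominating set** of each state graph is enumerated exactly. Nodes that
   belong to minimum dominating sets in *every* state are common drivers;
   ranked by the average fraction of regions they control, the top two are
   the proposed neuromodulation targets.

The package implements both analyses end to end, plus a synthetic-data
generator that plants multi-state correlation structure with a designated
hub region, so the whole pipeline is testable without any recording.

## Worked example

```r
library(nicodyn)

## craving model under the 2-minute protocol
sched <- generate_puff_schedule(iti = 120, n_puffs = 20, baseline_length = 300)
trace <- generate_craving_trace(sched, A = 4.2, B = 3.2, tau = 310,
                                noise_sd = 0.3, seed = 1)
fit <- fit_craving_model(trace, t0 = 300)
fit <- attr(decay_concentration(fit, sched, pk_params(c_inc = 0.6)), "fit")
fit <- attr(decay_in_puffs(fit, sched), "fit")
print(fit)
#> <craving_fit: A = 4.21 +/- 0.0068, B = 3.22 +/- 0.036, tau = 300.4 +/- 5.4 s>
#>   decay concentration 1.50 ng/mL (2.5 puffs)

delivery_efficiency(pk_params(0.6), dose_per_puff = 0.1, blood_volume = 5.6)
#> [1] 0.0336

## full simulated subject: states + driver nodes
res <- run_subject(run_config(seed = 3))
writeLines(format_report(res))
#> Subject    Condition    Driver Nodes                        Controllable Nodes (% of Total)
#> sim01      abstinence   Anterior Cingulate Cortex           26.09%
#>                         Amygdala (Left)                     8.70%
#> sim01      satiety      Anterior Cingulate Cortex           26.09%
#>                         Amygdala (Left)                     8.70%
```

The fitted decay time (300 s on this noisy replicate; the generating value
is 310 s) converts to a decay concentration of `0.6 × 300.4 / 120 ≈ 1.50
ng/mL` and `300.4 / 120 ≈ 2.5` puffs; the driver table
shows that the planted hub (the anterior cingulate) is recovered as the top
target, controlling its six clique neighbours (26.09% of 23 regions) in
every state, while leaf regions control their module only in the one state
that activates it.

A thin command-line front end with subcommands `simulate`, `fit-craving`,
`states`, `drivers`, `run`, `report` is installed at
`system.file("cli", "nicodyn", package = "nicodyn")`.

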