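# traumanet

A firing-rate network model of post-traumatic stress disorder (PTSD) and
its two first-line therapies — prolonged exposure (PE) and eye movement
desensitization and reprocessing (EMDR) — implemented as a tested,
configuration-driven R simulator.

## The model

The circuit spans four regions, each represented by leaky firing-rate
units: three pairs of mutually inhibiting sensory units (V1/V2, A1/A2,
S1/S2 for the visual, auditory and somatosensory cortices), a
winner-take-all hippocampus that indexes multi-modal memories, a single
amygdala unit whose cue-evoked activation is the symptom readout, and a
single PFC unit (ventromedial in PE, dorsolateral in EMDR) that inhibits
the amygdala with a fixed weight of magnitude φ.

Unit dynamics follow τV̇ = −V + I + Σ w·F with forward Euler integration
and F = [tanh(V − θ)]⁺, so rates live in [0, 1). Plastic weights follow a
simplified Bienenstock–Cooper–Munro rule with clipping,

    Δw = α (F_post − ρ) F_pre,

potentiating above the plasticity threshold ρ and depressing below it.
Cortical (sensory→PFC) connections learn ten times more slowly, and their
updates are multiplied by a gain ψ ≥ 1 that stands in for the
plasticity-promoting slow waves recorded during EMDR's bilateral
stimulation.

With this machinery the package reproduces, as emergent behaviour: trauma
establishment and persistent cue-evoked fear (PTSD), pattern-completion
flashbacks, fear incubation, loss of unreinforced memories, resilience
through a more excitable PFC, memory tagging by mild emotional
engagement, PE-driven remission, and the faster remission of EMDR. The
fitting module extracts a normalized per-session symptom curve from the
amygdala response and fits (φ, ψ) by grid search against a target curve
with root-mean-squared error (RMSE), including synthetic-curve generation
for parameter-recovery studies.

## A worked example

```r
library(traumanet)

net  <- build_network(network_spec(seed = 1))
ptsd <- trauma_protocol(net, variant = "trauma")
ptsd[c(1, 2, 3, 35), c("trial", "label", "winner",
                       "hippocampus_F", "amygdala_F", "w_hipp_amyg")]
#>    trial          label winner hippocampus_F amygdala_F w_hipp_amyg
#> 1      1       baseline   <NA>         0.000      0.000        0.05
#> 2      2 pattern+trauma     H4         0.974      0.972        1.20
#> 3      3            cue   H4         0.928      0.789        1.20
#> 35    35            cue   H4         0.928      0.789        1.20
```

Trial 1 shows the baseline: the visual cue alone moves neither the
hippocampus nor the amygdala. In trial 2 the full sensory pattern plus
the trauma input recruits one hippocampal engram unit (H4) and the
amygdala, and potentiates the hippocampus→amygdala weight to its ceiling.
From trial 3 on, the cue alone reinstates both — a persistent,
emotionally loaded memory that does not extinguish with repeated
exposure: the model has PTSD.

Twenty sessions of prolonged exposure (engram recall paired with a safety
signal to the PFC, each followed by a frozen-learning test trial with the
cue alone) then abolish the fear response progressively:

```r
pe  <- therapy_protocol(build_network(network_spec(seed = 1)), "PE")
tst <- subset(pe, label == "test")
round(setNames(tst$amygdala_F, paste0("s", tst$session)), 2)
#>   s1   s2   s3   s4   s5   s6   s7   s8   s9  s10  s11  s12  s13  s14
#> 0.79 0.79 0.79 0.79 0.79 0.77 0.73 0.69 0.64 0.58 0.51 0.43 0.33 0.22
#>  s15  s16  s17  s18  s19  s20
#> 0.09 0.03 0.01 0.00 0.00 0.00
```

The cue-evoked amygdala response declines to exactly zero while the
hippocampal memory settles at a neutral plateau — the memory survives,
freed of its emotional load. Running `therapy_protocol(..., "EMDR")`
(φ = 1.3, ψ = 5, the fitted dorsolateral-PFC parameters) reaches the same
end state within about five sessions.

The command-line interface wraps the same functions:

```sh
inst/cli/traumanet simulate --config inst/extdata/config/trauma.yaml \
    --seed 1 --out runs/trauma
```

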