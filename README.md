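# chcq: cortico-hippocampal qubit-neuron networks for classical conditioning

`chcq` simulates classical-conditioning experiments — acquisition,
extinction, stimulus discrimination, discrimination reversal, blocking,
overshadowing, easy–hard transfer, latent inhibition, sensory and compound
preconditioning, and context shifts — with a cortico-hippocampal
computational quantum (CHCQ) model built from two coupled *qubit-neuron*
networks, and measures trials-to-criterion for intact versus
hippocampal-lesioned systems.  It is aimed at computational-neuroscience
and cognitive-modeling work on what hippocampal processing contributes to
multi-phase associative learning.

## The model

A qubit neuron carries a phase angle rather than a scalar activation.
Inputs `p ∈ [0,1]` are encoded as phases `p̃ = (π/2)p`; a unit with weights
`w`, reversal parameter `ε`, and phase threshold `ϑ` computes

    v = Σᵢ wᵢ·e^{i p̃ᵢ} − e^{iϑ},      y = (π/2)·S(ε) − Arg(v),

with `S` the logistic function, and reads out the |1⟩-state probability
`a = sin²(y) ∈ [0,1]`.  Two such networks are coupled:

* **Hippocampal module** — an autoencoder (cue + US flag in, reconstruction
  out) trained by the unsupervised **instar** rule on its input layer and
  the **outstar** rule on its output layer:
  `Wᵢⱼ ← Wᵢⱼ + μ·aⱼ·(pᵢ − Wᵢⱼ)` and `Wᵢⱼ ← Wᵢⱼ + μ·(tⱼ − Wᵢⱼ)·aᵢ`,
  applied to weights, reversals, and thresholds alike.
* **Cortical module** — maps the cue to the scalar conditioned response
  (CR); instar on the hidden layer, **Widrow–Hoff (LMS)** on the single
  output unit: `Wᵢ ← Wᵢ + μ·aᵢ·e` with `e` the prediction error against
  the US target `d ∈ {0,1}`.

In the *intact* system the hippocampal hidden-layer parameters are blended
into the cortical hidden layer at build time (`lambda_init`) and after
every trial (`lambda_trial`) — the adaptive internal-representation
signal.  *Lesioning* removes that link, leaving the bare cortical network.
Learning on an item ends when its CR stays at the steady state (≥ 0.9
reinforced, ≤ 0.15 unreinforced) for three consecutive sweeps;
trials-to-criterion is the first sweep opening that run.

## A worked example

```r
library(chcq)
m <- chcq(seed = 1)                     # intact system, shipped defaults
res <- run_paradigm(m, "latent_inhibition")
res$trials
#> phase1 phase2
#>     50     14
```

Phase 1 is the fixed 50-sweep unreinforced pre-exposure (AX−); phase 2
reports that this intact model needed 14 sweeps of AX+ before the CR
stayed above 0.9 — its final phase-2 CRs run `0.894, 0.901, 0.906,
0.911`.  The per-presentation CR trace is in `res$log`.

Batteries aggregate medians across independently seeded models:

```r
cfg <- battery_config(tasks = c("a_plus", "a_minus",
                                "stimulus_discrimination"),
                      n_seeds = 25)
run_battery(cfg)
#>                     task   system phase trials_median trials_iqr n_seeds n_not_reached
#>                   a_plus   intact     1            20         71      25             5
#>                   a_plus lesioned     1            17          7      25             0
#>                  a_minus   intact     1             2          0      25             0
#>                  a_minus lesioned     1             2          0      25             0
#>  stimulus_discrimination   intact     1            23         12      25             0
#>  stimulus_discrimination lesioned     1            21          5      25             0
```

The unpaired task (A−) reaches its low steady state within 2 sweeps; the
paired task needs ~20 (intact) versus ~17 (lesioned) sweeps; the
discrimination row counts sweeps until *both* items hold their respective
criteria.  `n_not_reached` counts runs that exhausted the sweep budget
(they enter the median at the budget, never silently dropped).

`make_paradigm()` lists the full task catalogue;
`baseline_feedforward()` runs the classical multilayer-perceptron control
on the same protocols, and `calibrate_chcq()` grid-searches
configurations against the published reference counts
(`reference_counts()`).  A command-line front end is in
`inst/cli/chcq.R`.

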