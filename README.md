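# cogtrace

Symbolic fault anticipation for simulated cognitive signals.

Closed-loop brain–machine interfaces (BMIs) usually expose their *output* —
the decoded command — but not their *epistemic state*: how confident the
decoder is, whether competing intent hypotheses are unresolved, whether the
signal is drifting away from the trajectory the system committed to. When the
user's cognitive state destabilises (attentional drift, a late change of
mind, overload under a rapid stimulus stream), the first visible symptom is
often the behavioural error itself. `cogtrace` is a research toolkit for
studying the alternative: a detector that continuously externalises its
internal inference as a sparse stream of time-stamped symbolic markers, so
that destabilisation is flagged *before* performance breaks down.

Everything runs in simulation with recorded ground truth, so detection and
anticipation can be scored exactly.

## What the package does

**Simulation.** `simulate_episode()` generates EEG-like multichannel
episodes: pink (1/f) background noise plus a dominant alpha-band (8–12 Hz)
oscillation whose spatial pattern expresses the agent's intent class, a
non-negative behavioural-error series, and a ground-truth state timeline.
Three fault regimes are injected with published trigger parameters:

| task paradigm  | fault                | generative trigger |
|----------------|----------------------|--------------------|
| motor control  | gradual intent drift | Gaussian-profile low-frequency excursion, amplitude 0.12, onset ~ N(5.5 s, 1.0 s) |
| inhibition (Go/No-Go) | late decision reversal | intent flip once model spectral entropy crosses 0.6, enacted after a 300–500 ms delay |
| overload (RSVP) | schema collapse | 5 Hz input-locked component with precision decay τ = 2.2 s; overload state once the ambiguity index 1 − precision(t)/precision(0) exceeds 0.7 |

**Detection.** `detect_events()` slides 512-sample windows over the signal
and evaluates, per window: Jensen–Shannon divergence of the window's
normalized power spectrum against a baseline reference (drift trigger,
threshold 0.35), a matched-filter two-template hypothesis bank
(conflict ratio = second-best/best evidence, threshold 0.5; commitment at
confidence ≥ 0.75), normalized spectral entropy (rejection spike at 0.6),
alpha power, and alpha-band phase-locking synchrony. A hypothesis lifecycle
(σ1 commitment → acceptance or rejection) runs on top of the drift/conflict
branch rules.

**Symbolic emission.** `emit_trace()` maps events to the user-facing
vocabulary (σ1 "Intent committed", Δ "System diverging", ⚠ "Conflict
rising", ⊘ "Hypothesis rejected", ✓ "Hypothesis accepted") and
`write_trace()`/`read_trace()` serialize traces as JSON-lines.

**Evaluation.** `traceability_score()` (fraction of markers that are
type-consistent with the ground-truth timeline within a 1 s tolerance),
`anticipation_latency()` (lead of the first warning marker over behavioural
error onset), `marker_stats()` (activation frequency, correct-prediction
rate, false-positive rate, lead times per marker), `bootstrap_ci()` and
`compare_conditions()` (Shapiro–Wilk-gated paired t / Wilcoxon tests with
effect sizes).

**Studies.** `run_study()` orchestrates the full batch pipeline with
ablations and seed determinism; `calibrate_study()` is the seeded
random-search calibrator used once to fix the generator's free parameters
(the shipped defaults are the frozen result).

## Worked example

```r
library(cogtrace)

ep <- simulate_episode(task_scenario("motor_control", seed = 42))
ep
#> <cog_episode> motor_control, 60 s @ 256 Hz, 4 channel(s)
#>   fault: gradual_drift (onset 6.05 s), error onset 10.40 s
#>   states: stable > drift > stable

trace <- emit_trace(detect_events(ep), episode_id = "demo")
trace
#> <cog_trace> episode demo: 5 marker(s)
#>    2.00s  σ1 Intent committed     [intent_a]
#>    6.00s  ✓ Hypothesis accepted
#>    8.00s  Δ  System diverging
#>    9.00s  Δ  System diverging
#>   10.00s  Δ  System diverging

traceability_score(trace, ep$truth)   # 1.0: every marker type-consistent
anticipation_latency(trace, ep$truth)
#> [1] 2.40
```

The intent drift starts at 6.05 s; the first "System diverging" marker
appears at 8 s, 2.4 s before the behavioural error crosses its threshold at
10.4 s — the system warns while performance is still intact.

A small batch study aggregates the same quantities over tasks:

```r
st <- run_study(study_config(n_episodes_per_task = 25, root_seed = 7))
st
#> <cog_study> 75 episodes (motor_control, inhibition, overload), fault rate 0.80, seed 7
#>   mean traceability: 0.905 (per task: motor_control=0.917, inhibition=0.947, overload=0.852)
#>   anticipation latency: 2.13 +/- 0.68 s (n=58)
#>   per-marker statistics:
#>            marker                             tasks activation correct false_pos lead_s
#>            Sigma1 motor_control+inhibition+overload     100.0%   92.0%      0.0%      -
#>          AcceptH1 motor_control+inhibition+overload      96.0%   76.4%     23.6%      -
#>          RejectH1               inhibition+overload      46.0%   87.0%      0.0%   2.64
#>        DriftEvent            motor_control+overload      74.0%   92.6%      1.2%   1.41
#>  ConflictEscalate               inhibition+overload      22.0%    1.7%     11.7%   0.15
```

At the default study size (300 episodes per task) the percentages stabilise;
see the methods vignette (`vignettes/symbolic-fault-anticipation.Rmd`) for
the model, the calibration protocol, and known limitations.

A thin CLI over the same functions lives at `inst/cli/cogtrace.R`
(`simulate`, `detect`, `replay`, `evaluate`, `study` subcommands).

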