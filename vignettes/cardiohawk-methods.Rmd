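---
title: "Methods: chaotic hawk-optimized attention-GRU/ELM cardiac classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic hawk-optimized attention-GRU/ELM cardiac classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its model, the choices made where
the design was genuinely open, and what the synthetic experiments do and do
not show.

## The classification model

A cohort record is one subject: `patient_id`, `age` (years), `gender`,
`ecg` (an ECG-derived heart-rate summary, beats per minute), `bp` (systolic
blood pressure, mmHg) and a class label. Records may carry a short
per-record heart-rate sample stream; when present it supplies the temporal
input, otherwise the scalar summary is replicated.

**Preprocessing.** Numeric features are z-scored. Standard deviations use
the n denominator (population convention), so a two-point feature {0, 10}
maps exactly to {−1, 1}; the convention matters only for reproducibility,
not statistically. Normalization statistics are computed on training
records and stored in the model; held-out records are transformed with the
stored statistics and never update them. Missing sensor values are filled
by regression imputation (`ecg ~ bp + age`, symmetrically `bp ~ ecg +
age`, fitted on complete cases); complete records whose externally
(leave-one-out) studentized residual exceeds 2.5 in absolute value are
treated as non-meaningful sensor noise — electromagnetic interference and
motion artefacts are endemic in wearable ECG — and replaced by the
regression prediction. The threshold 2.5 flags roughly 1–2% of clean
Gaussian data, a deliberate balance between noise suppression and
over-correction. Flags are computed on the initial complete-case fit, but
the predictions used for filling and replacement come from a refit
excluding the flagged rows: otherwise a gross outlier (say, an ECG value of
10⁴) drags the regression toward itself and corrupts its own replacement.
At prediction time only the stored training-fold regression coefficients
are applied to missing entries; nothing is refitted.

**Feature extractor.** Each record becomes a `window × 4` sequence (age,
gender, heart-rate sample, bp; the non-stream channels are constant over
time). A stack of `gru_cells` layers processes it; per layer a GRU
recurrence

- `z_t = σ(W_z x_t + U_z h_{t−1} + b_z)` (update gate)
- `r_t = σ(W_r x_t + U_r h_{t−1} + b_r)` (reset gate)
- `h̃_t = tanh(W_h x_t + U_h (r_t ⊙ h_{t−1}) + b_h)`
- `h_t = (1 − z_t) ⊙ h_{t−1} + z_t ⊙ h̃_t`

is followed by scaled dot-product self-attention over the hidden-state
sequence, `softmax(QKᵀ/√d_k)·V` with row-wise softmax and `Q, K, V` linear
projections of the states. Each layer consumes the previous layer's
context sequence; the per-layer contexts are summed and mean-pooled over
time (concatenation is available as an option). The key/context dimension
`d_k` is fixed at 4, the input channel count, so layers compose without
shape bookkeeping. Attention rows are probability vectors by construction;
GRU states remain in (−1, 1) because each update is a convex combination
of the previous state and a tanh value.

The extractor is *reservoir-style*: weights are drawn once, uniform on
(−0.5, 0.5) under a seed derived from the master seed, and are not
gradient-trained. The learnable capacity sits entirely in the closed-form
head, which keeps a single model evaluation to milliseconds — essential
when a population-based optimizer evaluates hundreds of candidate models —
and makes every fit exactly reproducible. An alternative mode
(`tune = "weights"`) freezes the architecture mid-range and lets the
optimizer search the attention projection entries directly; it is provided
because the source material is ambiguous about whether the metaheuristic
tunes hyperparameters or dense weights, and neither reading is asserted as
authorial intent.

**Classification head.** An extreme learning machine: fixed random hidden
layer `H = tanh(XW + b)` (tanh chosen as an odd, bounded, non-zero-slope
activation; `W`, `b` uniform on (−1, 1) under a derived seed) and output
weights solved in closed form as the ridge solution. The kernel-style form
`β = Hᵀ(I/C + HHᵀ)⁻¹Y` and the primal form `β = (HᵀH + I/C)⁻¹HᵀY` are
algebraically identical; the implementation uses whichever system is
smaller (`n ≤ d_elm` chooses the kernel form) and the tests verify both
against an independent QR-based ridge solver. Binary classification uses
one-hot targets and argmax; ternary mode uses a single ordinal output `g`
with the staircase `g ≤ 1` normal, `g ≤ 2` disease-1, `g ≤ 3` disease-2,
and `g > 3` surfaced as an explicit `"uncertain"` label rather than a
hidden re-evaluation loop. The ternary disease grades are not clinically
defined in the source material; the staircase is implemented as specified
and the binary mode is the default.

## The optimizer

Harris Hawks Optimization is implemented as a minimizer (the classifier
fitness is negated), with hawks clipped to the search box after every move.
Per hawk and iteration the initial energy `E0 ~ U(−1, 1)` gives the escape
energy `E = 2·E0·(1 − t/T)`: `|E| ≥ 1` dispatches exploration (perching
relative to a random flock member or to rabbit and flock mean), smaller
values one of four exploitation strategies selected by the escape draw `r`
and `|E|`:

- soft besiege (`r ≥ 0.5, |E| ≥ 0.5`): `ΔX − E|J·rabbit − X|`, jump
  strength `J = 2(1 − r5)` redrawn per update;
- hard besiege (`r ≥ 0.5, |E| < 0.5`): `rabbit − E|rabbit − X|`;
- rapid dives (`r < 0.5`): `Y = rabbit − E|J·rabbit − X|` (soft) or with
  the swarm mean in place of `X` (hard), `Z = Y + S ⊙ LF(D)` with a
  Mantegna Lévy flight (`β = 1.5`, scale 0.01), and three-way greedy
  acceptance — the first strict improvement among `Y`, `Z`, else the hawk
  stays put.

`q`, `r`, `r1`–`r5` are independent uniform draws per hawk per iteration;
the source declares the symbols but not a draw schedule, and independent
draws are the canonical choice. The rabbit (best-so-far) is updated after
every evaluation, so the best-fitness trace is non-increasing by
construction.

**The logistic-chaotic variant.** The logistic map `x ← c·x(1 − x)` at
control `c = 4` is fully chaotic (conjugate to the doubling map — the
package tests its iterates against `sin²(2ⁿ·asin√x₀)`). LC-HHOA uses one
scalar chaotic stream, advanced once per coordinate use, initial value 0.7,
with initialization values on the degenerate orbit points {0, ¼, ½, ¾, 1}
rejected. The stream (a) seeds the initial population and (b) replaces the
hawk-position term inside the soft besiege:
`X⁺ = X_chaos − E|J·rabbit − X_chaos|` with `X_chaos = LB + c·(UB − LB)`.
The chaotic candidate is accepted greedily; when it does not improve the
hawk, the canonical soft-besiege move is taken instead. Design rationale:
the substituted update contains the jump strength `J`, which appears only
in the soft-besiege form, so the substitution is scoped there; and chaotic
candidates are global jumps, valuable for escaping local basins but — if
they *displace* the canonical rabbit-directed moves — costly for late-stage
refinement. The greedy-with-fallback rule keeps the chaotic exploration
while preserving the vanilla convergence machinery, which is what makes the
paired non-inferiority property (tested on sphere and Rastrigin) hold. The
hard besiege, exploration and dive branches keep their stochastic form.
Note the chaotic variant may consume one extra objective evaluation per
soft besiege; comparisons between variants are budgeted by iterations, with
evaluation counts reported alongside.

**Search space and decoding.** The optimizer works on the unit cube; each
coordinate maps affinely onto its hyperparameter range, integral fields
rounded half-up: epochs [50, 400], gru_cells [1, 3], hidden_units [4, 32]
(also the ELM hidden width), learning_rate [10⁻⁴, 10⁻²], batch_size
[16, 128], dropout [0, 0.5), elm_regularization [0.1, 1000]. In the default
reservoir mode epochs, learning_rate, batch_size and dropout are decoded
and stored for interface fidelity but are *inert* — there is no gradient
loop for them to steer; they become meaningful only in the weight-search
mode. A configured momentum or tree depth is likewise accepted and ignored;
these knobs have no role in a reservoir GRU with a closed-form head.

**Fitness and early stopping.** The fitness of a candidate is the mean of
accuracy, precision, recall and F1 on an internal stratified validation
split (25% by default), a bounded [0, 1] objective that uses all four
ingredients of the stated criterion without its dimensionally incoherent
per-iteration division. Zero-denominator metrics return a flagged 0 rather
than NaN precisely so this objective stays bounded. The search stops early
when the best validation fitness has not strictly improved for `patience`
consecutive iterations; the selected configuration is then refit on all
supplied records.

## The synthetic cohort generator

No public dataset carries this schema, so the generator emulates the
documented cohort structure: 1,672 records, 887 healthy; ages uniform on
[22, 65]; genders balanced. Class-conditional structure:

- **Blood pressure** (mmHg): healthy N(115, 10); diseased N(140, 12), with
  probability 0.8 truncated above 130 — diseased systolic pressure above
  130 is the documented marker.
- **Heart rate** (bpm): per record a stream of 16 samples. Healthy draws
  are a shifted, scaled Student-t with 5 degrees of freedom (location 75,
  scale 10) truncated at 160 — leptokurtic, as documented, with the
  healthy-cap at 160; diseased draws are Gaussian (location 100, scale 12)
  truncated at 150. The 25 bpm location gap models resting tachycardia in
  the diseased group.
- **Coupling**: within each class the stream location is shifted by 4 bpm
  per blood-pressure standard score, a sympathetic-activation coupling.
  This matters for imputation: the documented preprocessing fills a missing
  sensor from the *other* sensor by regression, which presupposes that ECG
  and BP carry information about each other beyond class membership. The
  coupling is kept moderate because within-class covariance aligned with
  the between-class axis erodes class separability; 4 bpm/SD yields a
  cohort-level ECG–BP correlation near 0.88, enough for regression
  imputation to beat half a feature SD with margin while held-out accuracy
  stays above 0.99.
- **ECG column**: the stream mean plus N(0, 3) sensor noise — an abstract
  sensor scalar, since the source tabulates "ECG data" without units.

What the generator does **not** emulate: ECG waveform morphology
(P-QRS-T), sensor noise spectra, electromagnetic interference structure,
age- or gender-dependent physiology, comorbidity, or any temporal
autocorrelation within the stream (samples are i.i.d. given the subject).
Passing tests therefore demonstrate that the pipeline recovers a strong,
low-dimensional class structure from noisy tabular-plus-stream input —
they say nothing about diagnostic performance on real ECGs, where the
signal is subtler and the structure richer.

## Numerical and reproducibility choices

- All randomness flows from one master seed through deterministic child
  seeds (a hash of seed and component tag, kept below 2³¹); reruns are
  bit-identical, and the CLI writes no timestamps for the same reason.
- Out-of-bounds hawks are clipped componentwise — the simplest rule that
  preserves the containment invariant.
- Weight initialization consumes no optimizer RNG (separate derived
  seeds), so the optimizer's draw sequence is invariant to model size.
- Model bundles serialize every numeric as a 17-significant-digit decimal
  string inside JSON, which round-trips IEEE doubles exactly; standard
  JSON number printing loses the last 1–2 bits.
- Signed-rank tests drop zero differences and use mid-ranks; p-values are
  exact by full sign enumeration for up to 14 non-zero differences (valid
  under ties), exact by the standard distribution up to 25 without ties,
  and normally approximated (no continuity correction) beyond. Shapiro-Wilk
  delegates to the standard implementation.
- Model building time is reported wherever trained models are compared but
  never asserted in tests: it is hardware-dependent.
- Stratified splits and folds deal classes round-robin after shuffling, so
  fold class ratios match the cohort within one record.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every claim while keeping a full run to a few minutes on one CPU:
optimizer benchmarks at N = 20 hawks, T = 300 iterations, dimension 10,
20 paired seeds; the end-to-end experiment on the full default cohort
(1,672 records) with a smoke-scale search (6 hawks, 10 iterations, patience
3) across 5 master seeds; 1,000 randomized micro-instances for the
optimizer invariants and 1,000 random confusion matrices for the metric
checks.

## Known limitations

- The reservoir extractor is not trained; its features are generic
  nonlinear projections, adequate for strongly structured cohorts but far
  from a trained GRU's representation power.
- The ordinal ternary head presumes the disease grades are ordered along a
  single score; nothing enforces clinical meaning.
- The weight-search mode optimizes only the attention projections at a
  frozen mid-range architecture; searching all dense weights would require
  dimensionality the hawk population sizes used here cannot cover.
- Chaotic substitution is scoped to the soft besiege; broader substitution
  schemes (other maps, parameter-stream substitution) are out of scope.
- The imputation regressions are linear; the truncated BP mixture makes the
  true conditional expectation mildly nonlinear, part of why recovery error
  sits near 0.4 SD rather than lower.
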