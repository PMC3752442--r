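---
title: "Simulating conduite d'approche in a dual-pathway recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating conduite d'approche in a dual-pathway recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdanet)
```

## The phenomenon

*Conduite d'approche* is the self-correcting behavior of conduction
aphasic patients: successive attempts at a target word that move toward
the correct phonological form. It is observed mostly for real words, and
mostly after a period of recovery. The classical interpretation is that
intact lexical-semantic knowledge "cleans up" a noisy phonological
trace between attempts. `cdanet` implements a neuroanatomically-shaped
simulation of this account: a simple-recurrent network with separate
dorsal (phonological) and ventral (semantic) routes is trained on spoken
word repetition, comprehension and naming; its dorsal route is damaged;
it partially recovers through retraining; and self-correction of
repetition errors is measured as an emergent behavior, together with its
lexicality effect and its dependence on the ventral route.

## Model

Five layers: an **Auditory** input layer, a dorsal hidden layer
(**iSMG**, for inferior supramarginal gyrus), a ventral hidden layer
(**aSTG/STS**), a semantic hub (**vATL**, ventral anterior temporal
lobe) and a **SpeechMotor** output layer. Feedforward connectivity
follows the two routes: Auditory → iSMG → SpeechMotor (dorsal) and
Auditory → aSTG/STS → vATL → SpeechMotor (ventral). Every non-input
layer also receives an Elman copy-back projection from its own
activation at the previous time event, with trainable weights; this
recurrence is the network's only memory. Units are logistic; the
recurrent context is initialized to the neutral value 0.5 at the first
event of a trial.

Time is discrete. A word is a sequence of three morae (the Japanese
subsyllabic timing unit); one mora is presented or produced per event.
The four tasks are event-clamped schedules:

| task | input | target | events |
|---|---|---|---|
| repetition | morae on Auditory, events 1–3 | morae on SpeechMotor, events 4–6 | 6 |
| double repetition | morae on Auditory, events 1–3 | morae on SpeechMotor, events 7–9 only | 9 |
| comprehension (development) | morae on Auditory, events 1–3 | semantics on vATL, events 1–3 | 3 |
| comprehension (recovery) | morae on Auditory, events 1–3 | semantics on vATL, events 1–9 | 9 |
| speaking/naming | semantics clamped on vATL, events 1–3 | morae on SpeechMotor, events 1–3 | 3 |

The double-repetition trial is the key instrument: the network hears the
word, produces it once at events 4–6 *without any teaching signal
there*, and is trained to produce it again at events 7–9. Nothing in the
trial forces the second attempt to use the maintained semantic
activation; whether it does is the question the simulation asks. In the
recovery phase the comprehension target is extended across all nine
events so that the meaning of the heard word remains available for the
same duration.

A development epoch presents each training word once for repetition,
three times for comprehension and twice for speaking, in random order; a
recovery epoch adds one double-repetition trial per word. Development
runs 200 epochs; recovery runs 20, with performance probed every 5.

## Training and numerical choices

The loss is cross-entropy summed over exactly the (layer, event) pairs
where the trial defines a target; gradients are backpropagated through
time across the whole trial. Updates are made after every trial.

Three numerical choices matter and are worth stating plainly:

* **Step size and momentum.** The original simulations were run in a
  simulator whose default regime batches updates over an epoch; its
  printed learning rate (0.1) is not transferable to per-trial updates,
  which diverge at that size here. `cdanet` uses *normalized momentum*:
  the gradient is exponentially smoothed, `v ← 0.9 v + 0.1 g`, and the
  update is `w ← (w − lr · v)(1 − decay)` with `lr = 0.03` and decay
  `1e-7`. The learning rate therefore multiplies a quantity on the scale
  of a single-trial gradient regardless of the momentum setting. The
  value 0.03 was chosen as the largest rate at which development
  converges smoothly across initialization seeds; the same rate is used
  in both phases, keeping the optimizer fixed across all simulations.
* **Gradient clipping.** The two tasks introduced at the start of
  recovery (9-event comprehension maintenance, double repetition) are
  novel demands on a network trained with a 3–6 event horizon; their
  first-encounter gradients are an order of magnitude above anything in
  the trained regime (per-trial norms near 300 versus 6–13) and, left
  alone, erase the network within one epoch. Per-trial gradients whose
  global 2-norm exceeds 50 are rescaled to that bound, preserving
  direction. Trials inside the trained regime are unaffected.
* **Error signal under output noise.** At a targeted event the
  pre-activation error uses the analytic sigmoid-plus-cross-entropy
  cancellation, `δ = a − y`, evaluated at the unit's (possibly noisy,
  clipped) output. The literal chain rule through the clipped noisy
  activation has a `1/a(1−a)` factor that explodes when noise pushes an
  activation against the clipping boundary; the cancelled form is exact
  for zero noise and bounded under noise.

Analytic gradients are verified against central finite differences
(relative error below `1e-4`) for every trial type, including through
the recurrent context and the event masks, and the compiled training
loop is verified against a plain-R reference implementation to machine
precision.

## The synthetic language

The study's original materials (a Japanese 3-mora corpus and its matched
probe sets) are not available, so `cdanet` generates an artificial
language with the same structure:

* a mora inventory (default 20 morae, one-hot feature codes; distinct
  random binary codes are available when a distributed code is wanted);
* a training vocabulary of distinct 3-mora words (100 at desk scale, 300
  at paper scale), each paired with a sparse random binary semantic
  vector (50 bits, 10 active) — pairwise distinct, and arbitrary with
  respect to phonology, as word meanings are;
* a 51-word probe set drawn from the vocabulary, and 108 nonwords:
  3-mora forms that collide with no trained word and whose pooled
  mora-bigram frequency profile matches the probe words'. Matching uses
  largest-remainder quotas over the word bigram distribution with
  chained sampling of the second bigram, followed by a hill-climbing
  refinement; acceptance requires a symmetric chi-square distance below
  0.05 (achieved values at study scale are typically near 0.013; very
  small corpora have a coarser attainable floor and need a
  correspondingly looser configured tolerance). Each item also carries one of four pitch-accent class tags,
  used only as matching bookkeeping, never encoded in the input.

What the generator does *not* emulate: real Japanese phonotactics, word
frequency distributions, accent acoustics, semantic similarity
structure, and variable word length. Passing results therefore show that
the lesion-recovery mechanism produces the phenomenon in a language-like
statistical environment, not that the model handles Japanese.

## Lesions

The **dorsal lesion** that produces the conduction-aphasic starting
state removes a random 20% of the individual iSMG→SpeechMotor weight
entries (mask and weight pinned to zero; masks survive all later
training) and adds Gaussian noise, SD 0.2, to iSMG unit outputs at every
event, clipped to [0, 1]. The noise stays on during recovery training
and all probing — the damage is chronic.

The **diagnostic ventral lesions** form a 20-level equal-interval dose
grid: at level *k*, output noise `0.01k` on vATL and `0.005k` on
aSTG/STS, with `0.5k`% of vATL-incoming and `0.25k`% of
aSTG/STS-incoming weight entries pruned (feedforward and recurrent
alike, per matrix, rounded half-up). Levels are independent doses
applied to fresh copies of the recovered network, giving a dose-response
curve rather than progressive damage.

## Scoring and statistics

A probe runs the 9-event double-repetition schedule under the network's
current noise, five noise realizations per item. Each speech-motor
output event is decoded to the nearest mora code (Euclidean distance,
ties to the lowest mora id); an attempt is correct only if all three
decoded morae match in order — no partial credit. The **self-correction
rate** is the number of records whose second attempt (events 7–9) is
correct among those whose first attempt (events 4–6) was wrong; with no
first-attempt errors the rate is explicitly undefined, never 0/0.
Records are pooled over the five probes within a network before rates
are compared across networks.

Replicate networks are the random-effects unit. Two-level
repeated-measures contrasts report `F(1, n−1)` equal to the squared
paired *t* statistic, with Cohen's *d* computed on the paired
differences; the lexicality-by-damage interaction is the paired *t²* of
the per-network double difference. Undefined rates are excluded
pairwise with a warning.

## Scale presets and runtimes

The `paper` preset reproduces the study layout: 300 training words, 10
replicate networks. The `desk` preset — used by the test suite and the
acceptance script — runs 2 replicate networks on a 100-word vocabulary
with the same probe-set sizes (51 words, 108 nonwords), the same
200-epoch development and 20-epoch recovery, and the same lesion
parameters; one network takes roughly four minutes on a single CPU.
Development length is kept at 200 epochs even at desk scale because the
phase is defined by reaching adult-like performance (repetition ≈ 0.96–1.0,
comprehension 1.0, naming ≈ 0.7–0.75 here); halving it leaves the model
pre-adult and the lesion meaningless.

Layer sizes are design choices (the study inherits its exact sizes from
a precursor implementation that is not reproduced here): iSMG 200 —
repetition learning at this vocabulary was unstable with substantially
fewer units — aSTG/STS 60, vATL 50 (the semantic dimensionality),
SpeechMotor 20 (the mora feature dimensionality).

## Degenerate inputs and tie-breaks

Decoding ties go to the lowest mora id. An undefined self-correction
rate (no first-attempt errors) is flagged and excluded pairwise from
statistics. Zero-variance paired differences yield `F = 0` (zero mean)
or an infinite-F flag with `p = 0` (nonzero mean). Lesion proportions 0
and 1 are exact (no entries / all entries); a severity level with
all-zero parameters is the identity. Probe seeds are shared between the
sweep baseline and the severity levels, so an all-zero dose reproduces
the baseline records exactly.

## Known limitations

* **The immediate post-lesion profile is only partly conduction-aphasic
  at desk scale.** The dorsal lesion leaves comprehension untouched
  (drop 0.00) while repetition falls by ≈ 0.3 — the defining
  dissociation. But naming falls *more* than repetition here: during
  speaking the iSMG layer carries no item information, so its SD-0.2
  output noise injects pure noise into the motor layer (effective SD
  ≈ 0.4 per motor logit) against decision margins that cross-entropy
  training leaves only just past threshold, whereas repetition routes
  its content through iSMG redundantly, scaling signal and noise
  together. Longer development does not repair this (intact naming 0.90
  after doubling development still drops to ≈ 0.2 under the lesion); at
  the original corpus scale the fragilities evidently order the other
  way. The corresponding acceptance check is left failing rather than
  weakened.
* Self-correction attempts that drift away from the target, repeated
  (more than two) attempts, and self-correction in spontaneous speech
  are outside the model, as is any acoustic feedback loop: the second
  attempt is driven purely by internal recurrent state.
* The desk preset's two replicate networks give the repeated-measures
  statistics almost no power (`df = (1, 1)`); at desk scale the
  statistics table documents directions and magnitudes, not inference.
* There is no command-line tool: the package's functions, this
  vignette and `scripts/acceptance.R` are the interface.

## Reproducing the study's layout

```{r, eval = FALSE}
cfg <- run_config("paper", seed = 1)   # 300 words, 10 networks
res <- run_all(cfg, out_dir = "paper_run")
res$stats$lexicality      # F(1, 9) for word vs nonword self-correction
res$stats$interaction     # lexicality x ventral-damage interaction
```

At desk scale (`run_config("desk")`) the same pipeline runs in well
under ten minutes; every number in the README's worked example comes
from that configuration.
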