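# cdanet

Conduction aphasic patients often correct themselves: asked to repeat a
word, they produce a wrong form, then a closer one — *conduite
d'approche*. The behavior is strongest for real words and grows during
recovery, which has long suggested that intact lexical-semantic
knowledge "cleans up" a damaged phonological trace between attempts.
`cdanet` implements a computational test of that account for
researchers in language neuroscience and connectionist modeling: a
dual-pathway simple-recurrent network is trained on spoken-word
repetition, comprehension and naming; its dorsal (phonological) route
is lesioned; it partially recovers through retraining; and
self-correction on a second repetition attempt is measured as an
emergent property, together with its lexicality effect and its
dose-response dependence on the ventral (semantic) route.

## Model

Five logistic layers — Auditory input, iSMG (dorsal hidden), aSTG/STS
(ventral hidden), vATL (semantic hub), SpeechMotor output — connected as

    dorsal:   Auditory → iSMG → SpeechMotor
    ventral:  Auditory → aSTG/STS → vATL → SpeechMotor

with an Elman copy-back recurrence on every non-input layer. Words are
3-mora sequences presented one mora per discrete time event. Training is
backpropagation through time with cross-entropy on event-masked targets.
A double-repetition trial presents the word at events 1–3, lets the
network produce it freely at events 4–6, and trains a second production
at events 7–9; the self-correction rate is

    P(attempt 2 correct | attempt 1 wrong)

pooled over 5 noise probes per item and compared across replicate
networks with paired F = t² statistics. The dorsal lesion removes 20% of
iSMG→SpeechMotor links and adds SD 0.2 Gaussian noise to iSMG outputs;
recovery retrains the four-task schedule for 20 epochs; a 20-level
equal-interval sweep then damages the ventral layers of independent
copies of the recovered network.

The training materials are synthetic: the generator builds a mora
inventory, a lexicon with sparse random semantic vectors, a 51-word
probe set and 108 nonwords matched to it on pooled mora-bigram
frequency (chi-square distance below a configured tolerance). See the
methods vignette (`vignettes/cdanet-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

```r
library(cdanet)
cfg <- run_config("desk", seed = 1)   # 100 words, 2 replicate networks
res <- run_all(cfg)
print(res)
#> cdanet experiment: 2 network(s), preset 'desk', seed 1
#>   post-recovery self-correction rate: words 0.193, nonwords 0.017
#>   lexicality contrast: F(1, 1) = 7.35, p = 0.225
```

Words self-correct on roughly a fifth of failed first attempts after
recovery; nonwords almost never do. The per-network table and the other
contrasts are in the result object:

```r
res$per_network[, c("network", "word_rate", "nonword_rate")]
#>   network word_rate nonword_rate
#> 1       1 0.1268657   0.01559454
#> 2       2 0.2588235   0.01747573
res$stats$recovery      # late vs early recovery checkpoints
#> F(1, 1) = 16.84, p = 0.1522, Cohen's d = 2.90 (n = 2)
```

`res$trajectory` holds the recovery time course (evaluations every 5
epochs), `res$sweep` the ventral dose-response curves (baseline plus 20
severity levels, both item sets), and `res$accuracies` the pre- and
post-lesion task accuracies. With two replicate networks the F tests
have df = (1, 1) and document direction and effect size rather than
inference; `run_config("paper")` runs the 10-network, 300-word layout.

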