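Package: cdanet
Title: Dual-Pathway Recurrent Network Simulation of Conduite d'Approche
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates spoken-word repetition, comprehension and naming in a
    simple-recurrent (Elman) network with separate dorsal (auditory to
    supramarginal gyrus to speech-motor) and ventral (auditory to anterior
    superior temporal to ventral anterior temporal to speech-motor) routes.
    Provides a synthetic-lexicon generator with bigram-matched nonwords,
    event-clamped task schedules for repetition, comprehension, speaking and
    double-repetition trials, dorsal lesioning that produces a conduction
    aphasia profile, a post-lesion recovery phase, graded diagnostic
    lesioning of the ventral route, and scoring of conduite d'approche
    (self-correction on a second repetition attempt) with the associated
    repeated-measures statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, withr, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
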