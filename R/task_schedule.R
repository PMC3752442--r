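# Trial construction for the four tasks, in both training phases.
#
# A trial is a set of event-indexed input clamps plus event-indexed target
# patterns. Events are discrete ticks; a mora is presented (or required)
# one per event. Development phase: repetition (hear events 1-3, reproduce
# 4-6), comprehension (hear 1-3, semantic target 1-3), speaking (semantic
# clamp 1-3, produce 1-3). Recovery adds the double-repetition trial
# (targets only at events 7-9, events 4-6 free-running) and extends the
# comprehension target to events 1-9.

new_trial <- function(task, n_events, inputs, targets, item_id) {
  structure(list(task = task, n_events = as.integer(n_events),
                 inputs = inputs, targets = targets, item_id = item_id),
            class = "trial_spec")
}

# layer pattern spread over events: cols is a units x k matrix, events an
# integer vector of length k
event_block <- function(cols, events, n_events, n_units) {
  values <- matrix(0, n_units, n_events)
  flag <- rep(FALSE, n_events)
  values[, events] <- cols
  flag[events] <- TRUE
  list(values = values, clamped = flag, active = flag)
}

mora_cols <- function(item, inventory) {
  feat <- inventory_matrix(inventory)
  feat[, item$morae, drop = FALSE]
}

item_key <- function(item) triple_key(item$morae)

#' Build a standard repetition trial
#'
#' The 3-mora sound pattern is clamped on the auditory layer at events 1-3
#' (one mora per event) and the speech-motor layer is required to reproduce
#' the same sequence at events 4-6. Six events; no semantic target, so
#' nonwords are accepted.
#'
#' @param item a lexicon item (word or nonword).
#' @param inventory the mora inventory the item indexes into.
#' @return a \code{trial_spec}.
#' @export
make_repetition <- function(item, inventory) {
  if (length(item$morae) != 3) stop("item must have exactly 3 morae")
  cols <- mora_cols(item, inventory)
  nd <- nrow(cols)
  inp <- event_block(cols, 1:3, 6, nd)
  tgt <- event_block(cols, 4:6, 6, nd)
  new_trial("repetition", 6,
            inputs = list(Auditory = inp[c("values", "clamped")]),
            targets = list(SpeechMotor = tgt[c("values", "active")]),
            item_id = item_key(item))
}

#' Build a conduite d'approche (double repetition) trial
#'
#' Identical input to [make_repetition()] (auditory clamp at events 1-3)
#' but the speech-motor target applies only at events 7-9: the network
#' free-runs over events 4-6 (where it produces its first, untargeted
#' repetition attempt) and is trained to produce the sequence again at
#' events 7-9. Nine events.
#'
#' @inheritParams make_repetition
#' @return a \code{trial_spec}.
#' @export
make_cda <- function(item, inventory) {
  if (length(item$morae) != 3) stop("item must have exactly 3 morae")
  cols <- mora_cols(item, inventory)
  nd <- nrow(cols)
  inp <- event_block(cols, 1:3, 9, nd)
  tgt <- event_block(cols, 7:9, 9, nd)
  new_trial("cda", 9,
            inputs = list(Auditory = inp[c("values", "clamped")]),
            targets = list(SpeechMotor = tgt[c("values", "active")]),
            item_id = item_key(item))
}

#' Build a comprehension trial
#'
#' The auditory sequence is clamped at events 1-3 while the semantic
#' pattern is the target on the vATL layer at every event: events 1-3 in
#' the development phase (3 events) or events 1-9 in the recovery phase
#' (9 events), where the network must also maintain the meaning after the
#' input ends.
#'
#' @inheritParams make_repetition
#' @param phase \code{"development"} or \code{"recovery"}.
#' @return a \code{trial_spec}; nonwords (no semantics) are an error.
#' @export
make_comprehension <- function(item, inventory,
                               phase = c("development", "recovery")) {
  phase <- match.arg(phase)
  if (!item$is_word || length(item$semantics) == 0) {
    stop("comprehension requires a word with a semantic vector")
  }
  cols <- mora_cols(item, inventory)
  nd <- nrow(cols)
  n_ev <- if (phase == "development") 3L else 9L
  inp <- event_block(cols, 1:3, n_ev, nd)
  sem <- matrix(item$semantics, length(item$semantics), n_ev)
  tgt <- list(values = sem, active = rep(TRUE, n_ev))
  new_trial("comprehension", n_ev,
            inputs = list(Auditory = inp[c("values", "clamped")]),
            targets = list(vATL = tgt),
            item_id = item_key(item))
}

#' Build a speaking/naming trial
#'
#' The semantic pattern is clamped onto the vATL layer for events 1-3 (the
#' semantic hub acting as the input surface) and the speech-motor layer
#' must produce the word's 3-mora sequence at events 1-3, one mora per
#' event. Identical in both phases.
#'
#' @inheritParams make_repetition
#' @return a \code{trial_spec}; nonwords are an error.
#' @export
make_speaking <- function(item, inventory) {
  if (!item$is_word || length(item$semantics) == 0) {
    stop("speaking requires a word with a semantic vector")
  }
  cols <- mora_cols(item, inventory)
  nd <- nrow(cols)
  sem <- matrix(item$semantics, length(item$semantics), 3)
  inp_sem <- list(values = sem, clamped = rep(TRUE, 3))
  tgt <- event_block(cols, 1:3, 3, nd)
  new_trial("speaking", 3,
            inputs = list(vATL = inp_sem),
            targets = list(SpeechMotor = tgt[c("values", "active")]),
            item_id = item_key(item))
}

#' Build one training epoch
#'
#' Per training word the development schedule holds 1 repetition, 3
#' comprehension and 2 speaking trials; the recovery schedule adds 1
#' double-repetition (conduite d'approche) trial and uses the extended
#' 9-event comprehension form. The multiset of trials is fixed; only the
#' order is randomized by the seed (consumed at presentation time by
#' [train_epoch()], which shuffles the list it is given).
#'
#' @param corpus a \code{cdanet_corpus}.
#' @param phase \code{"development"} or \code{"recovery"}.
#' @param seed integer seed randomizing trial order.
#' @return list of \code{trial_spec}s in seeded random order.
#' @export
build_epoch <- function(corpus, phase = c("development", "recovery"),
                        seed = 1L) {
  phase <- match.arg(phase)
  inv <- corpus$mora_inventory
  trials <- list()
  for (it in corpus$train_words) {
    per_word <- c(list(make_repetition(it, inv)),
                  if (phase == "recovery") list(make_cda(it, inv)),
                  replicate(3, make_comprehension(it, inv, phase),
                            simplify = FALSE),
                  replicate(2, make_speaking(it, inv), simplify = FALSE))
    trials <- c(trials, per_word)
  }
  withr::with_seed(seed, trials[sample.int(length(trials))])
}

#' Validate a trial against its task schema
#'
#' Structural check that a trial's event layout matches the schedule for
#' its task and phase: event counts, clamp events and target events.
#'
#' @param trial a \code{trial_spec}.
#' @return TRUE invisibly; errors describe the violation.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "trial_spec"))
  chk <- function(cond, msg) if (!cond) stop("invalid trial: ", msg)
  aud <- trial$inputs$Auditory
  tgt_m <- trial$targets$SpeechMotor
  switch(trial$task,
    repetition = {
      chk(trial$n_events == 6, "repetition spans 6 events")
      chk(identical(which(aud$clamped), 1:3), "auditory clamp at events 1-3")
      chk(identical(which(tgt_m$active), 4:6), "motor target at events 4-6")
      chk(is.null(trial$targets$vATL), "no semantic target in repetition")
    },
    cda = {
      chk(trial$n_events == 9, "double repetition spans 9 events")
      chk(identical(which(aud$clamped), 1:3), "auditory clamp at events 1-3")
      chk(identical(which(tgt_m$active), 7:9), "motor target at events 7-9")
      chk(is.null(trial$targets$vATL), "no semantic target")
    },
    comprehension = {
      chk(trial$n_events %in% c(3L, 9L), "comprehension spans 3 or 9 events")
      chk(identical(which(aud$clamped), 1:3), "auditory clamp at events 1-3")
      chk(all(trial$targets$vATL$active), "semantic target at every event")
      chk(is.null(tgt_m), "no motor target in comprehension")
    },
    speaking = {
      chk(trial$n_events == 3, "speaking spans 3 events")
      chk(identical(which(trial$inputs$vATL$clamped), 1:3),
          "semantic clamp at events 1-3")
      chk(identical(which(tgt_m$active), 1:3), "motor target at events 1-3")
    },
    stop("unknown task: ", trial$task))
  invisible(TRUE)
}
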