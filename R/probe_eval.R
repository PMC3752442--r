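# Output decoding, double-repetition probing, the conduite d'approche
# statistic, and the repeated-measures analyses run across replicate
# networks.

#' Decode one speech-motor activation into a mora
#'
#' Nearest neighbor by Euclidean distance over the inventory's feature
#' codes; ties break deterministically to the lowest mora id.
#'
#' @param activation numeric vector of mora-feature dimensionality.
#' @param inventory mora inventory.
#' @return the winning mora id (integer).
#' @export
decode_event <- function(activation, inventory) {
  feat <- inventory_matrix(inventory)
  if (length(activation) != nrow(feat)) {
    stop("activation dimensionality does not match the mora codes")
  }
  d2 <- colSums((feat - activation)^2)
  which.min(d2)  # first minimum = lowest id on ties
}

# vectorized decoding: acts is feature_dim x n columns; returns n mora ids
decode_cols <- function(acts, feat) {
  # squared distances: ||f||^2 - 2 f'a + ||a||^2 ; the ||a||^2 term is
  # constant per column
  g <- crossprod(feat, acts)            # n_morae x n
  d2 <- colSums(feat^2) - 2 * g
  max.col(t(-d2), ties.method = "first")
}

#' Probe double repetition
#'
#' Runs every item through a 9-event double-repetition-shaped trial
#' (auditory input at events 1-3, free run to event 9) under the network's
#' current noise levels, with \code{n_noise_probes} independent noise
#' realizations per item. Speech-motor activations at events 4-6 (first
#' attempt) and 7-9 (second attempt) are decoded by nearest-neighbor; an
#' attempt is correct iff all three decoded morae match the item's morae in
#' order.
#'
#' @param net a \code{cdanet_net}.
#' @param items list of lexicon items (words or nonwords).
#' @param inventory mora inventory.
#' @param n_noise_probes noise realizations per item (default 5).
#' @param seed integer seed for the probe noise.
#' @return data.frame with one row per item x probe: \code{item},
#'   \code{lexicality}, \code{probe}, \code{decoded1}, \code{decoded2},
#'   \code{attempt1_correct}, \code{attempt2_correct}.
#' @export
probe_double_repetition <- function(net, items, inventory,
                                    n_noise_probes = 5, seed = 1L) {
  stopifnot(length(items) > 0, n_noise_probes >= 1)
  sizes <- net$spec$sizes
  feat <- inventory_matrix(inventory)
  n_items <- length(items)
  B <- n_items * n_noise_probes
  # batch columns: item-major, probe-minor
  vals <- array(0, c(sizes["Auditory"], B, 9))
  for (i in seq_len(n_items)) {
    cols <- feat[, items[[i]]$morae, drop = FALSE]
    sel <- ((i - 1) * n_noise_probes + 1):(i * n_noise_probes)
    for (t in 1:3) vals[, sel, t] <- cols[, t]
  }
  clamps <- list(Auditory = list(values = vals,
                                 clamped = c(TRUE, TRUE, TRUE, rep(FALSE, 6))))
  fb <- withr::with_seed(seed, forward_batch(net, clamps, 9L, B))
  motor <- fb$a[["SpeechMotor"]]

  dec <- matrix(0L, B, 6)  # decoded morae for events 4..9
  for (t in 4:9) {
    dec[, t - 3] <- decode_cols(matrix(motor[, , t], sizes["SpeechMotor"], B),
                                feat)
  }
  item_idx <- rep(seq_len(n_items), each = n_noise_probes)
  target <- t(vapply(items, function(it) it$morae, integer(3)))[item_idx, ,
                                                               drop = FALSE]
  ok1 <- rowSums(dec[, 1:3, drop = FALSE] == target) == 3
  ok2 <- rowSums(dec[, 4:6, drop = FALSE] == target) == 3
  data.frame(
    item = vapply(items, item_key, "")[item_idx],
    lexicality = ifelse(vapply(items, function(it) it$is_word, TRUE)[item_idx],
                        "word", "nonword"),
    probe = rep(seq_len(n_noise_probes), n_items),
    decoded1 = apply(dec[, 1:3, drop = FALSE], 1, paste, collapse = ","),
    decoded2 = apply(dec[, 4:6, drop = FALSE], 1, paste, collapse = ","),
    attempt1_correct = ok1,
    attempt2_correct = ok2,
    stringsAsFactors = FALSE)
}

#' Conduite d'approche rate
#'
#' The number of records repeated correctly on the second attempt among
#' those repeated incorrectly on the first, as a proportion: successful
#' self-correction conditional on a first-attempt error. With no
#' first-attempt errors the rate is undefined (never 0/0) and flagged.
#'
#' @param records a probe-record data.frame from
#'   [probe_double_repetition()].
#' @return list of class \code{cda_result}: \code{n_first_errors},
#'   \code{n_self_corrected}, \code{rate} (NA when undefined),
#'   \code{defined}.
#' @export
cda_rate <- function(records) {
  stopifnot(nrow(records) > 0)
  err1 <- !records$attempt1_correct
  n_err <- sum(err1)
  n_corr <- sum(err1 & records$attempt2_correct)
  structure(list(n_first_errors = n_err, n_self_corrected = n_corr,
                 rate = if (n_err > 0) n_corr / n_err else NA_real_,
                 defined = n_err > 0),
            class = "cda_result")
}

#' @export
print.cda_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("conduite d'approche: %d/%d first-attempt errors self-corrected (rate %.3f)\n",
                x$n_self_corrected, x$n_first_errors, x$rate))
  } else {
    cat("conduite d'approche: undefined (no first-attempt errors)\n")
  }
  invisible(x)
}

#' Two-level repeated-measures contrast
#'
#' Paired comparison of two conditions measured on the same networks:
#' F(1, n-1) equal to the square of the paired t statistic on the
#' differences, the corresponding p value, and Cohen's d computed on the
#' paired differences (mean difference over SD of differences). Pairs where
#' either value is NA (e.g. an undefined self-correction rate) are dropped
#' with a warning. A zero-variance nonzero-mean difference yields an
#' infinite F with p = 0.
#'
#' @param cond_a,cond_b equal-length numeric vectors, paired by network.
#' @return list of class \code{stats_result}: \code{F}, \code{df},
#'   \code{p}, \code{cohen_d}, \code{n}.
#' @export
repeated_measures_2level <- function(cond_a, cond_b) {
  stopifnot(length(cond_a) == length(cond_b))
  keep <- !(is.na(cond_a) | is.na(cond_b))
  if (any(!keep)) {
    warning(sprintf("dropping %d pair(s) with undefined values", sum(!keep)))
  }
  a <- cond_a[keep]; b <- cond_b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- a - b
  sd_d <- stats::sd(d)
  m <- mean(d)
  if (sd_d == 0) {
    if (m == 0) {
      out <- list(F = 0, df = c(1, n - 1), p = 1, cohen_d = 0, n = n)
    } else {
      out <- list(F = Inf, df = c(1, n - 1), p = 0, cohen_d = Inf * sign(m),
                  n = n)
    }
  } else {
    tt <- m / (sd_d / sqrt(n))
    Fv <- tt^2
    out <- list(F = Fv, df = c(1, n - 1),
                p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
                cohen_d = m / sd_d, n = n)
  }
  structure(out, class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.4g, Cohen's d = %.2f (n = %d)\n",
              x$df[1], x$df[2], x$F, x$p, x$cohen_d, x$n))
  invisible(x)
}

#' 2x2 repeated-measures interaction
#'
#' Interaction between lexicality (word vs nonword) and condition (e.g.
#' with vs without additional ventral damage) for four paired samples: the
#' paired t-squared statistic on the per-network double difference
#' (word_a - word_b) - (nonword_a - nonword_b).
#'
#' @param word_a,word_b,nonword_a,nonword_b equal-length numeric vectors
#'   paired by network.
#' @return a \code{stats_result} for the interaction.
#' @export
interaction_2x2 <- function(word_a, word_b, nonword_a, nonword_b) {
  stopifnot(length(word_a) == length(word_b),
            length(word_a) == length(nonword_a),
            length(word_a) == length(nonword_b))
  repeated_measures_2level(word_a - word_b, nonword_a - nonword_b)
}

#' Task accuracies of a network
#'
#' Accuracy on the three trained tasks over a probe item set, under the
#' network's current noise levels. Repetition: all three morae decoded
#' correctly at events 4-6 of a standard repetition trial. Naming: morae
#' decoded at events 1-3 of a speaking trial. Comprehension: the vATL
#' activation at event 3 of a comprehension trial is nearest (Euclidean) to
#' the item's own semantic vector among all words' vectors.
#'
#' @param net a \code{cdanet_net}.
#' @param words list of word items to probe.
#' @param inventory mora inventory.
#' @param all_words the word set defining the semantic decoding candidates
#'   (defaults to \code{words}).
#' @param n_noise_probes noise realizations per item.
#' @param seed integer seed.
#' @return named numeric vector: repetition, comprehension, naming
#'   accuracies in \[0, 1\].
#' @export
evaluate_tasks <- function(net, words, inventory, all_words = words,
                           n_noise_probes = 5, seed = 1L) {
  sizes <- net$spec$sizes
  feat <- inventory_matrix(inventory)
  n_items <- length(words)
  B <- n_items * n_noise_probes
  item_idx <- rep(seq_len(n_items), each = n_noise_probes)
  target <- t(vapply(words, function(it) it$morae, integer(3)))[item_idx, ,
                                                               drop = FALSE]
  sem_mat <- vapply(all_words, function(it) it$semantics,
                    numeric(length(all_words[[1]]$semantics)))
  sem_self <- match(vapply(words, function(it)
    paste(it$semantics, collapse = ""), "")[item_idx],
    vapply(all_words, function(it) paste(it$semantics, collapse = ""), ""))

  withr::with_seed(seed, {
    # repetition: 6-event trial, decode events 4-6
    vals <- array(0, c(sizes["Auditory"], B, 6))
    for (i in seq_len(n_items)) {
      cols <- feat[, words[[i]]$morae, drop = FALSE]
      sel <- which(item_idx == i)
      for (t in 1:3) vals[, sel, t] <- cols[, t]
    }
    fb <- forward_batch(net, list(Auditory = list(
      values = vals, clamped = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))),
      6L, B)
    dec <- sapply(4:6, function(t) decode_cols(
      matrix(fb$a[["SpeechMotor"]][, , t], sizes["SpeechMotor"], B), feat))
    rep_acc <- mean(rowSums(dec == target) == 3)

    # comprehension: 3-event trial, vATL at event 3 vs word semantics
    fbc <- forward_batch(net, list(Auditory = list(
      values = vals[, , 1:3, drop = FALSE], clamped = rep(TRUE, 3))), 3L, B)
    v3 <- matrix(fbc$a[["vATL"]][, , 3], sizes["vATL"], B)
    nearest <- decode_cols(v3, sem_mat)
    comp_acc <- mean(nearest == sem_self)

    # naming: vATL clamped 1-3, decode motor events 1-3
    semvals <- array(0, c(sizes["vATL"], B, 3))
    for (i in seq_len(n_items)) {
      sel <- which(item_idx == i)
      semvals[, sel, ] <- words[[i]]$semantics
    }
    fbs <- forward_batch(net, list(vATL = list(values = semvals,
                                               clamped = rep(TRUE, 3))),
                         3L, B)
    decs <- sapply(1:3, function(t) decode_cols(
      matrix(fbs$a[["SpeechMotor"]][, , t], sizes["SpeechMotor"], B), feat))
    name_acc <- mean(rowSums(decs == target) == 3)

    c(repetition = rep_acc, comprehension = comp_acc, naming = name_acc)
  })
}
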