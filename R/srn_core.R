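# Simple-recurrent (Elman) network with dorsal and ventral routes.
#
# Layers: Auditory (input) feeds iSMG (dorsal hidden) and aSTG_STS (ventral
# hidden); aSTG_STS feeds vATL (semantic hub); iSMG and vATL feed
# SpeechMotor (output). Every non-input layer additionally receives a
# trainable recurrent (Elman copy-back) projection from its own previous-
# event activation. Activations are logistic; training is backpropagation
# through time with cross-entropy loss on event-masked targets.

LAYER_ORDER <- c("Auditory", "iSMG", "aSTG_STS", "vATL", "SpeechMotor")
COMPUTED_LAYERS <- c("iSMG", "aSTG_STS", "vATL", "SpeechMotor")

#' Architecture specification for the dual-pathway network
#'
#' Defines the five layers and their feedforward connectivity. The dorsal
#' route is Auditory -> iSMG -> SpeechMotor; the ventral route is
#' Auditory -> aSTG_STS -> vATL -> SpeechMotor. The vATL layer doubles as
#' the semantic input/output surface: comprehension targets are read off it
#' and speaking trials clamp the semantic pattern onto it.
#'
#' @param mora_dim feature dimensionality of a mora code (Auditory and
#'   SpeechMotor layer size).
#' @param semantic_dim semantic vector length (vATL layer size).
#' @param ismg_units dorsal hidden layer size (default 100).
#' @param astg_units ventral hidden layer size (default 60).
#' @return an \code{arch_spec} list with layer sizes and the connection
#'   list.
#' @export
arch_spec <- function(mora_dim, semantic_dim, ismg_units = 100,
                      astg_units = 60) {
  stopifnot(mora_dim >= 1, semantic_dim >= 1, ismg_units >= 1,
            astg_units >= 1)
  sizes <- c(Auditory = as.integer(mora_dim), iSMG = as.integer(ismg_units),
             aSTG_STS = as.integer(astg_units),
             vATL = as.integer(semantic_dim),
             SpeechMotor = as.integer(mora_dim))
  conns <- list(c("Auditory", "iSMG"), c("iSMG", "SpeechMotor"),
                c("Auditory", "aSTG_STS"), c("aSTG_STS", "vATL"),
                c("vATL", "SpeechMotor"))
  structure(list(sizes = sizes, connections = conns), class = "arch_spec")
}

conn_name <- function(conn) paste(conn[1], conn[2], sep = "->")

# connections feeding each computed layer, precomputed for the hot loop
incoming_map <- function(spec) {
  out <- list()
  for (l in COMPUTED_LAYERS) {
    out[[l]] <- Filter(function(cn) cn[2] == l, spec$connections)
  }
  out
}

outgoing_map <- function(spec) {
  out <- list()
  for (l in LAYER_ORDER) {
    out[[l]] <- Filter(function(cn) cn[1] == l, spec$connections)
  }
  out
}

#' Initialize a network
#'
#' Weights (feedforward, recurrent and bias) are drawn uniformly from
#' \[-0.1, 0.1\]; all structural-lesion masks start at 1 and all per-layer
#' output-noise levels at 0 (an intact network). Deterministic given the
#' seed.
#'
#' @param spec an [arch_spec()].
#' @param seed integer seed.
#' @return object of class \code{cdanet_net}: weight matrices \code{W}
#'   (target x source, one per connection), recurrent matrices \code{Wrec}
#'   and biases \code{b} per non-input layer, masks matching \code{W} and
#'   \code{Wrec}, and a named \code{noise_sd} vector.
#' @export
init_network <- function(spec, seed) {
  stopifnot(inherits(spec, "arch_spec"))
  sizes <- spec$sizes
  withr::with_seed(seed, {
    W <- list(); mask <- list()
    for (cn in spec$connections) {
      nm <- conn_name(cn)
      W[[nm]] <- matrix(stats::runif(sizes[cn[2]] * sizes[cn[1]], -0.1, 0.1),
                        sizes[cn[2]], sizes[cn[1]])
      mask[[nm]] <- matrix(1, sizes[cn[2]], sizes[cn[1]])
    }
    Wrec <- list(); mask_rec <- list(); b <- list()
    for (l in COMPUTED_LAYERS) {
      Wrec[[l]] <- matrix(stats::runif(sizes[l]^2, -0.1, 0.1),
                          sizes[l], sizes[l])
      mask_rec[[l]] <- matrix(1, sizes[l], sizes[l])
      b[[l]] <- stats::runif(sizes[l], -0.1, 0.1)
    }
    structure(list(spec = spec, W = W, Wrec = Wrec, b = b, mask = mask,
                   mask_rec = mask_rec,
                   noise_sd = stats::setNames(numeric(length(LAYER_ORDER)),
                                              LAYER_ORDER),
                   epoch = 0L),
              class = "cdanet_net")
  })
}

#' @export
print.cdanet_net <- function(x, ...) {
  sz <- x$spec$sizes
  cat("cdanet network:",
      paste(sprintf("%s(%d)", names(sz), sz), collapse = " "), "\n")
  pruned <- sum(vapply(x$mask, function(m) sum(m == 0), 0)) +
    sum(vapply(x$mask_rec, function(m) sum(m == 0), 0))
  cat(sprintf("  epoch %d, %d pruned links, noise: %s\n", x$epoch, pruned,
              paste(sprintf("%s=%.3g", names(x$noise_sd), x$noise_sd),
                    collapse = " ")))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Batched forward simulation. clamps: named list layer -> list(values =
# units x B x T array, clamped = logical(T)). Returns post-noise
# activations `a` and pre-noise logistic outputs `s` as units x B x T
# arrays. Context (event 0) is 0.5 everywhere. Gaussian output noise with
# the layer's noise_sd is added independently at every event and the result
# clipped to [0, 1].
forward_batch <- function(net, clamps, n_events, n_batch) {
  sizes <- net$spec$sizes
  inc <- incoming_map(net$spec)
  a <- list()
  for (l in LAYER_ORDER) a[[l]] <- array(0, c(sizes[l], n_batch, n_events))
  s <- list()
  for (l in COMPUTED_LAYERS) s[[l]] <- array(0, c(sizes[l], n_batch, n_events))
  for (t in seq_len(n_events)) {
    # input layer: trial pattern or zeros
    cl <- clamps[["Auditory"]]
    if (!is.null(cl) && cl$clamped[t]) {
      a[["Auditory"]][, , t] <- cl$values[, , t]
    }
    for (l in COMPUTED_LAYERS) {
      cl <- clamps[[l]]
      if (!is.null(cl) && cl$clamped[t]) {
        a[[l]][, , t] <- cl$values[, , t]
        s[[l]][, , t] <- cl$values[, , t]
        next
      }
      z <- matrix(net$b[[l]], sizes[l], n_batch)
      for (cn in inc[[l]]) {
        src <- cn[1]
        z <- z + net$W[[conn_name(cn)]] %*%
          matrix(a[[src]][, , t], sizes[src], n_batch)
      }
      prev <- if (t == 1) matrix(0.5, sizes[l], n_batch) else
        matrix(a[[l]][, , t - 1], sizes[l], n_batch)
      z <- z + net$Wrec[[l]] %*% prev
      sl <- sigmoid(z)
      s[[l]][, , t] <- sl
      sd_l <- net$noise_sd[[l]]
      if (sd_l > 0) {
        noisy <- sl + matrix(stats::rnorm(length(sl), 0, sd_l), nrow(sl))
        a[[l]][, , t] <- pmin(pmax(noisy, 0), 1)
      } else {
        a[[l]][, , t] <- sl
      }
    }
  }
  list(a = a, s = s)
}

# convert a TrialSpec's inputs into batched clamp structures (B = 1)
trial_clamps <- function(trial, sizes) {
  clamps <- list()
  for (l in names(trial$inputs)) {
    inp <- trial$inputs[[l]]
    clamps[[l]] <- list(values = array(inp$values,
                                       c(sizes[l], 1, trial$n_events)),
                        clamped = inp$clamped)
  }
  # the auditory layer is always an input surface: unclamped events are
  # zero vectors
  if (is.null(clamps[["Auditory"]])) {
    clamps[["Auditory"]] <- list(values = array(0, c(sizes["Auditory"], 1,
                                                     trial$n_events)),
                                 clamped = rep(FALSE, trial$n_events))
  }
  clamps
}

#' Run one trial forward
#'
#' Clamps the trial's input patterns event by event (zero vector on the
#' auditory layer at events without input), propagates each non-input layer
#' as \code{sigmoid(feedforward + recurrent(t-1) + bias)}, adds per-layer
#' Gaussian output noise and clips to \[0, 1\]. Recurrent context at event 1
#' is the neutral value 0.5. With all noise levels at 0 the pass is a pure
#' function of weights and input.
#'
#' @param net a \code{cdanet_net}.
#' @param trial a \code{trial_spec} (see [make_repetition()] and friends).
#' @return list with per-layer activation matrices (units x n_events) in
#'   \code{activations} and pre-noise logistic outputs in \code{prenoise}.
#' @export
forward_trial <- function(net, trial) {
  stopifnot(inherits(net, "cdanet_net"), inherits(trial, "trial_spec"))
  sizes <- net$spec$sizes
  for (l in names(trial$inputs)) {
    if (nrow(trial$inputs[[l]]$values) != sizes[l]) {
      stop(sprintf("input dimensionality mismatch on layer %s", l))
    }
  }
  fb <- forward_batch(net, trial_clamps(trial, sizes), trial$n_events, 1L)
  acts <- lapply(fb$a, function(x) matrix(x, dim(x)[1], dim(x)[3]))
  pren <- lapply(fb$s, function(x) matrix(x, dim(x)[1], dim(x)[3]))
  list(activations = acts, prenoise = pren)
}

CE_EPS <- 1e-7

# cross-entropy summed over the (layer, event) pairs where the trial
# defines a target
trial_loss_from_acts <- function(acts, trial) {
  loss <- 0
  for (l in names(trial$targets)) {
    tg <- trial$targets[[l]]
    for (t in which(tg$active)) {
      aa <- pmin(pmax(acts[[l]][, t], CE_EPS), 1 - CE_EPS)
      y <- tg$values[, t]
      loss <- loss - sum(y * log(aa) + (1 - y) * log(1 - aa))
    }
  }
  loss
}

#' Loss of a network on one trial
#'
#' Runs the trial forward and returns the summed cross-entropy over the
#' trial's event-masked targets. Stochastic if the network carries output
#' noise.
#'
#' @inheritParams forward_trial
#' @return scalar loss.
#' @export
trial_loss <- function(net, trial) {
  fw <- forward_trial(net, trial)
  trial_loss_from_acts(fw$activations, trial)
}

# Backpropagation through time for one trial (batch 1). Returns weight /
# recurrent / bias gradients and the loss. At a targeted (layer, event) the
# pre-activation error uses the analytic sigmoid+CE cancellation,
# delta_z = a - y, evaluated at the (possibly noisy) output: exact with
# zero noise and bounded in [-1, 1] under output noise, where the literal
# chain rule through the clipped noisy activation can blow up near the
# clipping boundary. Error arriving from downstream layers multiplies the
# pre-noise logistic slope as usual.
bptt_trial <- function(net, trial, fw = NULL) {
  sizes <- net$spec$sizes
  n_ev <- trial$n_events
  inc <- incoming_map(net$spec)
  if (is.null(fw)) fw <- forward_trial(net, trial)
  acts <- fw$activations
  pren <- fw$prenoise

  clamped_at <- function(l, t) {
    inp <- trial$inputs[[l]]
    !is.null(inp) && inp$clamped[t]
  }

  delta <- list()
  for (l in COMPUTED_LAYERS) delta[[l]] <- matrix(0, sizes[l], n_ev)

  rev_order <- rev(COMPUTED_LAYERS)
  for (t in rev(seq_len(n_ev))) {
    for (l in rev_order) {
      if (clamped_at(l, t)) next  # clamped activations carry no error
      dL_da <- numeric(sizes[l])
      for (cn in net$spec$connections) {
        if (cn[1] == l && !clamped_at(cn[2], t)) {
          dL_da <- dL_da + crossprod(net$W[[conn_name(cn)]],
                                     delta[[cn[2]]][, t])[, 1]
        }
      }
      if (t < n_ev && !clamped_at(l, t + 1)) {
        dL_da <- dL_da + crossprod(net$Wrec[[l]], delta[[l]][, t + 1])[, 1]
      }
      sl <- pren[[l]][, t]
      dz <- dL_da * sl * (1 - sl)
      tg <- trial$targets[[l]]
      if (!is.null(tg) && tg$active[t]) {
        dz <- dz + (acts[[l]][, t] - tg$values[, t])
      }
      delta[[l]][, t] <- dz
    }
  }

  gW <- lapply(net$W, function(m) matrix(0, nrow(m), ncol(m)))
  gWrec <- lapply(net$Wrec, function(m) matrix(0, nrow(m), ncol(m)))
  gb <- lapply(net$b, function(v) numeric(length(v)))
  for (l in COMPUTED_LAYERS) {
    for (t in seq_len(n_ev)) {
      if (clamped_at(l, t)) next
      d <- delta[[l]][, t]
      for (cn in inc[[l]]) {
        nm <- conn_name(cn)
        gW[[nm]] <- gW[[nm]] + tcrossprod(d, acts[[cn[1]]][, t])
      }
      prev <- if (t == 1) rep(0.5, sizes[l]) else acts[[l]][, t - 1]
      gWrec[[l]] <- gWrec[[l]] + tcrossprod(d, prev)
      gb[[l]] <- gb[[l]] + d
    }
  }
  list(gW = gW, gWrec = gWrec, gb = gb,
       loss = trial_loss_from_acts(acts, trial))
}

#' Training configuration
#'
#' @param learning_rate step size for gradient descent (default 0.1, the
#'   recovery-phase value used throughout).
#' @param weight_decay multiplicative decay applied after each update
#'   (default 1e-7).
#' @param momentum exponential smoothing of the per-trial gradient
#'   (normalized momentum, default 0.9): the update is
#'   \code{v <- m * v + (1 - m) * grad}; \code{w <- w - lr * v}, so the
#'   learning rate is the step on the smoothed gradient and keeps its
#'   printed meaning as momentum varies. Velocities reset at each epoch
#'   boundary.
#' @param max_grad_norm per-trial gradient clipping: when the global
#'   2-norm of a trial's gradient exceeds this bound the gradient is
#'   rescaled to it, preserving direction (default 50, above the norms
#'   seen on well-learned trials; Inf disables clipping).
#' @param epochs number of training epochs.
#' @param eval_interval epochs between performance evaluations (default 5).
#' @return a \code{training_config} list.
#' @export
training_config <- function(learning_rate = 0.1, weight_decay = 1e-7,
                            momentum = 0.9, max_grad_norm = 50,
                            epochs = 20L, eval_interval = 5L) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, momentum >= 0,
            momentum < 1, max_grad_norm > 0, epochs >= 1, eval_interval >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, max_grad_norm = max_grad_norm,
                 epochs = as.integer(epochs),
                 eval_interval = as.integer(eval_interval)),
            class = "training_config")
}

CONN_ORDER <- c("Auditory->iSMG", "iSMG->SpeechMotor", "Auditory->aSTG_STS",
                "aSTG_STS->vATL", "vATL->SpeechMotor")

# flatten a trial_spec into the structure the compiled trainer consumes
compile_trial <- function(trial, sizes) {
  n_ev <- trial$n_events
  aud <- trial$inputs$Auditory
  if (is.null(aud)) {
    aud <- list(values = matrix(0, sizes["Auditory"], n_ev),
                clamped = rep(FALSE, n_ev))
  }
  vatl <- trial$inputs$vATL
  tgt_layer_name <- names(trial$targets)[1]
  tgt <- trial$targets[[1]]
  list(n_events = as.integer(n_ev),
       aud_values = aud$values,
       aud_clamped = as.integer(aud$clamped),
       has_vatl_clamp = !is.null(vatl),
       vatl_values = if (!is.null(vatl)) vatl$values,
       vatl_clamped = if (!is.null(vatl)) as.integer(vatl$clamped),
       tgt_layer = if (tgt_layer_name == "vATL") 3L else 4L,
       tgt_values = tgt$values,
       tgt_active = as.integer(tgt$active))
}

#' Train for one epoch
#'
#' Visits the trials once in a seeded random order, updating after every
#' trial with the momentum-smoothed gradient:
#' \code{w <- (w - lr * v) * (1 - decay)} where
#' \code{v <- m * v + (1 - m) * grad}; structurally lesioned (masked)
#' weights stay pinned at zero. Loss is the cross-entropy over
#' each trial's event-masked targets, averaged over trials. The inner loop
#' runs in compiled code; \code{train_epoch_r} is the plain-R reference
#' implementation of the identical update.
#'
#' @param net a \code{cdanet_net}.
#' @param trials non-empty list of \code{trial_spec}s.
#' @param cfg a [training_config()].
#' @param seed integer seed controlling trial order and output noise.
#' @return list(net, mean_loss).
#' @export
train_epoch <- function(net, trials, cfg, seed) {
  stopifnot(length(trials) > 0, inherits(cfg, "training_config"))
  sizes <- net$spec$sizes
  compiled <- lapply(trials, compile_trial, sizes = sizes)
  withr::with_seed(seed, {
    ord <- sample.int(length(trials))
    res <- .train_epoch_cpp(
      net$W[CONN_ORDER], net$Wrec[COMPUTED_LAYERS], net$b[COMPUTED_LAYERS],
      net$mask[CONN_ORDER], net$mask_rec[COMPUTED_LAYERS],
      net$noise_sd[COMPUTED_LAYERS], compiled, ord,
      cfg$learning_rate, cfg$weight_decay, cfg$momentum,
      cfg$max_grad_norm, CE_EPS)
    names(res$W) <- CONN_ORDER
    names(res$Wrec) <- COMPUTED_LAYERS
    names(res$b) <- COMPUTED_LAYERS
    net$W <- res$W
    net$Wrec <- res$Wrec
    net$b <- lapply(res$b, as.numeric)  # arma vectors arrive as n x 1
    net$epoch <- net$epoch + 1L
    list(net = net, mean_loss = res$mean_loss)
  })
}

# Reference implementation of train_epoch in plain R; the compiled path is
# checked against it in the test suite.
#' @rdname train_epoch
#' @export
train_epoch_r <- function(net, trials, cfg, seed) {
  stopifnot(length(trials) > 0, inherits(cfg, "training_config"))
  lr <- cfg$learning_rate
  keep <- 1 - cfg$weight_decay
  mom <- cfg$momentum
  vW <- lapply(net$W, function(m) matrix(0, nrow(m), ncol(m)))
  vWrec <- lapply(net$Wrec, function(m) matrix(0, nrow(m), ncol(m)))
  vb <- lapply(net$b, function(v) numeric(length(v)))
  withr::with_seed(seed, {
    ord <- sample.int(length(trials))
    total <- 0
    for (i in ord) {
      g <- bptt_trial(net, trials[[i]])
      if (!is.finite(g$loss)) {
        stop(sprintf("non-finite loss on trial %d (task %s, item %s)",
                     i, trials[[i]]$task, trials[[i]]$item_id))
      }
      total <- total + g$loss
      if (is.finite(cfg$max_grad_norm)) {
        gnorm <- sqrt(sum(unlist(lapply(g$gW, function(m) sum(m^2)))) +
                        sum(unlist(lapply(g$gWrec, function(m) sum(m^2)))) +
                        sum(unlist(lapply(g$gb, function(v) sum(v^2)))))
        if (gnorm > cfg$max_grad_norm) {
          sc <- cfg$max_grad_norm / gnorm
          g$gW <- lapply(g$gW, `*`, sc)
          g$gWrec <- lapply(g$gWrec, `*`, sc)
          g$gb <- lapply(g$gb, `*`, sc)
        }
      }
      for (nm in names(net$W)) {
        vW[[nm]] <- mom * vW[[nm]] + (1 - mom) * g$gW[[nm]]
        net$W[[nm]] <- (net$W[[nm]] - lr * vW[[nm]]) * keep * net$mask[[nm]]
      }
      for (l in COMPUTED_LAYERS) {
        vWrec[[l]] <- mom * vWrec[[l]] + (1 - mom) * g$gWrec[[l]]
        net$Wrec[[l]] <- (net$Wrec[[l]] - lr * vWrec[[l]]) * keep *
          net$mask_rec[[l]]
        vb[[l]] <- mom * vb[[l]] + (1 - mom) * g$gb[[l]]
        net$b[[l]] <- (net$b[[l]] - lr * vb[[l]]) * keep
      }
    }
    net$epoch <- net$epoch + 1L
    list(net = net, mean_loss = total / length(trials))
  })
}

#' Write / read a network checkpoint
#'
#' Serializes the architecture, all weight matrices, masks, noise levels
#' and the epoch counter to a self-describing JSON text file; the
#' write/read round-trip restores the network bit-exactly.
#'
#' @param net a \code{cdanet_net}.
#' @param path file path.
#' @return \code{path} invisibly (write) or the restored network (read).
#' @export
write_checkpoint <- function(net, path) {
  # doubles are serialized as %.17g strings: 17 significant digits
  # round-trip IEEE doubles exactly, which JSON number formatting does not
  # guarantee
  enc <- function(x) {
    out <- sprintf("%.17g", x)
    dim(out) <- dim(x)
    out
  }
  payload <- list(
    format = "cdanet-checkpoint-v1",
    sizes = as.list(net$spec$sizes),
    connections = lapply(net$spec$connections, as.list),
    W = lapply(net$W, enc),
    Wrec = lapply(net$Wrec, enc),
    b = lapply(net$b, enc),
    mask = lapply(net$mask, enc),
    mask_rec = lapply(net$mask_rec, enc),
    noise_sd = as.list(stats::setNames(sprintf("%.17g", net$noise_sd),
                                       names(net$noise_sd))),
    epoch = net$epoch)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cdanet-checkpoint-v1")) {
    stop("not a cdanet checkpoint: ", path)
  }
  sizes <- unlist(p$sizes)
  # the connection pairs simplify to an n x 2 character matrix
  conns <- if (is.matrix(p$connections)) {
    lapply(seq_len(nrow(p$connections)), function(i) p$connections[i, ])
  } else {
    lapply(p$connections, unlist)
  }
  spec <- structure(list(sizes = sizes, connections = conns),
                    class = "arch_spec")
  dec_mat <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))
  structure(list(spec = spec,
                 W = lapply(p$W, dec_mat),
                 Wrec = lapply(p$Wrec, dec_mat),
                 b = lapply(p$b, as.numeric),
                 mask = lapply(p$mask, dec_mat),
                 mask_rec = lapply(p$mask_rec, dec_mat),
                 noise_sd = stats::setNames(vapply(p$noise_sd, as.numeric, 0),
                                            names(p$noise_sd)),
                 epoch = as.integer(p$epoch)),
            class = "cdanet_net")
}
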