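# Full experiment orchestration: generate a corpus, develop replicate
# networks, lesion the dorsal route, retrain through recovery while
# tracking self-correction, sweep graded ventral damage, and run the
# repeated-measures statistics.

#' Experiment configuration
#'
#' Bundles corpus, architecture, training, lesion and replication
#' parameters. The \code{"paper"} preset uses the full-scale settings (300
#' training words, 10 replicate networks); the \code{"desk"} preset is a
#' reduced configuration for interactive runs and tests (100 words, 2
#' networks). Both develop for 200 epochs: fewer leaves the model short of
#' the adult-like performance the lesion is meant to impair. Remaining
#' defaults are shared: 20-epoch recovery, weight decay 1e-7, evaluation
#' every 5 epochs, 51-word / 108-nonword probe sets, 5 noise probes per
#' item, and the dorsal lesion recipe (20% iSMG to speech-motor pruning,
#' SD 0.2 iSMG output noise). Optimization uses a learning rate of 0.03 on
#' the momentum-smoothed per-trial gradient (momentum 0.9) with per-trial
#' gradient-norm clipping at 50 in both phases; see the methods vignette
#' for how these relate to the original simulator's epoch-batched update
#' regime.
#'
#' @param preset \code{"desk"} or \code{"paper"}.
#' @param seed master seed; every random step derives its own seed from it.
#' @param ... overrides for any configuration field.
#' @return a \code{run_config} list.
#' @export
run_config <- function(preset = c("desk", "paper"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_morae = 20, feature_dim = 20,
    n_words = if (preset == "desk") 100 else 300,
    semantic_dim = 50, semantic_sparsity = 0.2,
    n_probe_words = 51, n_probe_nonwords = 108,
    bigram_tolerance = 0.05,
    ismg_units = 200, astg_units = 60,
    dev_epochs = 200L,
    rec_epochs = 20L,
    learning_rate = 0.03, weight_decay = 1e-7, momentum = 0.9,
    max_grad_norm = 50,
    eval_interval = 5L,
    n_networks = if (preset == "desk") 2L else 10L,
    n_noise_probes = 5L,
    dorsal_prune = 0.2, dorsal_noise = 0.2,
    seed = as.integer(seed), preset = preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# fixed-offset seed derivation: one block of 1000 seeds per network, well
# inside 32-bit range for small master seeds
net_seed <- function(cfg, k, offset = 0L) {
  as.integer(cfg$seed + 1000L * k + offset)
}

cfg_corpus <- function(cfg) {
  generate_corpus(n_morae = cfg$n_morae, feature_dim = cfg$feature_dim,
                  n_words = cfg$n_words, semantic_dim = cfg$semantic_dim,
                  semantic_sparsity = cfg$semantic_sparsity,
                  n_probe_words = cfg$n_probe_words,
                  n_probe_nonwords = cfg$n_probe_nonwords,
                  seed = cfg$seed, tolerance = cfg$bigram_tolerance)
}

cfg_arch <- function(cfg) {
  arch_spec(mora_dim = cfg$feature_dim, semantic_dim = cfg$semantic_dim,
            ismg_units = cfg$ismg_units, astg_units = cfg$astg_units)
}

#' Develop one network
#'
#' Initializes a network and trains it on the three-task development
#' schedule (per word and epoch: 1 repetition, 3 comprehension, 2 speaking
#' trials in random order) for \code{cfg$dev_epochs} epochs.
#'
#' @param cfg a [run_config()].
#' @param corpus the training corpus.
#' @param network_index replicate index (drives the derived seeds).
#' @param verbose print a progress line every 10 epochs.
#' @return the trained \code{cdanet_net} with a \code{loss_log} attribute.
#' @export
run_development <- function(cfg, corpus, network_index = 1L,
                            verbose = FALSE) {
  net <- init_network(cfg_arch(cfg), seed = net_seed(cfg, network_index))
  tcfg <- training_config(cfg$learning_rate, cfg$weight_decay,
                          cfg$momentum, cfg$max_grad_norm,
                          cfg$dev_epochs, cfg$eval_interval)
  losses <- numeric(cfg$dev_epochs)
  for (e in seq_len(cfg$dev_epochs)) {
    trials <- build_epoch(corpus, "development",
                          seed = net_seed(cfg, network_index, e))
    res <- train_epoch(net, trials, tcfg,
                       seed = net_seed(cfg, network_index, e))
    net <- res$net
    losses[e] <- res$mean_loss
    if (verbose && e %% 10 == 0) {
      message(sprintf("network %d development epoch %d/%d: mean loss %.4f",
                      network_index, e, cfg$dev_epochs, res$mean_loss))
    }
  }
  attr(net, "loss_log") <- losses
  net
}

#' Lesion the dorsal route of a developed network
#'
#' @param net a developed \code{cdanet_net}.
#' @param cfg a [run_config()] (pruning proportion and noise SD).
#' @param network_index replicate index.
#' @return the conduction-aphasic network.
#' @export
lesion_dorsal <- function(net, cfg, network_index = 1L) {
  spec <- lesion_spec(
    link_removals = c("iSMG->SpeechMotor" = cfg$dorsal_prune),
    output_noise = c(iSMG = cfg$dorsal_noise),
    seed = net_seed(cfg, network_index, 900L))
  apply_lesion(net, spec)
}

probe_both_sets <- function(net, corpus, cfg, seed) {
  rw <- probe_double_repetition(net, corpus$probe_words,
                                corpus$mora_inventory,
                                cfg$n_noise_probes, seed = seed)
  rn <- probe_double_repetition(net, corpus$probe_nonwords,
                                corpus$mora_inventory,
                                cfg$n_noise_probes, seed = seed + 1L)
  list(words = rw, nonwords = rn)
}

#' Recovery phase with self-correction trajectory
#'
#' Retrains a dorsal-lesioned network on the four-task recovery schedule
#' (adds the double-repetition trial; comprehension target extended to all
#' nine events) for \code{cfg$rec_epochs} epochs, probing double
#' repetition on the word and nonword sets every \code{eval_interval}
#' epochs. The structural lesion and the iSMG noise stay in place
#' throughout.
#'
#' @param net the lesioned network.
#' @param corpus the training corpus.
#' @param cfg a [run_config()].
#' @param network_index replicate index.
#' @return list: the recovered \code{net}, a \code{trajectory} data.frame
#'   (epoch, lexicality, rate, n_first_errors), and the epoch-20
#'   \code{final_records} probe data.frames.
#' @export
run_recovery <- function(net, corpus, cfg, network_index = 1L) {
  tcfg <- training_config(cfg$learning_rate, cfg$weight_decay,
                          cfg$momentum, cfg$max_grad_norm,
                          cfg$rec_epochs, cfg$eval_interval)
  traj <- list()
  final_records <- NULL
  for (e in seq_len(cfg$rec_epochs)) {
    trials <- build_epoch(corpus, "recovery",
                          seed = net_seed(cfg, network_index, 500L + e))
    res <- train_epoch(net, trials, tcfg,
                       seed = net_seed(cfg, network_index, 500L + e))
    net <- res$net
    if (e %% cfg$eval_interval == 0) {
      pr <- probe_both_sets(net, corpus, cfg,
                            seed = net_seed(cfg, network_index,
                                            700L + 2L * (e %/% cfg$eval_interval)))
      cw <- cda_rate(pr$words)
      cn <- cda_rate(pr$nonwords)
      traj[[length(traj) + 1L]] <- data.frame(
        network = network_index, epoch = e,
        lexicality = c("word", "nonword"),
        rate = c(cw$rate, cn$rate),
        n_first_errors = c(cw$n_first_errors, cn$n_first_errors))
      if (e == cfg$rec_epochs) final_records <- pr
    }
  }
  list(net = net, trajectory = do.call(rbind, traj),
       final_records = final_records)
}

#' Ventral diagnostic-lesion severity sweep
#'
#' Applies each of the 20 severity levels to an independent copy of the
#' recovered network (plus the level-0 baseline, i.e. no additional
#' damage) and probes double repetition on both item sets. The baseline
#' row reuses the same probe seed as the levels so a level with all-zero
#' parameters reproduces it exactly.
#'
#' @param net the recovered (post-recovery) network.
#' @param corpus the training corpus.
#' @param cfg a [run_config()].
#' @param network_index replicate index.
#' @return data.frame: network, level (0 = baseline), lexicality, rate,
#'   n_first_errors.
#' @export
run_sweep <- function(net, corpus, cfg, network_index = 1L) {
  grid <- severity_grid()
  rows <- list()
  for (lev in 0:20) {
    damaged <- if (lev == 0) net else {
      apply_severity(net, as.list(grid[grid$level == lev, ]),
                     seed = net_seed(cfg, network_index, 750L + lev))
    }
    pr <- probe_both_sets(damaged, corpus, cfg,
                          seed = net_seed(cfg, network_index, 780L))
    cw <- cda_rate(pr$words)
    cn <- cda_rate(pr$nonwords)
    rows[[length(rows) + 1L]] <- data.frame(
      network = network_index, level = lev,
      lexicality = c("word", "nonword"),
      rate = c(cw$rate, cn$rate),
      n_first_errors = c(cw$n_first_errors, cn$n_first_errors))
  }
  do.call(rbind, rows)
}

run_one_network <- function(cfg, corpus, k, verbose = FALSE) {
  net <- run_development(cfg, corpus, k, verbose = verbose)
  acc_pre <- evaluate_tasks(net, corpus$probe_words, corpus$mora_inventory,
                            all_words = corpus$train_words,
                            n_noise_probes = cfg$n_noise_probes,
                            seed = net_seed(cfg, k, 850L))
  net <- lesion_dorsal(net, cfg, k)
  acc_post <- evaluate_tasks(net, corpus$probe_words, corpus$mora_inventory,
                             all_words = corpus$train_words,
                             n_noise_probes = cfg$n_noise_probes,
                             seed = net_seed(cfg, k, 851L))
  rec <- run_recovery(net, corpus, cfg, k)
  sweep <- run_sweep(rec$net, corpus, cfg, k)
  list(network = k,
       accuracies = rbind(
         data.frame(network = k, stage = "pre_lesion",
                    task = names(acc_pre), accuracy = unname(acc_pre)),
         data.frame(network = k, stage = "post_lesion",
                    task = names(acc_post), accuracy = unname(acc_post))),
       trajectory = rec$trajectory,
       final_records = rec$final_records,
       sweep = sweep)
}

traj_rate <- function(traj, lex, ep) {
  traj$rate[traj$lexicality == lex & traj$epoch == ep]
}

sweep_rate <- function(sweep, lex, lev) {
  sweep$rate[sweep$lexicality == lex & sweep$level == lev]
}

#' Run the complete experiment
#'
#' Generates the corpus, then for each replicate network: development,
#' dorsal lesioning (with pre/post task-accuracy evaluation), 20-epoch
#' recovery with the self-correction trajectory, and the ventral severity
#' sweep. Aggregates per-network self-correction rates and runs the four
#' repeated-measures contrasts (lexicality; early vs late recovery; sweep
#' effect for words and for nonwords; lexicality-by-damage interaction).
#' Networks that fail are skipped with a warning; at least two survivors
#' are required for the statistics.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory for CSV/JSON outputs
#'   (\code{probe_records.csv}, \code{trajectory.csv}, \code{sweep.csv},
#'   \code{accuracies.csv}, \code{stats.json}).
#' @param verbose print progress.
#' @return object of class \code{cdanet_experiment}.
#' @export
run_all <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  corpus <- cfg_corpus(cfg)
  runs <- list()
  for (k in seq_len(cfg$n_networks)) {
    r <- tryCatch(run_one_network(cfg, corpus, k, verbose = verbose),
                  error = function(e) {
                    warning(sprintf("network %d failed: %s", k,
                                    conditionMessage(e)))
                    NULL
                  })
    if (!is.null(r)) runs[[length(runs) + 1L]] <- r
  }
  if (length(runs) < 2) stop("fewer than 2 networks completed; no statistics")

  trajectory <- do.call(rbind, lapply(runs, `[[`, "trajectory"))
  sweep <- do.call(rbind, lapply(runs, `[[`, "sweep"))
  accuracies <- do.call(rbind, lapply(runs, `[[`, "accuracies"))
  probe_records <- do.call(rbind, lapply(runs, function(r) {
    rbind(cbind(network = r$network, r$final_records$words),
          cbind(network = r$network, r$final_records$nonwords))
  }))

  per_net <- data.frame(
    network = vapply(runs, `[[`, 0L, "network"),
    word_rate = vapply(runs, function(r)
      traj_rate(r$trajectory, "word", cfg$rec_epochs), 0),
    nonword_rate = vapply(runs, function(r)
      traj_rate(r$trajectory, "nonword", cfg$rec_epochs), 0),
    word_rate_ep5 = vapply(runs, function(r)
      traj_rate(r$trajectory, "word", cfg$eval_interval), 0),
    word_base = vapply(runs, function(r)
      sweep_rate(r$sweep, "word", 0), 0),
    word_lev20 = vapply(runs, function(r)
      sweep_rate(r$sweep, "word", 20), 0),
    nonword_base = vapply(runs, function(r)
      sweep_rate(r$sweep, "nonword", 0), 0),
    nonword_lev20 = vapply(runs, function(r)
      sweep_rate(r$sweep, "nonword", 20), 0))

  stats <- list(
    lexicality = repeated_measures_2level(per_net$word_rate,
                                          per_net$nonword_rate),
    recovery = repeated_measures_2level(per_net$word_rate,
                                        per_net$word_rate_ep5),
    sweep_words = repeated_measures_2level(per_net$word_base,
                                           per_net$word_lev20),
    sweep_nonwords = repeated_measures_2level(per_net$nonword_base,
                                              per_net$nonword_lev20),
    interaction = interaction_2x2(per_net$word_base, per_net$word_lev20,
                                  per_net$nonword_base, per_net$nonword_lev20))

  result <- structure(list(config = cfg, corpus = corpus,
                           per_network = per_net, trajectory = trajectory,
                           sweep = sweep, accuracies = accuracies,
                           probe_records = probe_records, stats = stats,
                           n_completed = length(runs)),
                      class = "cdanet_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.cdanet_experiment <- function(x, ...) {
  cat(sprintf("cdanet experiment: %d network(s), preset '%s', seed %d\n",
              x$n_completed, x$config$preset, x$config$seed))
  cat(sprintf("  post-recovery self-correction rate: words %.3f, nonwords %.3f\n",
              mean(x$per_network$word_rate, na.rm = TRUE),
              mean(x$per_network$nonword_rate, na.rm = TRUE)))
  s <- x$stats$lexicality
  cat(sprintf("  lexicality contrast: F(%d, %d) = %.2f, p = %.4g\n",
              s$df[1], s$df[2], s$F, s$p))
  invisible(x)
}

#' Write experiment outputs
#'
#' @param result a \code{cdanet_experiment}.
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir} invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$probe_records,
                   file.path(out_dir, "probe_records.csv"), row.names = FALSE)
  utils::write.csv(result$trajectory,
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  utils::write.csv(result$sweep, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(result$accuracies,
                   file.path(out_dir, "accuracies.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(result$stats, function(s) list(F = s$F, df = s$df, p = s$p,
                                          cohen_d = s$cohen_d, n = s$n)),
    file.path(out_dir, "stats.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
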