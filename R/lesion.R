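# Structural lesions (link pruning) and cortical noise.
#
# A lesion removes a fixed proportion of individual weight entries from
# named connections (mask 0, weight 0; masks survive training) and/or sets
# per-layer Gaussian output-noise levels. The dorsal recipe that produces
# conduction aphasia removes 20% of iSMG->SpeechMotor links and adds
# SD 0.2 noise to iSMG outputs.

round_half_up <- function(x) floor(x + 0.5)

#' Build a lesion specification
#'
#' @param link_removals named numeric vector: names are connection labels
#'   (\code{"src->tgt"} for feedforward, \code{"rec:layer"} for a layer's
#'   recurrent projection), values are proportions in \[0, 1\] of weight
#'   entries to prune.
#' @param output_noise named numeric vector: Gaussian output-noise SD per
#'   layer.
#' @param seed integer seed for the random link selection.
#' @return a \code{lesion_spec}.
#' @export
lesion_spec <- function(link_removals = numeric(0),
                        output_noise = numeric(0), seed = 1L) {
  if (length(link_removals) && (any(link_removals < 0) ||
                                any(link_removals > 1))) {
    stop("removal proportions must lie in [0, 1]")
  }
  if (length(output_noise) && any(output_noise < 0)) {
    stop("noise SDs must be non-negative")
  }
  structure(list(link_removals = link_removals,
                 output_noise = output_noise, seed = as.integer(seed)),
            class = "lesion_spec")
}

#' The dorsal lesion producing conduction aphasia
#'
#' Removes 20% of the links from the iSMG layer to the speech-motor layer
#' and adds Gaussian noise (SD 0.2) to iSMG unit outputs.
#'
#' @param seed integer seed for link selection.
#' @return a \code{lesion_spec}.
#' @export
dorsal_lesion_spec <- function(seed = 1L) {
  lesion_spec(link_removals = c("iSMG->SpeechMotor" = 0.2),
              output_noise = c(iSMG = 0.2), seed = seed)
}

resolve_conn <- function(net, label) {
  if (startsWith(label, "rec:")) {
    l <- sub("^rec:", "", label)
    if (!l %in% names(net$Wrec)) stop("unknown recurrent connection: ", label)
    list(kind = "rec", key = l)
  } else {
    if (!label %in% names(net$W)) stop("unknown connection: ", label)
    list(kind = "ff", key = label)
  }
}

#' Apply a lesion to a network
#'
#' For every (connection, p) pair, exactly \code{round(p * L)} distinct
#' weight entries (L the matrix size, round half up) are selected uniformly
#' at random without replacement, among entries not already pruned, and set
#' to zero with mask zero; masked entries stay zero under any subsequent
#' training. For every (layer, sd) pair the layer's output-noise SD is set
#' to sd; the noise applies at every forward event until changed.
#'
#' @param net a \code{cdanet_net}.
#' @param spec a [lesion_spec()].
#' @return the lesioned network.
#' @export
apply_lesion <- function(net, spec) {
  stopifnot(inherits(net, "cdanet_net"), inherits(spec, "lesion_spec"))
  withr::with_seed(spec$seed, {
    for (label in names(spec$link_removals)) {
      p <- spec$link_removals[[label]]
      rc <- resolve_conn(net, label)
      m <- if (rc$kind == "ff") net$mask[[rc$key]] else net$mask_rec[[rc$key]]
      n_total <- length(m)
      n_remove <- round_half_up(p * n_total)
      if (n_remove > 0) {
        alive <- which(m != 0)
        if (n_remove > length(alive)) n_remove <- length(alive)
        hit <- alive[sample.int(length(alive), n_remove)]
        m[hit] <- 0
      }
      if (rc$kind == "ff") {
        net$mask[[rc$key]] <- m
        net$W[[rc$key]] <- net$W[[rc$key]] * m
      } else {
        net$mask_rec[[rc$key]] <- m
        net$Wrec[[rc$key]] <- net$Wrec[[rc$key]] * m
      }
    }
    for (l in names(spec$output_noise)) {
      if (!l %in% names(net$noise_sd)) stop("unknown layer: ", l)
      net$noise_sd[[l]] <- spec$output_noise[[l]]
    }
  })
  net
}

#' The 20-level ventral diagnostic severity grid
#'
#' Equal-interval grids over 20 damage levels: at level k, output noise
#' 0.01k (vATL) and 0.005k (aSTG/STS), and pruning of 0.5k% of
#' vATL-incoming links and 0.25k% of aSTG/STS-incoming links. Level 1 is
#' (0.01, 0.005, 0.5%, 0.25%); level 20 is (0.2, 0.1, 10%, 5%).
#'
#' @return data.frame with columns level, vatl_noise, astg_noise,
#'   vatl_prune, astg_prune.
#' @export
severity_grid <- function() {
  k <- 1:20
  data.frame(level = k,
             vatl_noise = 0.01 * k,
             astg_noise = 0.005 * k,
             vatl_prune = 0.005 * k,
             astg_prune = 0.0025 * k)
}

incoming_labels <- function(net, layer) {
  ff <- names(net$W)[vapply(net$spec$connections,
                            function(cn) cn[2] == layer, TRUE)]
  c(ff, paste0("rec:", layer))
}

#' Apply one ventral diagnostic severity level
#'
#' Prunes the level's proportion of all links incoming to the vATL and
#' aSTG/STS layers (feedforward and recurrent entries alike) and sets the
#' two layers' output-noise SDs. Levels are independent doses: each is
#' applied to a fresh copy of the recovered network, never cumulatively.
#'
#' @param net a post-recovery \code{cdanet_net} (copied, not modified).
#' @param level one row of [severity_grid()] (or a list with the same
#'   fields).
#' @param seed integer seed for link selection.
#' @return the additionally lesioned copy.
#' @export
apply_severity <- function(net, level, seed = 1L) {
  removals <- c(
    stats::setNames(rep(level$vatl_prune, length(incoming_labels(net, "vATL"))),
                    incoming_labels(net, "vATL")),
    stats::setNames(rep(level$astg_prune,
                        length(incoming_labels(net, "aSTG_STS"))),
                    incoming_labels(net, "aSTG_STS")))
  noise <- c(vATL = level$vatl_noise, aSTG_STS = level$astg_noise)
  apply_lesion(net, lesion_spec(removals, noise, seed = seed))
}
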