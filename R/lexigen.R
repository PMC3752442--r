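#' Build an artificial mora inventory
#'
#' Creates the inventory of morae (subsyllabic timing units) used as the
#' model's phonological tokens. Each mora carries a binary feature vector;
#' one mora is presented to the auditory layer per time event, and the
#' speech-motor layer is scored against the same codes.
#'
#' By default morae are coded localist (one-hot over the inventory), the
#' simplest scheme in which all codes are pairwise distinct and equidistant.
#' When \code{feature_dim < n_morae} a one-hot code is impossible and
#' distinct random binary vectors are drawn instead; \code{coding =
#' "distributed"} forces that scheme.
#'
#' @param n_morae number of morae (at least 2).
#' @param feature_dim length of each binary feature vector.
#' @param seed integer seed; the inventory is deterministic given the seed.
#' @param coding \code{"onehot"} (default) or \code{"distributed"}.
#' @return A list of morae, each a list with \code{id}, \code{label} and a
#'   0/1 \code{features} vector, plus attribute \code{feature_dim}.
#' @examples
#' inv <- build_inventory(8, 8, seed = 1)
#' length(inv)
#' @export
build_inventory <- function(n_morae, feature_dim, seed,
                            coding = c("onehot", "distributed")) {
  coding <- match.arg(coding)
  if (n_morae < 2) stop("need at least 2 morae")
  if (feature_dim < 1) stop("feature_dim must be positive")
  if (2^feature_dim < n_morae) {
    stop(sprintf(
      "cannot code %d distinct morae with %d binary features (capacity %d)",
      n_morae, feature_dim, 2^feature_dim))
  }
  if (coding == "onehot" && feature_dim < n_morae) coding <- "distributed"

  feats <- withr::with_seed(seed, {
    if (coding == "onehot") {
      diag(1, feature_dim)[seq_len(n_morae), , drop = FALSE]
    } else {
      # rejection-sample pairwise-distinct binary codes
      got <- matrix(NA_real_, n_morae, feature_dim)
      seen <- character(0)
      k <- 0L
      for (attempt in seq_len(1000L * n_morae)) {
        v <- stats::rbinom(feature_dim, 1, 0.5)
        key <- paste(v, collapse = "")
        if (!key %in% seen) {
          k <- k + 1L
          got[k, ] <- v
          seen <- c(seen, key)
          if (k == n_morae) break
        }
      }
      if (k < n_morae) stop("could not sample distinct mora codes")
      got
    }
  })
  inv <- lapply(seq_len(n_morae), function(i) {
    list(id = i, label = sprintf("m%02d", i), features = as.numeric(feats[i, ]))
  })
  attr(inv, "feature_dim") <- feature_dim
  inv
}

#' Feature matrix of an inventory
#'
#' @param inventory a mora inventory from [build_inventory()].
#' @return numeric matrix, one column per mora (feature_dim x n_morae),
#'   columns ordered by mora id.
#' @export
inventory_matrix <- function(inventory) {
  m <- vapply(inventory, function(x) x$features,
              numeric(length(inventory[[1]]$features)))
  matrix(m, nrow = length(inventory[[1]]$features))
}

new_item <- function(morae, semantics, is_word, accent_class) {
  list(morae = as.integer(morae), semantics = as.numeric(semantics),
       is_word = isTRUE(is_word), accent_class = as.character(accent_class))
}

triple_key <- function(morae) paste(morae, collapse = ",")

#' Generate a word lexicon over a mora inventory
#'
#' Samples \code{n_words} distinct 3-mora forms and pairs each with a sparse
#' random binary semantic vector (all vectors pairwise distinct, each with
#' \code{round(semantic_sparsity * semantic_dim)} active bits). Each word is
#' tagged with one of four pitch-accent classes; the tag is bookkeeping for
#' probe-set matching and is never encoded in the input vectors.
#'
#' @param inventory mora inventory.
#' @param n_words number of words; must not exceed the number of distinct
#'   mora triples (\code{n_morae^3}).
#' @param semantic_dim length of the semantic vectors (default 50).
#' @param semantic_sparsity fraction of active semantic bits (default 0.2).
#' @param seed integer seed.
#' @return list of lexicon items (\code{morae}, \code{semantics},
#'   \code{is_word}, \code{accent_class}).
#' @export
build_lexicon <- function(inventory, n_words, semantic_dim = 50,
                          semantic_sparsity = 0.2, seed = 1L) {
  n_m <- length(inventory)
  n_triples <- n_m^3
  if (n_words > n_triples) {
    stop(sprintf("requested %d words but only %d distinct mora triples exist",
                 n_words, n_triples))
  }
  k_active <- round(semantic_sparsity * semantic_dim)
  if (k_active < 1) stop("semantic sparsity too low: no active bits")
  if (choose(semantic_dim, k_active) < n_words) {
    stop("semantic code capacity exceeded")
  }
  withr::with_seed(seed, {
    # sample distinct triples by index into the n^3 enumeration
    idx <- sample.int(n_triples, n_words)
    i1 <- (idx - 1L) %/% (n_m^2)
    i2 <- ((idx - 1L) %/% n_m) %% n_m
    i3 <- (idx - 1L) %% n_m
    triples <- cbind(i1 + 1L, i2 + 1L, i3 + 1L)

    sem_seen <- character(0)
    sems <- vector("list", n_words)
    for (w in seq_len(n_words)) {
      repeat {
        v <- numeric(semantic_dim)
        v[sample.int(semantic_dim, k_active)] <- 1
        key <- paste(v, collapse = "")
        if (!key %in% sem_seen) {
          sem_seen <- c(sem_seen, key)
          sems[[w]] <- v
          break
        }
      }
    }
    accents <- sample(paste0("accent", 0:3), n_words, replace = TRUE)
    lapply(seq_len(n_words), function(w) {
      new_item(triples[w, ], sems[[w]], TRUE, accents[w])
    })
  })
}

# Pooled position-free mora-bigram counts of a set of 3-mora items.
# Each item contributes its two adjacent pairs. Returns a named count
# vector over "a-b" bigram keys.
bigram_counts <- function(items) {
  keys <- unlist(lapply(items, function(it) {
    m <- it$morae
    c(paste(m[1], m[2], sep = "-"), paste(m[2], m[3], sep = "-"))
  }))
  table_to_named <- table(keys)
  stats::setNames(as.numeric(table_to_named), names(table_to_named))
}

#' Chi-square distance between two bigram profiles
#'
#' Symmetric chi-square distance between the relative-frequency profiles of
#' two pooled bigram count vectors:
#' \eqn{\frac12 \sum_i (p_i - q_i)^2 / (p_i + q_i)} over cells where
#' \eqn{p_i + q_i > 0}. Zero iff the relative profiles are identical.
#'
#' @param counts_a,counts_b named count vectors as produced internally from
#'   item sets; any two named numeric vectors work.
#' @return non-negative scalar.
#' @export
bigram_chisq_distance <- function(counts_a, counts_b) {
  keys <- union(names(counts_a), names(counts_b))
  pa <- stats::setNames(numeric(length(keys)), keys)
  pb <- pa
  pa[names(counts_a)] <- counts_a
  pb[names(counts_b)] <- counts_b
  p <- pa / sum(pa)
  q <- pb / sum(pb)
  s <- p + q
  ok <- s > 0
  0.5 * sum((p[ok] - q[ok])^2 / s[ok])
}

#' Draw the probe word set and bigram-matched nonwords
#'
#' Samples \code{n_words} probe words from the lexicon and constructs
#' \code{n_nonwords} nonwords: 3-mora forms absent from the lexicon whose
#' pooled mora-bigram frequency profile matches the probe-word profile.
#' Nonwords are assembled by quota sampling over the probe-word bigram
#' distribution (first pair drawn from the remaining bigram quota, second
#' pair drawn from quota entries chained on the middle mora), rejecting any
#' form that collides with a trained word or an already-chosen nonword.
#' The candidate set is accepted when the symmetric chi-square distance
#' between the two bigram profiles falls below \code{tolerance}.
#'
#' @param lexicon word lexicon from [build_lexicon()].
#' @param n_words probe-word count (default 51).
#' @param n_nonwords nonword count (default 108).
#' @param seed integer seed.
#' @param tolerance chi-square distance acceptance threshold (default 0.05).
#' @param max_attempts resampling attempts before giving up.
#' @return list with elements \code{probe_words} and \code{probe_nonwords}.
#' @export
sample_probe_sets <- function(lexicon, n_words = 51, n_nonwords = 108,
                              seed = 1L, tolerance = 0.05,
                              max_attempts = 50L) {
  if (n_words > length(lexicon)) stop("probe word count exceeds lexicon size")
  withr::with_seed(seed, {
    probe_words <- lexicon[sort(sample.int(length(lexicon), n_words))]
    if (n_nonwords == 0) {
      return(list(probe_words = probe_words, probe_nonwords = list()))
    }
    word_keys <- vapply(lexicon, function(it) triple_key(it$morae), "")
    wc <- bigram_counts(probe_words)
    accent_pool <- vapply(probe_words, function(it) it$accent_class, "")

    best <- NULL
    best_d <- Inf
    for (attempt in seq_len(max_attempts)) {
      cand <- .sample_nonword_set(wc, n_nonwords, word_keys)
      if (is.null(cand)) next
      ref <- .refine_nonword_set(cand, wc, word_keys, tolerance)
      if (ref$distance < best_d) {
        best <- ref$items
        best_d <- ref$distance
      }
      if (best_d <= tolerance) break
    }
    if (is.null(best) || best_d > tolerance) {
      stop(sprintf(
        "bigram matching failed: best chi-square distance %.4f > tolerance %.4f after %d attempts",
        best_d, tolerance, max_attempts))
    }
    # accent classes mirror the probe-word class distribution
    best <- lapply(best, function(it) {
      it$accent_class <- sample(accent_pool, 1)
      it
    })
    list(probe_words = probe_words, probe_nonwords = best)
  })
}

# One candidate nonword set built by quota sampling on the word bigram
# profile. Returns NULL if assembly stalls.
.sample_nonword_set <- function(word_counts, n_nonwords, forbidden_keys) {
  # integer quota: 2 bigrams per nonword, proportional to the word profile
  # (largest-remainder apportionment)
  total <- 2L * n_nonwords
  p <- word_counts / sum(word_counts)
  raw <- p * total
  quota <- floor(raw)
  rem <- total - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  first_mora <- as.integer(sub("-.*", "", names(quota)))
  second_mora <- as.integer(sub(".*-", "", names(quota)))

  chosen <- vector("list", n_nonwords)
  chosen_keys <- character(0)
  n_done <- 0L
  stall <- 0L
  observed <- sort(unique(c(first_mora, second_mora)))
  while (n_done < n_nonwords && stall < 200L) {
    if (stall >= 100L) {
      # tiny triple spaces: most proposals collide, so complete the set
      # exhaustively from the unused triples over the observed morae and
      # let the refinement pass fix the profile
      grid <- expand.grid(a = observed, b = observed, c = observed)
      keys_all <- paste(grid$a, grid$b, grid$c, sep = ",")
      avail <- setdiff(keys_all, c(forbidden_keys, chosen_keys))
      need <- n_nonwords - n_done
      if (length(avail) < need) return(NULL)
      fill <- sample(avail, need)
      for (key in fill) {
        n_done <- n_done + 1L
        chosen[[n_done]] <- new_item(
          as.integer(strsplit(key, ",", fixed = TRUE)[[1]]),
          numeric(0), FALSE, "accent0")
        chosen_keys <- c(chosen_keys, key)
      }
      break
    }
    rq <- pmax(quota, 0)
    if (sum(rq) == 0) rq <- word_counts  # quota exhausted: fall back
    b1 <- sample.int(length(rq), 1, prob = rq)
    a <- first_mora[b1]; b <- second_mora[b1]
    cont <- which(first_mora == b & pmax(quota, 0) > 0)
    if (length(cont) == 0) cont <- which(first_mora == b)
    if (length(cont) > 0) {
      b2 <- if (length(cont) == 1) cont else {
        w2 <- pmax(quota[cont], 0)
        if (sum(w2) == 0) w2 <- word_counts[cont]
        cont[sample.int(length(cont), 1, prob = w2)]
      }
      third <- second_mora[b2]
    } else {
      # no profile bigram continues from b: draw the third mora from the
      # profile's second-position marginal to keep mora frequencies close
      b2 <- NA_integer_
      marg <- tapply(word_counts, second_mora, sum)
      third <- as.integer(names(marg))[
        sample.int(length(marg), 1, prob = as.numeric(marg))]
    }
    triple <- c(a, b, third)
    key <- triple_key(triple)
    if (key %in% forbidden_keys || key %in% chosen_keys) {
      stall <- stall + 1L
      next
    }
    stall <- 0L
    n_done <- n_done + 1L
    chosen[[n_done]] <- new_item(triple, numeric(0), FALSE, "accent0")
    chosen_keys <- c(chosen_keys, key)
    quota[b1] <- quota[b1] - 1L
    if (!is.na(b2)) quota[b2] <- quota[b2] - 1L
  }
  if (n_done < n_nonwords) return(NULL)
  chosen
}

# Hill-climbing refinement of a candidate nonword set: repeatedly propose
# replacing one nonword with a fresh form assembled from the current
# bigram deficit, accepting proposals that reduce the chi-square distance
# to the word profile. Makes the matching reliable for small corpora where
# one-shot quota sampling rarely lands under tolerance.
.refine_nonword_set <- function(items, word_counts, forbidden_keys,
                                tolerance, n_iter = 400L) {
  d <- bigram_chisq_distance(word_counts, bigram_counts(items))
  keys <- vapply(items, function(it) triple_key(it$morae), "")
  first_mora <- as.integer(sub("-.*", "", names(word_counts)))
  second_mora <- as.integer(sub(".*-", "", names(word_counts)))
  target <- word_counts / sum(word_counts) * (2 * length(items))
  for (iter in seq_len(n_iter)) {
    if (d <= tolerance) break
    vi <- sample.int(length(items), 1)
    cc <- bigram_counts(items[-vi])
    deficit <- target
    deficit[names(cc)[names(cc) %in% names(deficit)]] <-
      deficit[names(cc)[names(cc) %in% names(deficit)]] -
      cc[names(cc) %in% names(deficit)]
    w1 <- pmax(deficit, 0.02)
    b1 <- sample.int(length(w1), 1, prob = w1)
    a <- first_mora[b1]; b <- second_mora[b1]
    cont <- which(first_mora == b)
    third <- if (length(cont) > 0) {
      w2 <- pmax(deficit[cont], 0.02)
      second_mora[cont[sample.int(length(cont), 1, prob = w2)]]
    } else {
      marg <- tapply(word_counts, second_mora, sum)
      as.integer(names(marg))[sample.int(length(marg), 1,
                                         prob = as.numeric(marg))]
    }
    key <- triple_key(c(a, b, third))
    if (key %in% forbidden_keys || key %in% keys[-vi]) next
    prop <- items
    prop[[vi]] <- new_item(c(a, b, third), numeric(0), FALSE, "accent0")
    d2 <- bigram_chisq_distance(word_counts, bigram_counts(prop))
    if (d2 < d) {
      items <- prop
      keys[vi] <- key
      d <- d2
    }
  }
  list(items = items, distance = d)
}

#' Generate a complete corpus
#'
#' Convenience wrapper building the mora inventory, the training lexicon and
#' both probe sets in one call. Probe words are a subset of the training
#' words; nonwords never collide with any trained word.
#'
#' @param n_morae,feature_dim inventory parameters (defaults 20/20, one-hot).
#' @param n_words training vocabulary size (default 300).
#' @param semantic_dim,semantic_sparsity semantic code parameters.
#' @param n_probe_words,n_probe_nonwords probe-set sizes (defaults 51/108).
#' @param seed master seed for the corpus.
#' @param tolerance bigram-matching tolerance passed to
#'   [sample_probe_sets()].
#' @return object of class \code{cdanet_corpus}.
#' @examples
#' co <- generate_corpus(n_morae = 8, n_words = 30, n_probe_words = 10,
#'                       n_probe_nonwords = 20, seed = 1)
#' print(co)
#' @export
generate_corpus <- function(n_morae = 20, feature_dim = 20, n_words = 300,
                            semantic_dim = 50, semantic_sparsity = 0.2,
                            n_probe_words = 51, n_probe_nonwords = 108,
                            seed = 1L, tolerance = 0.05) {
  inv <- build_inventory(n_morae, feature_dim, seed = seed)
  lex <- build_lexicon(inv, n_words, semantic_dim, semantic_sparsity,
                       seed = seed + 1L)
  probes <- sample_probe_sets(lex, n_probe_words, n_probe_nonwords,
                              seed = seed + 2L, tolerance = tolerance)
  structure(list(mora_inventory = inv, train_words = lex,
                 probe_words = probes$probe_words,
                 probe_nonwords = probes$probe_nonwords,
                 seed = as.integer(seed)),
            class = "cdanet_corpus")
}

#' @export
print.cdanet_corpus <- function(x, ...) {
  cat(sprintf(
    "cdanet corpus: %d morae, %d train words, %d probe words, %d probe nonwords (seed %d)\n",
    length(x$mora_inventory), length(x$train_words), length(x$probe_words),
    length(x$probe_nonwords), x$seed))
  invisible(x)
}

fmt_bits <- function(v) paste(as.integer(v), collapse = "")

item_line <- function(it) {
  paste(if (it$is_word) "WORD" else "NONWORD",
        triple_key(it$morae),
        if (length(it$semantics)) fmt_bits(it$semantics) else "-",
        it$accent_class,
        sep = "\t")
}

parse_item_line <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 4 || !f[1] %in% c("WORD", "NONWORD")) {
    stop(sprintf("corpus parse error at line %d: %s", lineno, line))
  }
  morae <- suppressWarnings(as.integer(strsplit(f[2], ",", fixed = TRUE)[[1]]))
  if (length(morae) != 3 || anyNA(morae)) {
    stop(sprintf("corpus parse error at line %d: bad mora triple", lineno))
  }
  sem <- if (f[3] == "-") numeric(0) else {
    bits <- suppressWarnings(as.integer(strsplit(f[3], "")[[1]]))
    if (anyNA(bits) || any(!bits %in% 0:1)) {
      stop(sprintf("corpus parse error at line %d: bad semantic bits", lineno))
    }
    as.numeric(bits)
  }
  new_item(morae, sem, f[1] == "WORD", f[4])
}

#' Write a corpus to a plain-text file
#'
#' Line-oriented UTF-8 format: a header with the seed and the mora
#' inventory (id, label, feature bits), then one tab-separated record per
#' item grouped into TRAIN, PROBE_WORDS and PROBE_NONWORDS sections.
#' [read_corpus()] reproduces the corpus exactly.
#'
#' @param corpus a \code{cdanet_corpus}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- c("# cdanet corpus v1",
             paste0("SEED\t", corpus$seed))
  for (m in corpus$mora_inventory) {
    lines <- c(lines, paste("MORA", m$id, m$label, fmt_bits(m$features),
                            sep = "\t"))
  }
  for (sec in c("TRAIN", "PROBE_WORDS", "PROBE_NONWORDS")) {
    items <- switch(sec, TRAIN = corpus$train_words,
                    PROBE_WORDS = corpus$probe_words,
                    PROBE_NONWORDS = corpus$probe_nonwords)
    lines <- c(lines, paste0("SECTION\t", sec),
               vapply(items, item_line, ""))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param path corpus file path.
#' @return a \code{cdanet_corpus}; malformed input raises an error naming
#'   the offending line.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# cdanet corpus v1") {
    stop("corpus parse error at line 1: missing or unknown header")
  }
  seed <- NA_integer_
  inv <- list()
  sections <- list(TRAIN = list(), PROBE_WORDS = list(), PROBE_NONWORDS = list())
  current <- NULL
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "SEED") {
      seed <- as.integer(f[2])
    } else if (f[1] == "MORA") {
      if (length(f) != 4) stop(sprintf("corpus parse error at line %d", i))
      bits <- as.numeric(as.integer(strsplit(f[4], "")[[1]]))
      inv[[length(inv) + 1L]] <- list(id = as.integer(f[2]), label = f[3],
                                      features = bits)
    } else if (f[1] == "SECTION") {
      if (!f[2] %in% names(sections)) {
        stop(sprintf("corpus parse error at line %d: unknown section %s", i, f[2]))
      }
      current <- f[2]
    } else if (f[1] %in% c("WORD", "NONWORD")) {
      if (is.null(current)) {
        stop(sprintf("corpus parse error at line %d: item before any section", i))
      }
      sections[[current]] <- c(sections[[current]], list(parse_item_line(line, i)))
    } else {
      stop(sprintf("corpus parse error at line %d: %s", i, line))
    }
  }
  if (length(inv) == 0) stop("corpus parse error: no mora inventory")
  attr(inv, "feature_dim") <- length(inv[[1]]$features)
  structure(list(mora_inventory = inv, train_words = sections$TRAIN,
                 probe_words = sections$PROBE_WORDS,
                 probe_nonwords = sections$PROBE_NONWORDS, seed = seed),
            class = "cdanet_corpus")
}
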