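# Shared fixtures, built in code. Heavy objects are computed once per test
# run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small corpus: 6 morae, 12 words, 6 probe words, 10 nonwords. The bigram
# tolerance is loosened to 0.2: a 6-word probe profile is too coarse for
# the study-scale 0.05 bound.
tiny_corpus <- function(seed = 11) {
  cached(paste0("corpus", seed),
         generate_corpus(n_morae = 6, feature_dim = 6, n_words = 12,
                         semantic_dim = 12, semantic_sparsity = 0.25,
                         n_probe_words = 6, n_probe_nonwords = 10,
                         seed = seed, tolerance = 0.2))
}

tiny_arch <- function() arch_spec(mora_dim = 6, semantic_dim = 12,
                                  ismg_units = 16, astg_units = 6)

tiny_net <- function(seed = 5) init_network(tiny_arch(), seed)

# a developed small network that repeats its 12-word corpus correctly
trained_tiny_net <- function() {
  cached("trained_tiny", {
    co <- tiny_corpus()
    net <- init_network(tiny_arch(), 5)
    tc <- training_config(learning_rate = 0.1, epochs = 300)
    for (e in 1:300) {
      trials <- build_epoch(co, "development", seed = 300 + e)
      net <- train_epoch(net, trials, tc, seed = 300 + e)$net
    }
    net
  })
}

# set every weight and bias of a network to a constant
flatten_net <- function(net, value = 0) {
  net$W <- lapply(net$W, function(m) matrix(value, nrow(m), ncol(m)))
  net$Wrec <- lapply(net$Wrec, function(m) matrix(value, nrow(m), ncol(m)))
  net$b <- lapply(net$b, function(v) rep(value, length(v)))
  net
}

# independent bigram counter used as an oracle against the package's
# internal counting: nested loops, string keys assembled differently
oracle_bigram_counts <- function(items) {
  counts <- list()
  for (it in items) {
    for (j in 1:2) {
      key <- sprintf("%d-%d", it$morae[j], it$morae[j + 1])
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the desk-scale experiment shared by the acceptance tests; computed once
desk_experiment <- function() {
  cached("desk_experiment", run_all(run_config("desk", seed = 1)))
}
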