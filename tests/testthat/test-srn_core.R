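# Network mechanics: initialization, forward pass, gradients, training,
# checkpointing.

test_that("initialization is seeded, intact, and respects the architecture", {
  expect_identical(tiny_net(3), tiny_net(3))
  n1 <- tiny_net(3); n2 <- tiny_net(4)
  expect_gt(max(abs(n1$W[[1]] - n2$W[[1]])), 0)
  expect_true(all(vapply(n1$mask, function(m) all(m == 1), TRUE)))
  expect_true(all(n1$noise_sd == 0))
  expect_true(all(unlist(n1$W) >= -0.1) && all(unlist(n1$W) <= 0.1))
})

test_that("zero weights give 0.5 activations everywhere", {
  net <- flatten_net(tiny_net(), 0)
  co <- tiny_corpus()
  tr <- make_repetition(co$train_words[[1]], co$mora_inventory)
  fw <- forward_trial(net, tr)
  for (l in c("iSMG", "aSTG_STS", "vATL", "SpeechMotor")) {
    expect_true(all(fw$activations[[l]] == 0.5), info = l)
  }
})

test_that("noise-free forward pass is a pure function; noise changes it", {
  net <- tiny_net()
  co <- tiny_corpus()
  tr <- make_cda(co$train_words[[2]], co$mora_inventory)
  expect_identical(forward_trial(net, tr)$activations,
                   forward_trial(net, tr)$activations)
  net$noise_sd["iSMG"] <- 0.2
  set.seed(1); a1 <- forward_trial(net, tr)$activations
  set.seed(1); a2 <- forward_trial(net, tr)$activations
  set.seed(2); a3 <- forward_trial(net, tr)$activations
  expect_identical(a1, a2)
  expect_gt(max(abs(a1$SpeechMotor - a3$SpeechMotor)), 0)
  expect_true(all(a1$iSMG >= 0 & a1$iSMG <= 1))
})

test_that("a single-unit chain matches hand-computed sigmoid recursion", {
  # 1-unit layers; known weights. The dorsal chain is
  # a_iSMG(t) = sig(w1 * aud(t) + r1 * a_iSMG(t-1) + b1), etc.
  spec <- arch_spec(1, 1, ismg_units = 1, astg_units = 1)
  net <- init_network(spec, 1)
  net$W <- lapply(net$W, function(m) matrix(0.7, 1, 1))
  net$Wrec <- lapply(net$Wrec, function(m) matrix(-0.3, 1, 1))
  net$b <- lapply(net$b, function(v) 0.1)
  inv1 <- list(list(id = 1L, label = "m01", features = 1))
  attr(inv1, "feature_dim") <- 1L
  item <- list(morae = c(1L, 1L, 1L), semantics = numeric(0),
               is_word = FALSE, accent_class = "accent0")
  tr <- make_repetition(item, inv1)
  fw <- forward_trial(net, tr)

  sig <- function(z) 1 / (1 + exp(-z))
  aud <- c(1, 1, 1, 0, 0, 0)
  ismg <- astg <- vatl <- mot <- numeric(6)
  for (t in 1:6) {
    pi <- if (t == 1) 0.5 else ismg[t - 1]
    pa <- if (t == 1) 0.5 else astg[t - 1]
    pv <- if (t == 1) 0.5 else vatl[t - 1]
    pm <- if (t == 1) 0.5 else mot[t - 1]
    ismg[t] <- sig(0.7 * aud[t] - 0.3 * pi + 0.1)
    astg[t] <- sig(0.7 * aud[t] - 0.3 * pa + 0.1)
    vatl[t] <- sig(0.7 * astg[t] - 0.3 * pv + 0.1)
    mot[t] <- sig(0.7 * ismg[t] + 0.7 * vatl[t] - 0.3 * pm + 0.1)
  }
  expect_equal(as.numeric(fw$activations$SpeechMotor), mot, tolerance = 1e-12)
  expect_equal(as.numeric(fw$activations$vATL), vatl, tolerance = 1e-12)
})

test_that("analytic BPTT gradients match central finite differences", {
  co <- tiny_corpus()
  inv <- co$mora_inventory
  word <- co$train_words[[1]]
  trials <- list(make_repetition(word, inv),
                 make_cda(word, inv),
                 make_comprehension(word, inv, "recovery"),
                 make_speaking(word, inv))
  net <- tiny_net(21)
  h <- 1e-5
  for (tr in trials) {
    g <- cdanet:::bptt_trial(net, tr)
    # spot-check a sample of entries in every parameter block
    for (nm in names(net$W)) {
      idx <- seq(1, length(net$W[[nm]]), length.out = 5)
      for (i in round(idx)) {
        np <- net; np$W[[nm]][i] <- np$W[[nm]][i] + h
        nm2 <- net; nm2$W[[nm]][i] <- nm2$W[[nm]][i] - h
        num <- (trial_loss(np, tr) - trial_loss(nm2, tr)) / (2 * h)
        if (abs(num) > 1e-8) {
          expect_lt(abs(g$gW[[nm]][i] - num) / max(abs(num), 1e-4), 1e-4)
        }
      }
    }
    for (l in c("iSMG", "vATL", "SpeechMotor")) {
      i <- 1L
      np <- net; np$Wrec[[l]][i] <- np$Wrec[[l]][i] + h
      nm2 <- net; nm2$Wrec[[l]][i] <- nm2$Wrec[[l]][i] - h
      num <- (trial_loss(np, tr) - trial_loss(nm2, tr)) / (2 * h)
      if (abs(num) > 1e-8) {
        expect_lt(abs(g$gWrec[[l]][i] - num) / max(abs(num), 1e-4), 1e-4)
      }
      np <- net; np$b[[l]][1] <- np$b[[l]][1] + h
      nm2 <- net; nm2$b[[l]][1] <- nm2$b[[l]][1] - h
      num <- (trial_loss(np, tr) - trial_loss(nm2, tr)) / (2 * h)
      if (abs(num) > 1e-8) {
        expect_lt(abs(g$gb[[l]][1] - num) / max(abs(num), 1e-4), 1e-4)
      }
    }
  }
})

test_that("targets at non-target events never affect loss or gradient", {
  co <- tiny_corpus()
  tr <- make_cda(co$train_words[[3]], co$mora_inventory)
  net <- tiny_net(8)
  g0 <- cdanet:::bptt_trial(net, tr)
  # scribble garbage into the inactive target events (1-6)
  tr2 <- tr
  tr2$targets$SpeechMotor$values[, 1:6] <- 99
  g1 <- cdanet:::bptt_trial(net, tr2)
  expect_identical(g0$loss, g1$loss)
  expect_identical(g0$gW, g1$gW)
  expect_identical(g0$gWrec, g1$gWrec)
})

test_that("compiled trainer reproduces the R reference exactly", {
  co <- tiny_corpus()
  net <- tiny_net(9)
  trials <- build_epoch(co, "recovery", seed = 4)[1:25]
  cfg <- training_config(epochs = 1)
  rc <- train_epoch(net, trials, cfg, seed = 6)
  rr <- train_epoch_r(net, trials, cfg, seed = 6)
  expect_equal(rc$mean_loss, rr$mean_loss, tolerance = 1e-12)
  for (nm in names(rc$net$W)) {
    expect_equal(rc$net$W[[nm]], rr$net$W[[nm]], tolerance = 1e-12)
  }
  expect_equal(rc$net$b, rr$net$b[names(rc$net$b)], tolerance = 1e-12)
})

test_that("zero learning rate leaves weights unchanged except decay", {
  co <- tiny_corpus()
  net <- tiny_net(10)
  trials <- build_epoch(co, "development", seed = 4)[1:10]
  cfg <- training_config(learning_rate = 0, weight_decay = 1e-3, epochs = 1)
  out <- train_epoch(net, trials, cfg, seed = 2)$net
  expect_equal(out$W[[1]], net$W[[1]] * (1 - 1e-3)^10, tolerance = 1e-12)
})

test_that("trial order is seed-dependent but the trial multiset is fixed", {
  co <- tiny_corpus()
  t1 <- build_epoch(co, "development", seed = 1)
  t2 <- build_epoch(co, "development", seed = 2)
  id1 <- vapply(t1, function(x) paste(x$task, x$item_id), "")
  id2 <- vapply(t2, function(x) paste(x$task, x$item_id), "")
  expect_false(identical(id1, id2))
  expect_identical(sort(id1), sort(id2))
})

test_that("training on the development schedule learns repetition", {
  # 10-word toy corpus, 200 epochs: adult-like repetition
  co <- generate_corpus(n_morae = 10, feature_dim = 10, n_words = 10,
                        n_probe_words = 5, n_probe_nonwords = 0, seed = 42)
  net <- init_network(arch_spec(10, 50), 7)
  tc <- training_config(epochs = 200)
  for (e in 1:200) {
    trials <- build_epoch(co, "development", seed = 100 + e)
    net <- train_epoch(net, trials, tc, seed = 100 + e)$net
  }
  acc <- evaluate_tasks(net, co$train_words, co$mora_inventory,
                        n_noise_probes = 1, seed = 1)
  expect_gte(acc[["repetition"]], 0.95)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- trained_tiny_net()
  net$noise_sd["iSMG"] <- 0.2
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_identical(back$W, net$W)
  expect_identical(back$Wrec, net$Wrec)
  expect_identical(back$b, net$b)
  expect_identical(back$noise_sd, net$noise_sd)
  expect_identical(back$epoch, net$epoch)
  expect_equal(back$spec$sizes, net$spec$sizes)
})
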