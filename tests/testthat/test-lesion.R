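# Lesioning: exact mask counts, the dorsal recipe, the severity grid, and
# persistence under training.

test_that("link removal prunes exactly round(p * L) entries", {
  net <- tiny_net(2)
  L <- length(net$W[["iSMG->SpeechMotor"]])
  for (p in c(0, 0.2, 0.5, 1)) {
    out <- apply_lesion(net, lesion_spec(c("iSMG->SpeechMotor" = p), seed = 3))
    expect_equal(sum(out$mask[["iSMG->SpeechMotor"]] == 0), round(p * L))
    expect_true(all(out$W[["iSMG->SpeechMotor"]][
      out$mask[["iSMG->SpeechMotor"]] == 0] == 0))
  }
  # round-half-up at the boundary: 8x6 = 48 entries, p such that pL = 2.5
  p_half <- 2.5 / length(net$W[["Auditory->iSMG"]])
  out <- apply_lesion(net, lesion_spec(c("Auditory->iSMG" = p_half), seed = 1))
  expect_equal(sum(out$mask[["Auditory->iSMG"]] == 0), 3)
  expect_error(lesion_spec(c("Auditory->iSMG" = 1.2)), "\\[0, 1\\]")
})

test_that("zero-proportion, zero-noise lesion is the identity", {
  net <- tiny_net(4)
  out <- apply_lesion(net, lesion_spec(c("iSMG->SpeechMotor" = 0),
                                       c(iSMG = 0), seed = 9))
  expect_identical(out$W, net$W)
  expect_identical(out$mask, net$mask)
  expect_identical(out$noise_sd, net$noise_sd)
})

test_that("the dorsal recipe prunes 20% and sets iSMG noise 0.2", {
  net <- tiny_net(6)
  out <- apply_lesion(net, dorsal_lesion_spec(seed = 2))
  L <- length(net$W[["iSMG->SpeechMotor"]])
  expect_equal(sum(out$mask[["iSMG->SpeechMotor"]] == 0), round(0.2 * L))
  expect_equal(out$noise_sd[["iSMG"]], 0.2)
  expect_true(all(out$mask[["Auditory->iSMG"]] == 1))
})

test_that("lesion selection is seeded and deterministic", {
  net <- tiny_net(6)
  a <- apply_lesion(net, dorsal_lesion_spec(seed = 5))
  b <- apply_lesion(net, dorsal_lesion_spec(seed = 5))
  d <- apply_lesion(net, dorsal_lesion_spec(seed = 6))
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$mask[["iSMG->SpeechMotor"]],
                         d$mask[["iSMG->SpeechMotor"]]))
})

test_that("severity grid follows the equal-interval closed form", {
  g <- severity_grid()
  expect_equal(nrow(g), 20)
  # endpoints
  expect_equal(unlist(g[g$level == 1, -1]),
               c(vatl_noise = 0.01, astg_noise = 0.005,
                 vatl_prune = 0.005, astg_prune = 0.0025))
  expect_equal(unlist(g[g$level == 20, -1]),
               c(vatl_noise = 0.2, astg_noise = 0.1,
                 vatl_prune = 0.10, astg_prune = 0.05))
  # midpoint by equal-interval arithmetic
  expect_equal(unlist(g[g$level == 10, -1]),
               c(vatl_noise = 0.10, astg_noise = 0.05,
                 vatl_prune = 0.05, astg_prune = 0.025))
  # closed form at every level, strictly increasing
  for (col in c("vatl_noise", "astg_noise", "vatl_prune", "astg_prune")) {
    expect_equal(g[[col]], g[[col]][1] * (1:20))
    expect_true(all(diff(g[[col]]) > 0))
  }
})

test_that("severity levels damage the ventral layers as dosed", {
  net <- trained_tiny_net()
  g <- severity_grid()
  lev20 <- as.list(g[g$level == 20, ])
  out <- apply_severity(net, lev20, seed = 3)
  for (nm in c("Auditory->aSTG_STS", "aSTG_STS->vATL")) {
    p <- if (nm == "aSTG_STS->vATL") 0.10 else 0.05
    expect_equal(sum(out$mask[[nm]] == 0), round(p * length(out$mask[[nm]])))
  }
  expect_equal(sum(out$mask_rec[["vATL"]] == 0),
               round(0.10 * length(out$mask_rec[["vATL"]])))
  expect_equal(out$noise_sd[["vATL"]], 0.2)
  expect_equal(out$noise_sd[["aSTG_STS"]], 0.1)
  # dorsal route untouched
  expect_true(all(out$mask[["iSMG->SpeechMotor"]] ==
                    net$mask[["iSMG->SpeechMotor"]]))

  # all-zero severity is the identity
  zero <- list(level = 0, vatl_noise = 0, astg_noise = 0,
               vatl_prune = 0, astg_prune = 0)
  same <- apply_severity(net, zero, seed = 3)
  expect_identical(same$W, net$W)
  expect_identical(same$noise_sd, net$noise_sd)

  expect_identical(apply_severity(net, lev20, seed = 8)$mask,
                   apply_severity(net, lev20, seed = 8)$mask)
})

test_that("masked weights stay zero through recovery training", {
  co <- tiny_corpus()
  net <- apply_lesion(trained_tiny_net(), dorsal_lesion_spec(seed = 4))
  hit <- net$mask[["iSMG->SpeechMotor"]] == 0
  expect_true(any(hit))
  cfg <- training_config(epochs = 3)
  for (e in 1:3) {
    trials <- build_epoch(co, "recovery", seed = 40 + e)
    net <- train_epoch(net, trials, cfg, seed = 40 + e)$net
  }
  expect_true(all(net$W[["iSMG->SpeechMotor"]][hit] == 0))
  # noise persisted through training too
  expect_equal(net$noise_sd[["iSMG"]], 0.2)
})
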