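# Decoding, double-repetition probing, the self-correction statistic, and
# the repeated-measures analyses.

test_that("decoding is nearest-neighbor with lowest-id tie-break", {
  inv <- build_inventory(8, 8, seed = 1)
  # exact code decodes to itself
  expect_equal(decode_event(inv[[5]]$features, inv), 5L)
  # equidistant between morae 3 and 7 (one-hot codes): tie to 3
  mid <- (inv[[3]]$features + inv[[7]]$features) / 2
  expect_equal(decode_event(mid, inv), 3L)
  expect_error(decode_event(c(0, 1), inv), "dimensionality")
  # brute-force oracle on random activations
  withr::with_seed(33, {
    feat <- inventory_matrix(inv)
    for (i in 1:25) {
      v <- runif(8)
      d <- apply(feat, 2, function(f) sqrt(sum((f - v)^2)))
      expect_equal(decode_event(v, inv), which.min(d))
    }
  })
})

test_that("double-repetition probing yields items x probes records", {
  co <- tiny_corpus()
  net <- trained_tiny_net()
  rec <- probe_double_repetition(net, co$probe_words, co$mora_inventory,
                                 n_noise_probes = 5, seed = 2)
  expect_equal(nrow(rec), length(co$probe_words) * 5)
  expect_identical(rec,
                   probe_double_repetition(net, co$probe_words,
                                           co$mora_inventory,
                                           n_noise_probes = 5, seed = 2))
  # a developed noise-free net repeats correctly on the first attempt:
  # events 1-6 of the 9-event trial replay the trained repetition task
  expect_true(all(rec$attempt1_correct))
  # flags are consistent with the decoded strings
  target <- vapply(co$probe_words, function(it)
    paste(it$morae, collapse = ","), "")
  expect_equal(rec$attempt1_correct,
               rec$decoded1 == rep(target, each = 5))
  expect_equal(rec$attempt2_correct,
               rec$decoded2 == rep(target, each = 5))
})

test_that("the self-correction rate is a conditional proportion", {
  mk <- function(ok1, ok2) data.frame(attempt1_correct = ok1,
                                      attempt2_correct = ok2)
  r <- cda_rate(mk(c(rep(FALSE, 10), rep(TRUE, 5)),
                   c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 5))))
  expect_equal(r$n_first_errors, 10)
  expect_equal(r$n_self_corrected, 3)
  expect_equal(r$rate, 0.3)
  expect_true(r$defined)

  all_ok <- cda_rate(mk(rep(TRUE, 6), rep(TRUE, 6)))
  expect_false(all_ok$defined)
  expect_true(is.na(all_ok$rate))

  # brute-force recount oracle over random record sets
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      df <- mk(sample(c(TRUE, FALSE), n, TRUE), sample(c(TRUE, FALSE), n, TRUE))
      num <- 0; den <- 0
      for (j in seq_len(n)) {
        if (!df$attempt1_correct[j]) {
          den <- den + 1
          if (df$attempt2_correct[j]) num <- num + 1
        }
      }
      r <- cda_rate(df)
      expect_equal(r$n_first_errors, den)
      if (den > 0) expect_equal(r$rate, num / den) else expect_false(r$defined)
      expect_true(is.na(r$rate) || (r$rate >= 0 && r$rate <= 1))
    }
  })
})

test_that("the two-level contrast equals the squared paired t statistic", {
  a <- c(0.3, 0.45, 0.5)
  b <- c(0.1, 0.2, 0.3)
  s <- repeated_measures_2level(a, b)
  tt <- t.test(a, b, paired = TRUE)        # independent implementation
  expect_equal(s$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(s$p, tt$p.value, tolerance = 1e-12)
  expect_equal(s$df, c(1, 2))
  expect_equal(s$cohen_d, mean(a - b) / sd(a - b))

  same <- repeated_measures_2level(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$cohen_d, 0)

  const <- repeated_measures_2level(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(const$F))
  expect_equal(const$p, 0)

  expect_warning(repeated_measures_2level(c(0.2, NA, 0.4, 0.5),
                                          c(0.1, 0.2, 0.3, 0.2)),
                 "undefined")

  # F = t^2 identity on random paired samples
  withr::with_seed(19, {
    for (i in 1:20) {
      n <- sample(3:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      s <- repeated_measures_2level(x, y)
      tt <- t.test(x, y, paired = TRUE)
      expect_equal(s$F, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(s$p, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the 2x2 interaction is the paired t^2 of the double difference", {
  x <- c(0.5, 0.6, 0.4, 0.55)
  expect_equal(interaction_2x2(x, x, x, x)$F, 0)
  # equal drops per network: null interaction
  wa <- c(0.5, 0.6, 0.4); wb <- wa - c(0.1, 0.2, 0.15)
  na_ <- c(0.3, 0.35, 0.2); nb <- na_ - c(0.1, 0.2, 0.15)
  expect_equal(interaction_2x2(wa, wb, na_, nb)$F, 0, tolerance = 1e-12)
  # brute-force double-difference oracle
  withr::with_seed(5, {
    A <- runif(6); B <- runif(6); C <- runif(6); D <- runif(6)
    dd <- (A - B) - (C - D)
    tt <- t.test(dd)
    s <- interaction_2x2(A, B, C, D)
    expect_equal(s$F, unname(tt$statistic)^2, tolerance = 1e-10)
  })
})

test_that("task accuracies are perfect for a developed tiny network", {
  co <- tiny_corpus()
  net <- trained_tiny_net()
  acc <- evaluate_tasks(net, co$train_words, co$mora_inventory,
                        n_noise_probes = 1, seed = 3)
  expect_gte(acc[["repetition"]], 0.95)
  expect_gte(acc[["comprehension"]], 0.9)
  expect_true(all(acc >= 0 & acc <= 1))
})
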