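test_that("ITR reproduces the closed-form identities", {
  # chance-level accuracy carries zero information
  expect_equal(itr(32, 1 / 32, 2.6), 0)
  expect_equal(itr(8, 1 / 8, 1), 0)

  # perfect 32-choice selection once a minute: exactly 5 bits/min
  expect_equal(itr(32, 1, 60), 5)

  # direct formula evaluation at p = 0.95, N = 32, t = 2.6 s
  p <- 0.95
  by_hand <- (log2(32) + p * log2(p) + (1 - p) * log2((1 - p) / 31)) / (2.6 / 60)
  expect_equal(itr(32, 0.95, 2.6), by_hand)

  # strictly increasing in p above chance, inversely proportional to t
  grid <- seq(1 / 32 + 1e-3, 1, length.out = 50)
  vals <- itr(32, grid, 2.6)
  expect_true(all(diff(vals) > 0))
  expect_equal(itr(32, 0.9, 5), itr(32, 0.9, 10) * 2)

  expect_error(itr(32, 1.2, 1), "\\[0, 1\\]")
  expect_warning(out <- itr(32, 0.01, 1), "clamped")
  expect_equal(out, 0)
})

test_that("selection time adds stimulation, exclusion and gaze shift", {
  # 1 repetition of the 1.05 s code with the 150 ms exclusion needs
  # 0.150 + 1.05 = 1.2 s of stimulation, plus 0.5 s to shift gaze
  expect_equal(selection_time(1, 1.05, 0.150, 0), 1.2)
  expect_equal(selection_time(1, 1.05, 0.150), 1.7)
  expect_equal(selection_time(2, 0.525, 0, 0.5), 1.55)
  expect_equal(selection_time(2, 1.05, 0, 0.5), 2.6)
})

test_that("stratified folds partition epochs with one epoch per target each", {
  sc <- small_sim(seed = 6)
  cfg <- small_config()
  ep <- simulate_epochs(sc, cfg)
  ev <- stratified_cv(ep, cfg, repetitions = 1)

  pf <- ev$per_fold[ev$per_fold$n_repetitions == 1, ]
  expect_equal(sort(pf$epoch), seq_len(dim(ep$data)[3]))   # partition
  for (f in 1:5) {
    fold_targets <- pf$true[pf$fold == f]
    expect_equal(sort(fold_targets), seq_len(sc$n_targets)) # one per target
  }

  # noiseless simulation is decoded perfectly at one repetition
  expect_equal(unname(ev$accuracy_by_repetitions["1"]), 1.0)

  # reproducibility: identical data and config give identical results
  ev2 <- stratified_cv(ep, cfg, repetitions = 1)
  expect_identical(ev$per_fold, ev2$per_fold)

  # uneven counts are rejected
  bad <- epoch_set(ep$data[, , 1:39], ep$rate, ep$labels[1:39])
  expect_error(stratified_cv(bad, cfg), "equal epoch count")
})

test_that("greedy selection finds a single informative channel and stops", {
  # signal only on Oz: topography zero elsewhere, zero noise on Oz
  mont <- c("Oz", "P3", "P4", "TP9", "TP10")
  mix <- c(1, 0, 0, 0, 0)
  sc <- sim_config("120", n_targets = 8, trials_per_target = 5,
                   montage = mont, mixing = mix, acquisition_rate = 1000,
                   noise_sd = 1, alpha_amp_uv = 0, pink_amp_uv = 0, seed = 9)
  cfg <- small_config()
  ep <- simulate_epochs(sc, cfg)
  sel <- greedy_channel_selection(ep, cfg, candidates = c("Oz", "P3", "P4"))
  expect_equal(sel$channels[1], "Oz")
  expect_length(sel$channels, 1L)          # stops at 100% accuracy
  expect_equal(sel$accuracy[1], 1.0)
})

test_that("greedy selection on pure noise stalls at chance", {
  mont <- c("Oz", "P3", "TP9", "TP10")
  sc <- sim_config("120", n_targets = 8, trials_per_target = 5,
                   montage = mont, mixing = rep(0, 4), acquisition_rate = 1000,
                   noise_sd = 5, alpha_amp_uv = 0, pink_amp_uv = 5, seed = 10)
  cfg <- small_config()
  ep <- simulate_epochs(sc, cfg)
  sel <- greedy_channel_selection(ep, cfg, candidates = c("Oz", "P3"))
  # chance band: 40 epochs at 1/8
  expect_lte(max(sel$accuracy), qbinom(0.999, 40, 1 / 8) / 40)
  expect_lte(length(sel$channels), 2L)
})

test_that("signed-rank harness matches exact enumeration and edge rules", {
  # hand-worked 6-pair example vs exhaustive enumeration of 2^6 sign flips
  a <- c(1.1, 2.3, 0.2, 4.8, 3.1, 0.9)
  b <- c(0.8, 2.9, 0.1, 3.9, 2.25, 1.4)   # all |differences| distinct
  d <- a - b
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  # enumerate the null distribution of V over all sign assignments
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  Vnull <- apply(signs, 1, function(s) sum(r[s == 1]))
  p_exact <- mean(abs(Vnull - sum(r) / 2) >= abs(V - sum(r) / 2))
  got <- paired_signed_rank(a, b)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  expect_equal(got$statistic, V)

  # a large constant shift is detected
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_lt(paired_signed_rank(x, x + 5)$p_value, 0.05)

  # identical vectors: degenerate rule p = 1
  expect_equal(paired_signed_rank(x, x)$p_value, 1)

  expect_error(paired_signed_rank(1:3, 1:3), "5 pairs")
})

test_that("stratified_cv accepts a pluggable comparator classifier", {
  sc <- small_sim(n_targets = 4L, n_channels = 4L, seed = 44)
  cfg <- small_config(n_targets = 4L)
  ep <- simulate_epochs(sc, cfg)

  # nearest-template comparator: correlate the averaged repetition window
  # with each target's mean training epoch over the same window
  template_classifier <- list(
    fit = function(epochs, config) {
      n <- round(config$segment_s * epochs$rate)
      templates <- sapply(sort(unique(epochs$labels)), function(t) {
        idx <- which(epochs$labels == t)
        rowMeans(sapply(idx, function(j) as.numeric(epochs$data[, 1:n, j])))
      })
      list(templates = templates, n = n, m = dim(epochs$data)[1])
    },
    predict = function(model, epoch, n_repetitions) {
      acc <- 0
      for (g in seq_len(n_repetitions)) {
        acc <- acc + epoch[, (g - 1) * model$n + seq_len(model$n), drop = FALSE]
      }
      which.max(cor(as.numeric(acc / n_repetitions), model$templates))
    })
  ev <- stratified_cv(ep, cfg, repetitions = 1, classifier = template_classifier)
  # a zero-noise session is easy for template matching too
  expect_equal(unname(ev$accuracy_by_repetitions["1"]), 1.0)
})
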