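test_that("re-referencing subtracts the mastoid average", {
  # hand toy: A = 3, TP9 = 1, TP10 = 3 -> A becomes 3 - 2 = 1
  rec <- eeg_recording(matrix(c(3, 1, 3), ncol = 1), 100,
                       c("A", "TP9", "TP10"))
  rr <- rereference(rec)
  expect_equal(unname(rr$data["A", ]), 1)

  # the mean of the two reference channels is identically zero afterwards
  rec2 <- toy_recording()
  rr2 <- rereference(rec2)
  expect_equal(colMeans(rr2$data[c("TP9", "TP10"), ]),
               rep(0, ncol(rec2$data)))

  # idempotence: re-referencing twice equals re-referencing once
  expect_equal(rereference(rr2)$data, rr2$data)

  # drop flag removes the reference rows
  expect_equal(rownames(rereference(rec2, drop_refs = TRUE)$data), "A")

  expect_error(rereference(rec2, c("TP9", "nope")), "not found")
})

test_that("band-pass keeps the passband and rejects drift and DC", {
  rate <- 2000
  t <- (0:(8 * rate - 1)) / rate
  rec <- eeg_recording(
    rbind(sin(2 * pi * 15 * t), rep(1, length(t)), sin(2 * pi * 0.5 * t)),
    rate, c("pass", "dc", "drift"))
  out <- bandpass_filter(rec)          # defaults: 4-31 Hz, order 4
  mid <- (2 * rate):(6 * rate)         # steady-state portion
  expect_lt(abs(max(abs(out$data["pass", mid])) - 1), 0.05)
  expect_lt(max(abs(out$data["dc", mid])), 1e-6)
  expect_lt(max(abs(out$data["drift", mid])), 0.10)

  expect_error(bandpass_filter(rec, low = 4, high = 1200), "Nyquist")
})

test_that("epoching cuts one labelled epoch per onset event", {
  rate <- 2000
  events <- data.frame(sample = seq(0, by = 11000, length.out = 4),
                       label = c(3L, 1L, 4L, 1L))
  rec <- eeg_recording(matrix(rnorm(2 * 50000), nrow = 2), rate,
                       c("a", "b"), events)
  ep <- epoch_recording(rec, 5.25)
  expect_equal(dim(ep$data), c(2, 10500, 4))   # 5.25 s x 2000 Hz
  expect_equal(ep$labels, events$label)
  # epoch content is the half-open window starting at the onset sample
  expect_equal(ep$data[, , 2], rec$data[, 11000 + 1:10500])

  # zero events -> empty epoch set
  ep0 <- epoch_recording(eeg_recording(rec$data, rate, c("a", "b")))
  expect_equal(dim(ep0$data)[3], 0L)

  # an event too close to the end errors and names the offender
  bad <- eeg_recording(rec$data, rate, c("a", "b"),
                       data.frame(sample = 45000L, label = 1L))
  expect_error(epoch_recording(bad), "45000")
})

test_that("downsampling decimates by the integer factor only", {
  ep <- epoch_set(array(seq_len(2 * 1000 * 3), dim = c(2, 1000, 3)),
                  2000, c(1L, 2L, 3L))
  dn <- downsample_epochs(ep, 100)
  expect_equal(dim(dn$data)[2], 50L)
  expect_equal(dn$rate, 100)
  expect_equal(dn$data[1, 1:3, 1], ep$data[1, c(1, 21, 41), 1])

  expect_identical(downsample_epochs(ep, 2000), ep)
  expect_error(downsample_epochs(ep, 300), "integer multiple")
})

test_that("segment extraction reproduces the protocol's counts", {
  # 5.25 s at 100 Hz, c = 1.05 s: 105-sample segments, 5 per epoch,
  # 4 when the initial 150 ms are excluded (20% fewer)
  ep60 <- epoch_set(array(rnorm(2 * 525 * 3), dim = c(2, 525, 3)),
                    100, c(1L, 2L, 1L))
  s <- extract_segments(ep60, 1.05)
  expect_equal(dim(s$data), c(2, 105, 15))
  s_ex <- extract_segments(ep60, 1.05, 0.150)
  expect_equal(dim(s_ex$data)[3], 4L * 3L)

  # 5.25 s at 200 Hz, c = 0.525 s: also 105 samples, 10 per epoch,
  # 9 with the exclusion (10% fewer)
  ep120 <- epoch_set(array(rnorm(2 * 1050 * 2), dim = c(2, 1050, 2)),
                     200, c(1L, 2L))
  expect_equal(dim(extract_segments(ep120, 0.525)$data), c(2, 105, 20))
  expect_equal(dim(extract_segments(ep120, 0.525, 0.150)$data)[3], 9L * 2L)

  # labels follow the epochs; segments tile from the exclusion offset
  expect_equal(s$labels, rep(c(1L, 2L, 1L), each = 5))
  expect_equal(s_ex$data[, , 1], ep60$data[, 15 + 1:105, 1],
               ignore_attr = TRUE)

  # c longer than the usable epoch: zero segments, not an error
  none <- extract_segments(ep60, 6)
  expect_equal(dim(none$data)[3], 0L)
})

test_that("segment counts follow floor((T - excl)/c) across random setups", {
  set.seed(11)
  for (i in 1:20) {
    rate <- sample(c(100, 200, 250), 1)
    dur <- runif(1, 1, 8)
    c_s <- runif(1, 0.2, 2)
    excl <- sample(c(0, 0.15, 0.3), 1)
    nsamp <- round(dur * rate)
    ep <- epoch_set(array(0, dim = c(1, nsamp, 2)), rate, c(1L, 1L))
    got <- dim(extract_segments(ep, c_s, excl)$data)[3] / 2
    expect_equal(got, (nsamp - round(excl * rate)) %/% round(c_s * rate))
  }
})

test_that("the preprocessing chain is deterministic end to end", {
  sc <- small_sim(noise_sd = 2, alpha_amp_uv = 5, pink_amp_uv = 5, seed = 3)
  cfg <- small_config()
  ep1 <- preprocess_recording(simulate_session(sc), cfg)
  ep2 <- preprocess_recording(simulate_session(sc), cfg)
  expect_identical(ep1, ep2)
})
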