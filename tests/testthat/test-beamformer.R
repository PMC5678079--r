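toy_segments <- function() {
  # 2 channels x 2 samples x 3 segments with hand-written entries
  dat <- array(c(1, 5, 2, 6,   3, 7, 4, 8,   5, 9, 6, 10), dim = c(2, 2, 3))
  segment_set(dat, rate = 2, labels = c(1L, 1L, 1L), segment_duration_s = 1)
}

test_that("activation patterns are element-wise segment means", {
  segs <- toy_segments()
  ap <- activation_pattern(segs)
  expect_equal(ap$pattern, matrix(c(3, 7, 4, 8), nrow = 2))  # hand mean

  # mean of identical segments is the segment itself; k = 1 is identity
  one <- segment_set(array(segs$data[, , 1], dim = c(2, 2, 1)), 2, 1L, 1)
  expect_equal(activation_pattern(one)$pattern, segs$data[, , 1])

  rep3 <- segment_set(array(rep(segs$data[, , 2], 3), dim = c(2, 2, 3)),
                      2, rep(1L, 3), 1)
  expect_equal(activation_pattern(rep3)$pattern, segs$data[, , 2])

  expect_error(activation_pattern(segs, target = 7), "no training segments")
})

test_that("flattening is channel-major and invertible", {
  seg <- matrix(c(1, 4, 2, 5, 3, 6), nrow = 2)   # [[1,2,3],[4,5,6]]
  expect_equal(flatten_matrix(seg), c(1, 2, 3, 4, 5, 6))

  segs <- toy_segments()
  E <- flatten_segments(segs)
  expect_equal(dim(E), c(3L, 4L))
  expect_equal(E[1, ], c(1, 2, 5, 6))

  # round trip restores the tensor exactly
  expect_equal(unflatten_segments(E, 2, 2), segs$data)

  # single-channel flattening is the identity up to reshaping
  one <- array(1:6, dim = c(1, 3, 2))
  expect_equal(flatten_segments(one), rbind(1:3, 4:6))
})

test_that("spatiotemporal covariance matches hand and brute-force values", {
  # two rows [0,0] and [2,2]: covariance [[2,2],[2,2]] with the r-1 divisor
  E2 <- rbind(c(0, 0), c(2, 2))
  expect_equal(spatiotemporal_covariance(E2), matrix(2, 2, 2))

  # identical rows -> zero matrix
  E1 <- rbind(c(1, 3), c(1, 3), c(1, 3))
  expect_equal(spatiotemporal_covariance(E1), matrix(0, 2, 2))

  # brute-force double loop on a 5 x 6 random matrix
  set.seed(21)
  E <- matrix(rnorm(30), 5, 6)
  S <- spatiotemporal_covariance(E)
  mu <- colMeans(E)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(S[i, j], sum((E[, i] - mu[i]) * (E[, j] - mu[j])) / 4)
  }
  expect_equal(S, t(S))
})

test_that("covariance pseudoinverse from data equals pinv of the covariance", {
  set.seed(31)
  for (dims in list(c(8, 5), c(4, 6), c(12, 12))) {   # r x p, incl. singular
    E <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    expect_equal(covariance_pinv(E),
                 pracma::pinv(spatiotemporal_covariance(E)),
                 tolerance = 1e-9)
  }
})

test_that("LCMV weights solve the constrained minimum-variance problem", {
  # identity covariance: w = a / (a'a), and the pattern scores exactly 1
  a <- c(2, 1, 2)
  w <- lcmv_weights(a, diag(3))
  expect_equal(w, a / sum(a^2))
  expect_equal(beamformer_score(w, a), 1)

  # 2-d toy solved by hand: a = [1,0], S = diag(2,1) -> w = [1,0]
  expect_equal(lcmv_weights(c(1, 0), diag(c(2, 1))), c(1, 0))

  # oracle equivalence on random full-rank instances with mn <= 12
  set.seed(41)
  for (i in 1:25) {
    p <- sample(2:12, 1)
    X <- matrix(rnorm((p + 6) * p), ncol = p)
    sigma <- crossprod(X) / (p + 5)
    a <- rnorm(p)
    w <- lcmv_weights(a, sigma)
    expect_lt(max(abs(w - nullspace_lcmv(a, sigma))), 1e-8)
    expect_lt(abs(sum(a * w) - 1), 1e-6)
  }

  # singular covariance (fewer segments than dimensions): finite weights
  E <- matrix(rnorm(3 * 8), 3, 8)
  w_sing <- lcmv_weights(rnorm(8), spatiotemporal_covariance(E))
  expect_true(all(is.finite(w_sing)))

  expect_error(lcmv_weights(rep(0, 4), diag(4)), "zero vector")
})

test_that("scoring is a dot product and linear in the segment", {
  set.seed(51)
  w <- rnorm(6)
  seg <- matrix(rnorm(6), nrow = 2)
  # hand loop oracle
  s <- flatten_matrix(seg)
  acc <- 0
  for (k in 1:6) acc <- acc + s[k] * w[k]
  expect_equal(beamformer_score(w, seg), acc)

  expect_equal(beamformer_score(w, matrix(0, 2, 3)), 0)
  s1 <- matrix(rnorm(6), 2); s2 <- matrix(rnorm(6), 2)
  expect_equal(beamformer_score(w, 2 * s1 + 3 * s2),
               2 * beamformer_score(w, s1) + 3 * beamformer_score(w, s2))
  expect_error(beamformer_score(w, matrix(0, 2, 4)), "features")
})

test_that("the trained bank satisfies the unit-response constraint", {
  sc <- small_sim(noise_sd = 2, alpha_amp_uv = 4, pink_amp_uv = 4, seed = 5)
  ep <- simulate_epochs(sc, small_config())
  segs <- extract_segments(ep, 0.525)
  bank <- beamformer_bank(segs)
  for (t in seq_along(bank$targets)) {
    a <- flatten_matrix(bank$patterns[, , t])
    expect_lt(abs(sum(a * bank$weights[, t]) - 1), 1e-6)
  }
  # score_segments agrees with per-segment beamformer_score
  sc1 <- score_segments(bank, segs$data[, , 1:3])
  expect_equal(unname(sc1[2, 4]),
               beamformer_score(bank$weights[, 4], segs$data[, , 2]))
})

test_that("independent per-target patterns beat shifted-template patterns", {
  # simulate with target-heterogeneous responses: per-target amplitude
  # jitter makes circular shifts of target 1's template a poorer match
  sc <- small_sim(noise_sd = 3, alpha_amp_uv = 6, pink_amp_uv = 6, seed = 8,
                  target_gain_sd = 0.3)
  ep <- simulate_epochs(sc, small_config())
  segs <- extract_segments(ep, 0.525)
  bank <- beamformer_bank(segs)

  # shifted-template bank: pattern i = target 1's pattern circularly
  # shifted by the lag difference (in analysis samples)
  shift_samples <- function(mat, k) {
    n <- ncol(mat)
    mat[, ((seq_len(n) - 1 - k) %% n) + 1, drop = FALSE]
  }
  cb <- build_codebook(binary_code(CVEP_CODE63, frames_per_bit = 1L),
                       sc$n_targets, 2L)
  E <- flatten_segments(segs)
  spinv <- covariance_pinv(E)
  base_pat <- bank$patterns[, , 1]
  shifted <- bank
  for (t in seq_along(bank$targets)) {
    lag_s <- cb$lag_frames[t] / 120 * segs$rate
    pat <- shift_samples(base_pat, round(lag_s))
    shifted$patterns[, , t] <- pat
    shifted$weights[, t] <- lcmv_weights(flatten_matrix(pat), sigma_pinv = spinv)
  }
  truth <- segs$labels
  acc_of <- function(b) {
    sc_mat <- score_segments(b, segs)
    mean(b$targets[max.col(sc_mat, ties.method = "first")] == truth)
  }
  expect_gte(acc_of(bank), acc_of(shifted))
})
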