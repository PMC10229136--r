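test_that("optical density conversion is exact and round-trips", {
  const <- vec_recording(rep(2.5, 100), kind = "intensity")
  expect_true(all(intensity_to_od(const)$data == 0))
  # closed form: a sample equal to e * mean(I) has OD exactly -1
  n <- 100; v <- 1
  z <- exp(1) * (n - 1) * v / (n - exp(1))
  tr <- c(rep(v, n - 1), z)
  od1 <- intensity_to_od(vec_recording(tr, kind = "intensity"))
  expect_equal(unname(od1$data[1, n]), -1, tolerance = 1e-12)
  set.seed(4)
  raw <- vec_recording(runif(200, 0.5, 2), kind = "intensity")
  od <- intensity_to_od(raw)
  rebuilt <- exp(-od$data) * mean(raw$data)
  expect_equal(as.vector(rebuilt), as.vector(raw$data), tolerance = 1e-12)
  expect_error(intensity_to_od(vec_recording(c(1, -1, 1),
                                             kind = "intensity")),
               "positive")
})

test_that("Beer-Lambert inversion recovers forward-modelled concentrations", {
  cfg <- preprocess_config()
  set.seed(11)
  hbo <- vec_recording(rnorm(300, 0, 0.5))
  hbr <- vec_recording(rnorm(300, 0, 0.2))
  hbo$chromophore <- "HbO"; hbr$chromophore <- "HbR"
  ods <- forward_mbll(hbo, hbr, cfg)
  out <- mbll(ods, cfg)
  expect_equal(out$HbO$data, hbo$data, tolerance = 1e-9)
  expect_equal(out$HbR$data, hbr$data, tolerance = 1e-9)
  expect_equal(out$HbO$chromophore, "HbO")
  expect_equal(out$HbR$chromophore, "HbR")
  # zero OD maps to zero concentrations
  z <- lapply(ods, function(r) { r$data[] <- 0; r })
  zc <- mbll(z, cfg)
  expect_true(all(zc$HbO$data == 0) && all(zc$HbR$data == 0))
  # doubling dpf*distance halves the estimates
  cfg2 <- preprocess_config(dpf = c(12, 12))
  half <- mbll(ods, cfg2)
  expect_equal(half$HbO$data, hbo$data / 2, tolerance = 1e-9)
  expect_error(preprocess_config(extinction = matrix(1, 2, 2)), "singular")
})

test_that("polynomial detrend removes fitted drift and only that", {
  n <- 400
  t <- seq_len(n)
  lin <- vec_recording(3 + 0.01 * t)
  out <- polynomial_detrend(lin, 1)
  expect_lt(max(abs(out$data)), 1e-9)
  m <- vec_recording(rnorm(n) + 5)
  out0 <- polynomial_detrend(m, 0)
  expect_equal(as.vector(out0$data), as.vector(m$data) - mean(m$data),
               tolerance = 1e-12)
  t2 <- seq_len(3000)
  sine <- sin(2 * pi * 0.05 * t2 / 6.78)
  mixed <- vec_recording(sine + 0.002 * t2 + 7)
  det <- polynomial_detrend(mixed, 1)
  # independent fit-and-subtract oracle
  oracle <- unname(lm(as.vector(mixed$data) ~ t2)$residuals)
  expect_equal(as.vector(det$data), oracle, tolerance = 1e-9)
  expect_gt(cor(as.vector(det$data), sine), 0.999)
  expect_error(polynomial_detrend(vec_recording(1:3), 5), "few samples")
})

test_that("TDDR preserves clean signal and repairs motion transients", {
  fs <- 6.78
  t <- seq(0, 300, by = 1 / fs)
  clean <- sin(2 * pi * 0.04 * t)
  rec <- vec_recording(clean, fs)
  out <- tddr(rec)
  expect_gt(cor(as.vector(out$data), clean), 0.99)
  expect_true(all(tddr(vec_recording(rep(3, 50), fs))$data == 3))
  # ~2.5 s motion transient, 10x the signal SD
  art <- clean
  i0 <- 1000
  bump_len <- round(2.5 * fs)
  art[i0:(i0 + bump_len)] <- art[i0:(i0 + bump_len)] + 10 * sd(clean)
  rec_a <- vec_recording(art, fs)
  fixed <- as.vector(tddr(rec_a)$data)
  mid <- i0 + round(bump_len / 2)
  before <- abs(art[mid] - clean[mid])
  after <- abs(fixed[mid] - clean[mid])
  expect_lt(after, 0.2 * before)
  # full-band variant removes even a single-sample spike
  spike <- clean
  spike[2000] <- spike[2000] + 10 * sd(clean)
  fixed2 <- as.vector(tddr(vec_recording(spike, fs), split_freq = NULL)$data)
  expect_lt(abs(fixed2[2000] - clean[2000]),
            0.2 * abs(spike[2000] - clean[2000]))
})

test_that("TDDR is idempotent in practice", {
  # drift-dominated channel with a spike and a baseline step: the
  # artifacts are removed on the first pass, so a second pass only
  # re-shrinks residual in-band noise, a negligible fraction of the signal
  fs <- 6.78
  t <- seq(0, 300, by = 1 / fs)
  set.seed(9)
  x <- 0.02 * t + 0.02 * rnorm(length(t))
  x[500] <- x[500] + 8
  x[1200:length(x)] <- x[1200:length(x)] + 3
  once <- as.vector(tddr(vec_recording(x, fs))$data)
  twice <- as.vector(tddr(vec_recording(once, fs))$data)
  rel <- sqrt(mean((twice - once)^2)) / sqrt(mean(once^2))
  expect_lt(rel, 0.01)
})

test_that("bandpass has unit passband gain, strong stopband attenuation, zero phase", {
  fs <- 6.78
  t <- seq(0, 900, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  # DC removed
  dc <- bandpass(vec_recording(rep(1, length(t)), fs))
  expect_lt(mean(abs(dc$data[1, mid])), 1e-3)
  # 0.04 Hz passes with >= 0.95 amplitude and no phase shift
  s04 <- sin(2 * pi * 0.04 * t)
  y04 <- as.vector(bandpass(vec_recording(s04, fs))$data)
  expect_gte((max(y04[mid]) - min(y04[mid])) / 2, 0.95)
  expect_gt(cor(y04[mid], s04[mid]), 0.999)
  # 1 Hz attenuated below 0.01
  s1 <- sin(2 * pi * 1 * t)
  y1 <- as.vector(bandpass(vec_recording(s1, fs))$data)
  expect_lte((max(y1[mid]) - min(y1[mid])) / 2, 0.01)
  expect_error(bandpass(vec_recording(s1, fs), band = c(0.01, 4)), "Nyquist")
})

test_that("bandpass is linear and preprocessing is channel-wise independent", {
  fs <- 6.78
  set.seed(21)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n)
  f <- function(x) as.vector(bandpass(vec_recording(x, fs))$data)
  # linearity up to the conditioning of the near-unit-circle IIR recursion
  expect_lt(max(abs(f(a + b) - (f(a) + f(b)))) / max(abs(f(a + b))), 1e-2)
  # permuting channels commutes with each stage
  X <- matrix(rnorm(5 * n), 5, n)
  rec <- fnirs_recording(X, fs)
  perm <- c(3, 1, 5, 2, 4)
  recp <- fnirs_recording(X[perm, ], fs)
  for (op in list(function(r) polynomial_detrend(r, 1),
                  function(r) tddr(r),
                  function(r) bandpass(r))) {
    straight <- op(rec)$data[perm, ]
    permuted <- op(recp)$data
    dimnames(straight) <- NULL; dimnames(permuted) <- NULL
    expect_equal(straight, permuted, tolerance = 1e-10)
  }
})
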