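test_that("block averaging reproduces segments and reduces noise variance", {
  d <- tiny_design(1)
  fs <- d$sampling_rate
  set.seed(8)
  x <- rnorm(design_n_samples(d))
  rec <- vec_recording(x, fs)
  ba <- block_average(rec, d, "gentle_touch", window = c(5, 35))
  len <- floor(30 * fs)
  expect_equal(ncol(ba), 203) # floor(30 * 6.78)
  i0 <- round(5 * fs) + 1
  expect_equal(as.vector(ba), x[i0:(i0 + len - 1)])
  # 20 blocks of a shared template + IID noise: variance shrinks ~ 1/20
  d20 <- make_block_design(20)
  n <- design_n_samples(d20)
  template <- sin(2 * pi * (0:(n - 1)) / 305)
  reps <- sapply(1:300, function(i) {
    rec_i <- vec_recording(template + rnorm(n), fs)
    block_average(rec_i, d20, "gentle_touch")[1, 100]
  })
  v <- var(reps)
  expect_gt(v, (1 / 20) * 0.6)
  expect_lt(v, (1 / 20) * 1.6)
  expect_error(block_average(rec, d, "gentle_touch", window = c(5, 500)),
               "bounds")
})

test_that("feature extraction concatenates ROI-averaged curves", {
  m <- make_montage()
  d <- tiny_design(2)
  rec <- simulate_subject_fnirs(m, d, null_effect_spec(), seed = 1)
  f0 <- extract_features(rec, d, m)
  expect_length(f0, 3 * 203)
  expect_true(all(f0 == 0))
  # permuting channels within an ROI leaves the feature unchanged
  spec <- amp_only_spec(1)
  spec$noise_sd <- 0.2
  rec1 <- simulate_subject_fnirs(m, d, spec, seed = 2)
  f1 <- extract_features(rec1, d, m)
  rec2 <- rec1
  rec2$data[12:15, ] <- rec1$data[c(14, 12, 15, 13), ]
  expect_equal(extract_features(rec2, d, m), f1)
  expect_error(extract_features(rec1, d, m, rois = c("mOFC", "insula")),
               "unknown ROI")
})

test_that("LOO classification is perfect for disjoint patterns, ties are incorrect", {
  template <- sin(seq(0, 6 * pi, length.out = 50))
  F <- rbind(t(replicate(5, template + rnorm(50, 0, 0.05))),
             t(replicate(5, -template + rnorm(50, 0, 0.05))))
  labels <- rep(c("OT", "PLC"), each = 5)
  res <- loo_classify(F, labels)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_ties, 0)
  # exact tie: subject identical to both group means
  Ftie <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4),
                c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  rtie <- loo_classify(Ftie, rep(c("A", "B"), each = 3))
  expect_equal(rtie$n_ties + rtie$n_undefined, 6)
  expect_equal(rtie$accuracy, 0)
  # constant feature vector flagged as undefined
  Fu <- rbind(matrix(rnorm(40), 4), rep(1, 10), matrix(rnorm(10), 1))
  ru <- loo_classify(Fu, rep(c("A", "B"), each = 3))
  expect_gte(ru$n_undefined, 1)
  expect_error(loo_classify(F, rep("OT", 10)), "2 distinct")
})

test_that("LOO accuracy matches a direct per-subject reimplementation", {
  set.seed(14)
  F <- matrix(rnorm(12 * 30), 12, 30)
  F[1:6, ] <- F[1:6, ] + 0.5
  labels <- rep(c("A", "B"), each = 6)
  res <- loo_classify(F, labels)
  # independent oracle: explicit loop with cor()
  preds <- vapply(1:12, function(i) {
    ma <- colMeans(F[setdiff(which(labels == "A"), i), , drop = FALSE])
    mb <- colMeans(F[setdiff(which(labels == "B"), i), , drop = FALSE])
    ca <- cor(F[i, ], ma); cb <- cor(F[i, ], mb)
    if (ca == cb) NA_character_ else if (ca > cb) "A" else "B"
  }, character(1))
  expect_equal(res$predictions$predicted, preds)
  expect_equal(res$accuracy, mean(preds == labels, na.rm = FALSE))
})

test_that("LOO classification is invariant to common affine rescaling", {
  set.seed(15)
  F <- matrix(rnorm(20 * 40), 20, 40) +
    rep(c(0.4, -0.4), each = 10) %o% rep(1, 40)
  labels <- rep(c("A", "B"), each = 10)
  base <- loo_classify(F, labels)
  scaled <- loo_classify(3.7 * F + 11, labels)
  expect_equal(scaled$accuracy, base$accuracy)
  expect_equal(scaled$predictions$predicted, base$predictions$predicted)
})

test_that("permutation p follows the literal greater-or-equal rule", {
  set.seed(16)
  # strong signal: actual accuracy above every null accuracy -> p = 0
  F <- rbind(matrix(rnorm(8 * 20, 3), 8, 20) * rep(c(1, -1), each = 4))
  labels <- rep(c("A", "B"), each = 4)
  template <- sin(seq(0, 4 * pi, length.out = 20))
  F <- rbind(t(replicate(6, template + rnorm(20, 0, 0.01))),
             t(replicate(6, -template + rnorm(20, 0, 0.01))))
  labels <- rep(c("A", "B"), each = 6)
  res <- permutation_test(F, labels, n_permutations = 200, seed = 2)
  expect_equal(res$accuracy, 1.0)
  expect_lte(res$p_value, mean(res$null_distribution >= 1))
  expect_equal(res$p_value,
               mean(res$null_distribution >= res$accuracy))
  expect_length(res$null_distribution, 200)
  # degenerate: every permutation at least as good -> p = 1
  Fc <- matrix(rnorm(6 * 10), 6, 10)
  rc <- permutation_test(Fc, rep(c("A", "B"), each = 3),
                         n_permutations = 50, seed = 3)
  if (all(rc$null_distribution >= rc$accuracy))
    expect_equal(rc$p_value, 1.0)
  # determinism
  res2 <- permutation_test(F, labels, n_permutations = 200, seed = 2)
  expect_identical(res$null_distribution, res2$null_distribution)
})

test_that("shuffling labels and features together leaves accuracy unchanged", {
  set.seed(17)
  F <- matrix(rnorm(16 * 25), 16, 25) +
    rep(c(0.5, -0.5), each = 8) %o% rep(1, 25)
  labels <- rep(c("A", "B"), each = 8)
  base <- loo_classify(F, labels)
  perm <- sample(16)
  shuf <- loo_classify(F[perm, ], labels[perm])
  expect_equal(shuf$accuracy, base$accuracy)
})

test_that("accuracy grows from chance to perfect along the effect-size sweep", {
  set.seed(18)
  template <- sin(seq(0, 4 * pi, length.out = 30))
  acc_at <- vapply(c(0, 0.5, 3), function(eff) {
    accs <- replicate(20, {
      F <- rbind(t(replicate(8, eff * template + rnorm(30))),
                 t(replicate(8, -eff * template + rnorm(30))))
      loo_classify(F, rep(c("A", "B"), each = 8))$accuracy
    })
    mean(accs)
  }, numeric(1))
  expect_lt(abs(acc_at[1] - 0.5), 0.1)
  expect_gt(acc_at[2], acc_at[1])
  expect_gt(acc_at[3], 0.95)
})
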