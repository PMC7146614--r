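# Brute-force spectral energy: explicit O(n^2) DFT sum.
dft_energy_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  acc <- 0
  for (kk in k) {
    X <- sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
    acc <- acc + Mod(X)^2
  }
  acc / n^2
}

test_that("channel statistics match hand-computed cases", {
  s <- channel_stats(c(1, 1, 1, 1))
  expect_equal(unname(s[c("mean", "std", "variance", "rms", "energy", "abs_diff")]),
               c(1, 0, 0, 1, 1, 0))
  s2 <- channel_stats(c(1, -1, 1, -1))
  expect_equal(unname(s2[c("mean", "variance", "rms", "energy", "abs_diff")]),
               c(0, 1, 1, 1, 2))
  expect_error(channel_stats(1), "at least 2")
})

test_that("channel statistics agree with independent oracles on random input", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(2:64, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    s <- channel_stats(x)
    expect_equal(s[["mean"]], mean(x))
    expect_equal(s[["variance"]], var(x) * (n - 1) / n)
    expect_equal(s[["std"]], sqrt(var(x) * (n - 1) / n))
    expect_equal(s[["rms"]], sqrt(mean(x^2)))
    expect_equal(s[["energy"]], mean(x^2))
    expect_equal(s[["abs_diff"]], mean(abs(diff(x))))
    # Parseval: spectral energy equals time-domain energy
    expect_equal(s[["spectral_energy"]], s[["energy"]], tolerance = 1e-9)
    if (i <= 20) {
      expect_equal(s[["spectral_energy"]], dft_energy_oracle(x), tolerance = 1e-9)
    }
  }
})

test_that("statistics scale as expected under x -> c x", {
  set.seed(11)
  x <- rnorm(50)
  c0 <- 3.7
  s1 <- channel_stats(x)
  s2 <- channel_stats(c0 * x)
  linear <- c("rms", "mean", "std", "abs_diff")
  quadratic <- c("energy", "spectral_energy", "variance")
  expect_equal(unname(s2[linear]), unname(c0 * s1[linear]))
  expect_equal(unname(s2[quadratic]), unname(c0^2 * s1[quadratic]))
})

test_that("roll and pitch are quadrant-aware gravity angles in degrees", {
  expect_equal(roll(0, 1), 0)
  expect_equal(roll(1, 0), 90)
  expect_equal(roll(1, 1), 45)
  expect_equal(pitch(0, 1), 0)
  expect_equal(pitch(1, 0), 90)
  expect_equal(pitch(1, 1), 45)
  expect_equal(roll(-1, -1), -135)
  expect_warning(out <- roll(0, 0), "degenerate")
  expect_equal(out, 0)
  # vectorized atan2 oracle
  set.seed(12)
  y <- rnorm(1000); z <- rnorm(1000)
  expect_equal(roll(y, z), 180 / pi * atan2(y, z))
  expect_true(all(roll(y, z) > -180 & roll(y, z) <= 180))
})

test_that("sma and sv match their defining sums and sv <= sma", {
  expect_equal(sma(c(0, 0), c(0, 0)), 0)
  expect_equal(sma(c(1, -1), c(2, -2)), 3)
  expect_equal(sma(3, 4), 7)
  expect_equal(sv(3, 4), 5)
  expect_equal(sv(c(3, 0), c(4, 0)), 2.5)
  expect_error(sma(1:3, 1:2), "equal length")
  expect_error(sv(numeric(0), numeric(0)), "empty")
  set.seed(13)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(sma(x, y), sum(abs(x) + abs(y)) / n)
    expect_equal(sv(x, y), sum(sqrt(x^2 + y^2)) / n)
    expect_gte(sma(x, y), 0)
    expect_lte(sv(x, y), sma(x, y) + 1e-12)
  }
})

test_that("feature sets have the documented cardinality and ordering", {
  expect_length(feature_names("FS1"), 42)
  expect_length(feature_names("FS2"), 58)
  expect_equal(anyDuplicated(feature_names("FS2")), 0L)
  expect_equal(feature_names("FS1")[1:7],
               paste0("ax_", c("rms", "mean", "std", "energy",
                               "spectral_energy", "abs_diff", "variance")))
  expect_equal(utils::tail(feature_names("FS2"), 2), c("sma", "sv"))
  expect_equal(setdiff(feature_names("FS2"), feature_names("FS1")),
               c(paste0("roll_", c("rms", "mean", "std", "energy",
                                   "spectral_energy", "abs_diff", "variance")),
                 paste0("pitch_", c("rms", "mean", "std", "energy",
                                    "spectral_energy", "abs_diff", "variance")),
                 "sma", "sv"))

  set.seed(14)
  seg <- segment_nonoverlap(fake_portion(90))[[1]]
  fv1 <- featurize(seg, "FS1")
  fv2 <- featurize(seg, "FS2")
  expect_length(fv1$values, 42)
  expect_length(fv2$values, 58)
  expect_equal(length(fv2$values) - length(fv1$values), 16)
  expect_equal(names(fv1$values), feature_names("FS1"))
  expect_equal(names(fv2$values), feature_names("FS2"))
  # FS2 extends FS1 without changing the shared features
  expect_equal(fv2$values[feature_names("FS1")], fv1$values)
  # variance = std^2 for every channel
  for (ch in c("ax", "gy", "roll")) {
    expect_equal(fv2$values[[paste0(ch, "_variance")]],
                 fv2$values[[paste0(ch, "_std")]]^2, tolerance = 1e-12)
  }
})

test_that("a static gravity-aligned segment has all-zero derived features", {
  n <- 50
  p <- fake_portion(n, accel = cbind(0, 0, rep(1, n)), gyro = matrix(0, n, 3))
  seg <- segment_nonoverlap(p)[[1]]
  fv <- featurize(seg, "FS2")
  gyro_feats <- fv$values[grep("^g[xyz]_", names(fv$values))]
  expect_true(all(gyro_feats == 0))
  rp_feats <- fv$values[grep("^(roll|pitch)_", names(fv$values))]
  expect_true(all(abs(rp_feats) < 1e-12))
  expect_equal(unname(fv$values[c("sma", "sv")]), c(0, 0))
})

test_that("feature matrices carry metadata plus ordered feature columns", {
  set.seed(15)
  portions <- list(fake_portion(60, mas_label = 1, subject_id = "A"),
                   fake_portion(60, mas_label = 4, subject_id = "B"))
  segs <- build_segment_table(portions, "overlap50")
  fm <- feature_matrix(segs, "FS2")
  expect_equal(dim(fm), c(10, 4 + 58))
  expect_equal(names(fm)[1:4], feature_meta_cols())
  expect_equal(names(fm)[-(1:4)], feature_names("FS2"))
  expect_equal(fm$mas_label, rep(c(1L, 4L), each = 5))
  expect_equal(fm$scheme, rep("overlap50", 10))
})
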