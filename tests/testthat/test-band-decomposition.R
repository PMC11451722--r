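test_that("coarse graining averages windows, truncates tails, composes", {
  expect_equal(coarse_grain(c(1, 3, 5, 7), 2), c(2, 6))
  x <- stats::rnorm(101)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(length(coarse_grain(x, 7)), 14)       # floor(101/7)
  expect_equal(coarse_grain(x, 7), colMeans(matrix(x[1:98], nrow = 7)))
  # composition at compatible scales
  y <- stats::rnorm(96)
  expect_equal(coarse_grain(coarse_grain(y, 4), 3), coarse_grain(y, 12))
  expect_error(coarse_grain(x, 0), "positive")
  expect_error(coarse_grain(numeric(0), 2), "empty")
})

test_that("coarse graining equals Haar approximations up to 2^(k/2)", {
  set.seed(31)
  x <- stats::rnorm(512)
  for (k in 1:4) {
    d <- dwt_decompose(x, levels = k, wavelet = "haar")
    expect_equal(d$approx, coarse_grain(x, 2^k) * 2^(k / 2), tolerance = 1e-12)
  }
})

test_that("wavelet decomposition reconstructs perfectly and conserves energy", {
  set.seed(32)
  for (wv in c("haar", "db2", "db4", "db8")) {
    x <- stats::rnorm(4096)
    d <- dwt_decompose(x, levels = 5, wavelet = wv)
    expect_lt(max(abs(dwt_reconstruct(d) - x)), 1e-10)
    # orthogonality: coefficient energy equals signal energy
    en <- sum(d$approx^2) + sum(unlist(d$details)^2)
    expect_equal(en, sum(x^2), tolerance = 1e-8)
  }
  # unit impulse reconstructs exactly
  imp <- c(1, numeric(255))
  expect_lt(max(abs(dwt_reconstruct(dwt_decompose(imp, 4)) - imp)), 1e-10)
  # constant series has all detail coefficients zero (Haar)
  d <- dwt_decompose(rep(2.5, 128), 4, wavelet = "haar")
  expect_true(all(abs(unlist(d$details)) < 1e-12))
  expect_error(dwt_decompose(stats::rnorm(7), 3), "too short")
})

test_that("a tone concentrates energy in the detail level containing it", {
  x <- sin(2 * pi * 40 * (0:4095) / 256)          # 40 Hz at fs 256: level 2 (32, 64]
  d <- dwt_decompose(x, levels = 6, wavelet = "db8")
  en <- vapply(d$details, function(v) sum(v^2), numeric(1))
  tot <- sum(en) + sum(d$approx^2)
  expect_gt(en[2] / tot, 0.8)
})

test_that("band splitting yields named dyadic bands that sum to the input", {
  set.seed(33)
  x <- stats::rnorm(1024)
  b <- to_band_signals(x, fs = 250)
  expect_named(b$bands, c("gamma2", "gamma1", "beta", "alpha", "theta", "delta"))
  for (j in seq_along(b$ranges))
    expect_equal(b$ranges[[j]], c(250 / 2^(j + 1), 250 / 2^j))
  expect_lt(max(abs(Reduce(`+`, b$bands) + b$approx - x)), 1e-8)
  expect_equal(length(b$bands$alpha), length(x))    # full time resolution
  expect_error(to_band_signals(x, fs = 16, n_bands = 6), "floor")
})

test_that("a 10 Hz tone lands >80% in the alpha band", {
  r <- generate_system("sine", 2048, params = list(frequency = 10), fs = 250)
  b <- to_band_signals(r, fs = 250)
  pw <- vapply(b$bands, band_power, numeric(1))
  expect_gt(pw["alpha"] / (sum(pw) + band_power(b$approx)), 0.8)
})

test_that("band power matches analytic values", {
  t_ <- (0:9999) / 1000
  expect_equal(band_power(sin(2 * pi * 10 * t_)), 0.5, tolerance = 1e-3)
  expect_equal(band_power(numeric(5)), 0)
  w <- generate_system("white_noise", 10000, params = list(sd = 2), seed = 9)
  expect_equal(band_power(w$data[1, ]), 4, tolerance = 0.05 * 4)
  expect_error(band_power(numeric(0)), "empty")
})

test_that("total power splits across bands within 1% for long series", {
  set.seed(34)
  x <- stats::rnorm(4096)
  b <- to_band_signals(x, fs = 128)
  # band series overlap in time, so compare energy via coefficients instead:
  # orthogonal split => band power + approx power ~ total power
  tot <- band_power(x)
  parts <- sum(vapply(b$bands, band_power, numeric(1))) + band_power(b$approx)
  expect_equal(parts, tot, tolerance = 0.01 * tot)
})
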