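test_that("logistic map reproduces direct iteration", {
  r <- generate_system("logistic", 5, params = list(r = 4), initial_state = 0.3)
  # x <- 4 x (1 - x) iterated by hand from 0.3
  expect_equal(as.numeric(r$data[1, ]),
               c(0.3, 0.84, 0.5376, 0.99434496, 0.0224922421),
               tolerance = 1e-9)
})

test_that("sinusoid hits quarter-period samples exactly", {
  r <- generate_system("sine", 4, params = list(frequency = 10), fs = 40)
  expect_equal(as.numeric(r$data[1, ]), c(0, 1, 0, -1), tolerance = 1e-12)
})

test_that("Lorenz trajectories stay on the bounded attractor and depend on the start", {
  a <- generate_system("lorenz", 2000)
  b <- generate_system("lorenz", 2000, initial_state = c(1.001, 1, 1))
  expect_equal(ncol(a$data), 2000)
  expect_lt(max(abs(a$data["x", ])), 25)
  expect_lt(max(abs(a$data["y", ])), 30)
  expect_true(all(a$data["z", ] > 0 & a$data["z", ] < 60))
  expect_lt(max(abs(b$data["x", ])), 25)
  # nearby starts diverge (chaos) but both remain bounded
  expect_gt(max(abs(a$data["x", ] - b$data["x", ])), 1)
  # deterministic: identical spec reproduces bit-identically
  expect_identical(a$data, generate_system("lorenz", 2000)$data)
})

test_that("stochastic generators require a seed and are seed-reproducible", {
  expect_error(generate_system("white_noise", 100), "seed")
  for (nm in c("white_noise", "pink_noise", "brownian", "fgn")) {
    a <- generate_system(nm, 256, seed = 5)
    b <- generate_system(nm, 256, seed = 5)
    expect_identical(a$data, b$data)
    expect_false(identical(a$data, generate_system(nm, 256, seed = 6)$data))
  }
})

test_that("fGn has the designed mean, variance and memory structure", {
  x <- generate_fgn(0.5, 10000, seed = 1)
  expect_lt(abs(mean(x)), 3 / sqrt(10000))          # mean -> 0 within 3 SE
  expect_lt(abs(stats::var(x) - 1), 3 * sqrt(2 / 10000) * 3)
  expect_lt(abs(stats::acf(x, plot = FALSE)$acf[2]), 0.05)  # H = .5 is white
  y8 <- generate_fgn(0.8, 10000, seed = 2)
  y2 <- generate_fgn(0.2, 10000, seed = 2)
  # theoretical lag-1 autocorrelation: 2^(2H-1) - 1
  expect_equal(stats::acf(y8, plot = FALSE)$acf[2], 2^0.6 - 1, tolerance = 0.1)
  expect_lt(stats::acf(y2, plot = FALSE)$acf[2], 0)
  expect_error(generate_fgn(1.2, 100, seed = 1), "hurst")
  expect_error(generate_fgn(0, 100, seed = 1), "hurst")
})

test_that("fGn Hurst target is recovered by an aggregate-variance estimator", {
  # independent estimator: var of block means of fGn scales as s^(2H-2)
  agv_hurst <- function(x) {
    sizes <- c(4, 8, 16, 32, 64, 128)
    v <- vapply(sizes, function(s) {
      m <- length(x) %/% s
      stats::var(colMeans(matrix(x[1:(m * s)], nrow = s)))
    }, numeric(1))
    fit <- stats::lm.fit(cbind(1, log(sizes)), log(v))
    1 + unname(fit$coefficients[2]) / 2
  }
  x <- generate_fgn(0.8, 10000, seed = 3)
  expect_equal(agv_hurst(x), 0.8, tolerance = 0.1)
  w <- generate_fgn(0.5, 10000, seed = 4)
  expect_equal(agv_hurst(w), 0.5, tolerance = 0.1)
})

test_that("cohort ages span the range on a grid and the alpha power effect is monotone", {
  co <- generate_cohort(n_subjects = 10, seed = 11, noise_sd = 0)
  expect_equal(range(co$cohort$age_months), c(6, 84))
  expect_true(all(diff(co$cohort$age_months) > 0))
  expect_equal(length(co$recordings), 10)
  expect_equal(n_channels(co$recordings[[1]]), 4)
  # noise-free: designed alpha-band power strictly increases with age
  pw <- vapply(co$recordings, function(r) {
    b <- to_band_signals(r$data["O1", ], fs = r$fs)
    band_power(b$bands$alpha)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # and a designed decreasing band decreases
  pd <- vapply(co$recordings, function(r) {
    b <- to_band_signals(r$data["O1", ], fs = r$fs)
    band_power(b$bands$theta)
  }, numeric(1))
  expect_true(all(diff(pd) < 0))
})

test_that("cohort generation is reproducible and subject streams are independent", {
  a <- generate_cohort(n_subjects = 6, seed = 3)
  b <- generate_cohort(n_subjects = 6, seed = 3)
  expect_identical(lapply(a$recordings, `[[`, "data"),
                   lapply(b$recordings, `[[`, "data"))
  expect_false(identical(a$recordings[[1]]$data,
                         generate_cohort(n_subjects = 6, seed = 4)$recordings[[1]]$data))
  expect_error(generate_cohort(n_subjects = 4, n_channels = 25, seed = 1),
               "montage")
})
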