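test_that("assemble_tensor aligns subjects, sorts axes and masks gaps", {
  co <- generate_cohort(n_subjects = 3, seed = 71)
  cfg <- feature_config(measures = c("Power", "SampEn"), max_points = 200)
  ft <- lapply(co$recordings, extract_features, config = cfg)
  x <- assemble_tensor(ft, co$cohort)
  expect_equal(unname(dim(x$values)), c(3, 4, 6, 2))
  expect_equal(dimnames(x$values)[[1]], co$cohort$subject_id)
  expect_equal(dimnames(x$values)[[2]], sort(co$recordings[[1]]$labels))
  # single subject: tensor slice equals the feature table
  x1 <- assemble_tensor(ft[1], co$cohort[1, ])
  tb <- ft[[1]]
  expect_equal(x1$values[1, "O1", "alpha", "Power"],
               tb$Power[tb$channel == "O1" & tb$band == "alpha"])
  # missing channel slice -> masked, others intact
  ft2 <- ft
  ft2[[2]] <- ft2[[2]][ft2[[2]]$channel != "O1", ]
  x2 <- assemble_tensor(ft2, co$cohort)
  expect_true(all(x2$mask[2, "O1", , ]))
  expect_false(any(x2$mask[2, "F3", , ]))
  expect_false(any(x2$mask[1, , , ]))
  expect_error(assemble_tensor(stats::setNames(ft, c("a", "a", "b"))), "duplicate")
})

test_that("normalization z-scores per measure, flags constants, round-trips", {
  set.seed(72)
  x <- rank_tensor(matrix(stats::rnorm(24), 8), matrix(stats::rnorm(9), 3),
                   matrix(stats::rnorm(12), 4), matrix(stats::rnorm(15), 5))
  x$values[, , , 2] <- 7                      # constant measure slice
  x <- feature_tensor(x$values, x$mask)
  n <- normalize_tensor(x)
  for (ms in dimnames(n$values)[[4]][-2]) {
    v <- n$values[, , , ms]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(stats::sd(v) - 1), 1e-10)
  }
  expect_true(all(n$values[, , , 2] == 0))
  expect_true("m2" %in% attr(n, "constant"))
  back <- denormalize_tensor(n)
  expect_equal(back$values[, , , -2], x$values[, , , -2], tolerance = 1e-10)
})

test_that("CP recovers exact low-rank structure", {
  set.seed(73)
  A <- matrix(stats::rnorm(40), 10); B <- matrix(stats::rnorm(16), 4)
  C <- matrix(stats::rnorm(20), 5); D <- matrix(stats::rnorm(24), 6)
  x1 <- rank_tensor(A[, 1, drop = FALSE], B[, 1, drop = FALSE],
                    C[, 1, drop = FALSE], D[, 1, drop = FALSE])
  f1 <- cp_decompose(x1, 1, seed = 1)
  expect_gt(f1$fit, 1 - 1e-6)
  x3 <- rank_tensor(A[, 1:3], B[, 1:3], C[, 1:3], D[, 1:3])
  f3 <- cp_decompose(x3, 3, seed = 1)
  expect_gt(f3$fit, 1 - 1e-6)
  expect_gt(match_congruence(A[, 1:3], f3$factors$subject), 0.99)
  expect_gt(match_congruence(D[, 1:3], f3$factors$measure), 0.99)
  # nested model classes
  expect_gte(f3$fit + 1e-9, cp_decompose(x3, 1, seed = 1)$fit)
  # unit-norm columns, descending weights
  expect_equal(colSums(f3$factors$sensor^2), rep(1, 3), tolerance = 1e-8)
  expect_true(all(diff(f3$weights) <= 1e-8))
})

test_that("identical seeds give identical factors; masked cells are inert", {
  set.seed(74)
  x <- rank_tensor(matrix(stats::rnorm(24), 12), matrix(stats::rnorm(8), 4),
                   matrix(stats::rnorm(6), 3), matrix(stats::rnorm(10), 5))
  a <- cp_decompose(x, 2, seed = 9)
  b <- cp_decompose(x, 2, seed = 9)
  expect_identical(a$factors, b$factors)
  mask <- array(FALSE, dim(x$values)); mask[3, 2, 1, 4] <- TRUE
  xa <- feature_tensor(x$values, mask)
  vals2 <- x$values; vals2[3, 2, 1, 4] <- 1e6
  xb <- feature_tensor(vals2, mask)
  fa <- cp_decompose(xa, 2, seed = 9)
  fb <- cp_decompose(xb, 2, seed = 9)
  expect_equal(fa$factors, fb$factors, tolerance = 1e-12)
})

test_that("explained_fit matches the direct residual norm", {
  set.seed(75)
  x <- rank_tensor(matrix(stats::rnorm(20), 10, 2), matrix(stats::rnorm(6), 3, 2),
                   matrix(stats::rnorm(8), 4, 2), matrix(stats::rnorm(4), 2, 2))
  f <- cp_decompose(x, 1, seed = 2)
  recon <- 0
  for (r in seq_len(f$rank))
    recon <- recon + f$weights[r] * outer(outer(outer(
      f$factors$subject[, r], f$factors$sensor[, r]),
      f$factors$band[, r]), f$factors$measure[, r])
  direct <- 1 - sqrt(sum((x$values - recon)^2)) / sqrt(sum(x$values^2))
  expect_equal(explained_fit(x, f), direct, tolerance = 1e-12)
})

test_that("gamma = 0 supervision is exactly the unsupervised factorization", {
  set.seed(76)
  x <- rank_tensor(matrix(stats::rnorm(30), 10, 3), matrix(stats::rnorm(12), 4, 3),
                   matrix(stats::rnorm(9), 3, 3), matrix(stats::rnorm(15), 5, 3))
  y <- stats::rnorm(10)
  f0 <- supervised_cp(x, 2, supervision_spec(y, gamma = 0), seed = 4)
  fu <- cp_decompose(x, 2, seed = 4)
  expect_identical(f0$factors, fu$factors)
  expect_identical(f0$weights, fu$weights)
})

test_that("supervision recovers a target-driven component out of sample", {
  # one of three components driven by the target; noiseless construction
  set.seed(77)
  n <- 30
  y <- seq(-1, 1, length.out = n)
  A <- cbind(y, matrix(stats::rnorm(2 * n), n))
  B <- matrix(stats::rnorm(12), 4); C <- matrix(stats::rnorm(9), 3)
  D <- matrix(stats::rnorm(15), 5)
  x <- rank_tensor(A, B[, 1:3], C[, 1:3], D[, 1:3])
  fit <- supervised_cp(x, 3, supervision_spec(y, gamma = 3), seed = 5)
  S <- project_subjects(fit, x)
  expect_gt(max(abs(stats::cor(S, y))), 0.99)
  expect_false(is.null(fit$supervised_component))
  # pure rank-1 target tensor: held-out projection is near-perfect
  x1 <- rank_tensor(cbind(y), B[, 1, drop = FALSE], C[, 1, drop = FALSE],
                    D[, 1, drop = FALSE])
  f1 <- supervised_cp(x1, 1, supervision_spec(y, gamma = 1), seed = 6)
  tr <- 1:20
  xtr <- feature_tensor(x1$values[tr, , , , drop = FALSE])
  ftr <- supervised_cp(xtr, 1, supervision_spec(y[tr], gamma = 1), seed = 6)
  xte <- feature_tensor(x1$values[-tr, , , , drop = FALSE])
  Ste <- project_subjects(ftr, xte)
  expect_gt(abs(stats::cor(Ste[, 1], y[-tr])), 0.99)
  expect_error(supervision_spec(y, gamma = -1), "gamma")
})

test_that("tensor persistence round-trips through the portable directory", {
  set.seed(78)
  x <- rank_tensor(matrix(stats::rnorm(12), 6, 2), matrix(stats::rnorm(6), 3, 2),
                   matrix(stats::rnorm(4), 2, 2), matrix(stats::rnorm(6), 3, 2))
  x$mask[2, 1, 1, 2] <- TRUE
  x <- feature_tensor(x$values, x$mask)
  dir <- withr::local_tempdir()
  write_tensor(x, dir)
  y <- read_tensor(dir)
  expect_equal(y$values, x$values, tolerance = 1e-12)
  expect_identical(y$mask, x$mask)
})
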