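test_that("delay selection finds the quarter period of a tone and lag 1 for noise", {
  s <- generate_system("sine", 500, params = list(frequency = 5), fs = 100)
  expect_equal(as.integer(select_delay(s$data[1, ], "autocorr_zero")), 5L)
  w <- generate_system("white_noise", 2000, seed = 21)
  expect_equal(as.integer(select_delay(w$data[1, ], "autocorr_zero")), 1L)
  expect_lte(as.integer(select_delay(w$data[1, ], "mutual_info_min")), 2L)
  expect_error(select_delay(rep(1, 100)), "constant")
  expect_error(select_delay(1:5), "short")
})

test_that("delay embedding lays out lagged coordinates", {
  e <- delay_embed(c(1, 2, 3, 4), m = 2, tau = 1)
  expect_equal(unclass(e)[, 1], c(1, 2, 3))
  expect_equal(unclass(e)[, 2], c(2, 3, 4))
  x <- stats::rnorm(10)
  expect_equal(nrow(delay_embed(x, 3, 2)), 6)   # n - (m-1) tau
  e1 <- delay_embed(x, 1, 1)
  expect_equal(as.numeric(unclass(e1)), x)
  expect_error(delay_embed(x, 6, 2), "short")
})

test_that("false nearest neighbors saturates for deterministic signals only", {
  # generic (non-integer samples-per-period) sinusoid: a closed curve in 2D
  s <- generate_system("sine", 800, params = list(frequency = 5.3), fs = 100)
  m_sine <- select_embedding_dim(s$data[1, ], tau = 5)
  expect_lte(as.integer(m_sine), 2L)
  expect_false(attr(m_sine, "warning"))
  lz <- generate_system("lorenz", 1500)
  tau <- as.integer(select_delay(lz$data[1, ], "mutual_info_min"))
  m_lz <- select_embedding_dim(lz$data[1, ], tau = tau)
  expect_lte(as.integer(m_lz), 4L)
  w <- generate_system("white_noise", 800, seed = 22)
  m_w <- select_embedding_dim(w$data[1, ], tau = 1, max_m = 8)
  expect_equal(as.integer(m_w), 8L)
  expect_true(attr(m_w, "warning"))
})

test_that("fixed-RR mode hits the target density on continuous-distance signals", {
  lz <- generate_system("lorenz", 2300)
  x <- lz$data[1, 1:2100]
  e <- delay_embed(x, 3, 10)
  rp <- recurrence_matrix(e, target_rr = 0.05, theiler = 10)
  expect_lt(abs(rp$achieved_rr - 0.05), 0.005)
  expect_true(isSymmetric(rp$matrix))
  # property over stochastic signals and targets
  for (rr in c(0.02, 0.1)) {
    w <- generate_system("white_noise", 400, seed = 23)
    rpw <- recurrence_matrix(delay_embed(w$data[1, ], 3, 2),
                             target_rr = rr, theiler = 2)
    expect_lt(abs(rpw$achieved_rr - rr), 0.005)
  }
})

test_that("epsilon mode marks exactly the close pairs; degenerate cases behave", {
  pts <- delay_embed(c(0, 10, 20, 30, 40, 50), 1, 1)
  rp0 <- recurrence_matrix(pts, epsilon = 0)
  expect_equal(rp0$matrix, diag(6), ignore_attr = TRUE)
  same <- delay_embed(rep(1, 12), 1, 1)
  expect_warning(rp1 <- recurrence_matrix(same, target_rr = 0.1), "identical")
  expect_true(all(rp1$matrix == 1))
  expect_error(recurrence_matrix(pts), "exactly one")
  expect_error(recurrence_matrix(pts, target_rr = 0.05, epsilon = 1), "exactly one")
  # raising epsilon never removes recurrences
  set.seed(24)
  y <- delay_embed(stats::rnorm(60), 2, 1)
  r_small <- recurrence_matrix(y, epsilon = 0.5)$matrix
  r_big <- recurrence_matrix(y, epsilon = 1)$matrix
  expect_true(all(r_big >= r_small))
})

test_that("line histograms match the brute-force scanner on hand matrices", {
  # all-ones 5x5, theiler 1: two length-4 runs on each remaining diagonal side
  R5 <- matrix(1L, 5, 5)
  h <- line_histograms(R5, theiler = 1)
  o <- oracle_line_hists(R5, theiler = 1)
  expect_equal(sort(h$diagonal), sort(o$diagonal))
  expect_equal(sort(h$vertical), sort(o$vertical))
  expect_equal(sort(h$white_vertical), sort(o$white_vertical))
  # checkerboard: verticals alternate (all singleton runs); diagonals
  # parallel to the identity are constant, so odd offsets are full runs
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  hc <- line_histograms(cb, theiler = 0)
  expect_true(all(hc$vertical == 1))
  expect_true(all(hc$white_vertical == 1))
  oc <- oracle_line_hists(cb, theiler = 0)
  expect_equal(sort(hc$diagonal), sort(oc$diagonal))
  # random hand matrices, symmetric, against the exhaustive oracle
  set.seed(25)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 1L
    th <- sample(0:1, 1)
    h <- line_histograms(A, theiler = th)
    o <- oracle_line_hists(A, theiler = th)
    expect_equal(sort(h$diagonal), sort(o$diagonal))
    expect_equal(sort(h$vertical), sort(o$vertical))
    expect_equal(sort(h$white_vertical), sort(o$white_vertical))
  }
})

test_that("all nine RQA measures equal the brute-force oracle exactly", {
  set.seed(26)
  for (i in 1:10) {
    n <- sample(6:8, 1)
    A <- matrix(rbinom(n * n, 1, 0.45), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 1L
    th <- sample(0:1, 1)
    m <- rqa_measures(A, lmin = 2, theiler = th)
    o <- oracle_rqa(A, lmin = 2, theiler = th)
    expect_equal(as.numeric(m), as.numeric(o), tolerance = 1e-12,
                 label = sprintf("case %d (n=%d, theiler=%d)", i, n, th))
  }
})

test_that("a noise-free sinusoid is fully deterministic; iid noise is not", {
  s <- generate_system("sine", 2000, params = list(frequency = 10), fs = 250)
  e <- delay_embed(s$data[1, ], m = 3, tau = 6)       # quarter period ~ 25/4
  rp <- recurrence_matrix(e, target_rr = 0.05, theiler = 6)
  m <- rqa_measures(rp, lmin = 2)
  expect_equal(unname(m["DET"]), 1, tolerance = 0.02)
  expect_gte(unname(m["Lmax"]), 100)
  w <- generate_system("white_noise", 2000, seed = 27)
  # embeddings without coordinate sharing between diagonal neighbors
  for (emb in list(delay_embed(w$data[1, ], 1, 1), delay_embed(w$data[1, ], 3, 2))) {
    rpw <- recurrence_matrix(emb, target_rr = 0.05,
                             theiler = attr(emb, "tau"))
    expect_lt(unname(rqa_measures(rpw, lmin = 2)["DET"]), 0.3)
  }
})

test_that("RQA measure bounds and epsilon monotonicity hold across signals", {
  set.seed(28)
  sigs <- list(generate_system("white_noise", 300, seed = 1)$data[1, ],
               generate_system("fgn", 300, params = list(hurst = 0.8), seed = 2)$data[1, ],
               generate_system("lorenz", 400)$data[1, 1:300])
  for (x in sigs) {
    e <- delay_embed(x, 3, 2)
    rp <- recurrence_matrix(e, target_rr = 0.08, theiler = 2)
    m <- rqa_measures(rp)
    expect_true(all(m[c("DET", "LAM")] >= 0 & m[c("DET", "LAM")] <= 1))
    expect_lte(m["Lmax"], nrow(e) - 1)
    expect_true(all(m[c("Lentr", "VertEnt", "AvgWhiteVertEnt")] >= 0))
    r1 <- recurrence_matrix(e, epsilon = rp$epsilon)$matrix
    r2 <- recurrence_matrix(e, epsilon = rp$epsilon * 1.5)$matrix
    expect_true(all(r2 >= r1))
  }
})
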