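# Independent brute-force oracles. These re-derive expected values by direct
# enumeration, never by calling the package's own implementation paths.

# all maximal runs of 1s along every diagonal/column of a binary matrix,
# scanning cell by cell; theiler zeroes |i-j| <= theiler first
oracle_line_hists <- function(R, theiler = 0L) {
  np <- nrow(R)
  Rz <- R
  for (i in seq_len(np)) for (j in seq_len(np))
    if (abs(i - j) <= theiler) Rz[i, j] <- 0L
  runs <- function(v) {
    out <- integer(0); cur <- 0L
    for (b in c(v, 0L)) {
      if (b == 1L) cur <- cur + 1L
      else { if (cur > 0L) out <- c(out, cur); cur <- 0L }
    }
    out
  }
  diag_lens <- integer(0)
  for (off in seq.int(-(np - 1L), np - 1L)) {
    if (abs(off) <= theiler) next
    cells <- integer(0)
    for (i in seq_len(np)) {
      j <- i + off
      if (j >= 1L && j <= np) cells <- c(cells, Rz[i, j])
    }
    diag_lens <- c(diag_lens, runs(cells))
  }
  vert <- integer(0); white <- integer(0)
  for (j in seq_len(np)) {
    vert <- c(vert, runs(Rz[, j]))
    white <- c(white, runs(1L - Rz[, j]))
  }
  list(diagonal = diag_lens, vertical = vert, white_vertical = white)
}

# the nine RQA measures recomputed from oracle_line_hists from first principles
oracle_rqa <- function(R, lmin = 2L, theiler = 0L) {
  h <- oracle_line_hists(R, theiler)
  np <- nrow(R)
  n_off <- 0L; n_rec <- 0L
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (abs(i - j) > theiler) {
      n_off <- n_off + 1L
      if (R[i, j] == 1L) n_rec <- n_rec + 1L
    }
  }
  ent <- function(lens) {
    if (!length(lens)) return(0)
    p <- as.numeric(table(lens)) / length(lens)
    -sum(p * log(p))
  }
  d <- h$diagonal; v <- h$vertical; w <- h$white_vertical
  dk <- d[d >= lmin]; vk <- v[v >= lmin]
  c(RR = n_rec / n_off,
    DET = if (sum(d)) sum(dk) / sum(d) else 0,
    LAM = if (sum(v)) sum(vk) / sum(v) else 0,
    Lmean = if (length(dk)) mean(dk) else 0,
    Lmax = if (length(d)) max(d) else 0,
    Lentr = ent(dk),
    TT = if (length(vk)) mean(vk) else 0,
    VertEnt = ent(vk),
    AvgWhiteVertEnt = ent(w))
}

# direct O(n^2) double-loop template counting sample entropy
oracle_sampen <- function(x, m, r_abs) {
  n <- length(x)
  nt <- n - m
  chord <- function(i, j, mm) {
    mx <- 0
    for (k in 0:(mm - 1L)) mx <- max(mx, abs(x[i + k] - x[j + k]))
    mx
  }
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    if (chord(i, j, m) <= r_abs) B <- B + 1L
    if (chord(i, j, m + 1L) <= r_abs) A <- A + 1L
  }
  -log(A / B)
}

# direct approximate entropy (Pincus), self-matches included
oracle_apen <- function(x, m, r_abs) {
  n <- length(x)
  phi <- function(mm) {
    np <- n - mm + 1L
    tot <- 0
    for (i in seq_len(np)) {
      cnt <- 0L
      for (j in seq_len(np)) {
        mx <- 0
        for (k in 0:(mm - 1L)) mx <- max(mx, abs(x[i + k] - x[j + k]))
        if (mx <= r_abs) cnt <- cnt + 1L
      }
      tot <- tot + log(cnt / np)
    }
    tot / np
  }
  phi(m) - phi(m + 1L)
}

# direct ordinal-pattern entropy, ties by order of occurrence
oracle_permen <- function(x, order) {
  np <- length(x) - order + 1L
  pats <- character(np)
  for (i in seq_len(np)) pats[i] <- paste(order(x[i:(i + order - 1L)]), collapse = ".")
  p <- as.numeric(table(pats)) / np
  -sum(p * log(p))
}

# exhaustive shortest paths by Floyd-Warshall on a binary adjacency
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# exact betweenness centrality by enumerating all shortest paths (small n)
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  # count shortest paths s->t via dynamic programming over distance layers
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (t in which(D[s, ] == d)) {
        preds <- which(A[, t] == 1L & D[s, ] == d - 1)
        nsp[s, t] <- sum(nsp[s, preds])
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + nsp[s, v] * nsp[v, t] / nsp[s, t]
    }
    btw[v] <- tot / 2   # undirected: each unordered pair counted twice
  }
  btw
}

# Pearson r from the covariance formula, written out
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# relative factor congruence after greedy permutation/sign matching
match_congruence <- function(A, B) {
  R <- ncol(A)
  used <- logical(R)
  out <- numeric(R)
  for (r in seq_len(R)) {
    cc <- abs(suppressWarnings(stats::cor(A[, r], B)))
    cc[used] <- -Inf
    k <- which.max(cc)
    used[k] <- TRUE
    out[r] <- cc[k]
  }
  min(out)
}
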