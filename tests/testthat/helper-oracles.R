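# Independent brute-force oracles, deliberately written in the plainest
# possible pixel-by-pixel style so they share no code path with the package.

rand_gray <- function(n, m = n) matrix(stats::runif(n * m), n, m)

rand_rgb <- function(n, m = n) array(stats::runif(n * m * 3), dim = c(n, m, 3))

# All-pairs O(n^4) color correlogram.
oracle_correlogram <- function(labels, M, d_set) {
  n <- nrow(labels)
  mm <- ncol(labels)
  lab <- as.vector(labels)
  rr <- rep(seq_len(n), mm)
  cc <- rep(seq_len(mm), each = n)
  counts <- array(0, dim = c(M, M, length(d_set)))
  N <- length(lab)
  for (p1 in seq_len(N)) {
    for (p2 in seq_len(N)) {
      k <- max(abs(rr[p1] - rr[p2]), abs(cc[p1] - cc[p2]))
      ki <- match(k, d_set)
      if (!is.na(ki)) {
        counts[lab[p1], lab[p2], ki] <- counts[lab[p1], lab[p2], ki] + 1
      }
    }
  }
  gam <- counts
  for (ki in seq_along(d_set)) {
    for (i in seq_len(M)) {
      s <- sum(counts[i, , ki])
      gam[i, , ki] <- if (s > 0) counts[i, , ki] / s else 0
    }
  }
  list(counts = counts, gamma = gam)
}

# Chessboard distance to the nearest TRUE pixel by naive relaxation.
oracle_chessboard <- function(mask) {
  n <- nrow(mask)
  m <- ncol(mask)
  Tm <- matrix(Inf, n, m)
  Tm[mask] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- i + di
            jj <- j + dj
            if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
                Tm[ii, jj] + 1 < Tm[i, j]) {
              Tm[i, j] <- Tm[ii, jj] + 1
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  Tm
}

# Pure distance-decayed averaging filter: the ordered filter's reduction
# (B = G = 1, weight = a^T(y)), implemented pixel by pixel.
oracle_decay_filter <- function(D, mask, a) {
  Tm <- oracle_chessboard(mask)
  out <- D
  n <- nrow(D)
  m <- ncol(D)
  for (t in seq_len(max(Tm))) {
    cur <- out
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        if (Tm[i, j] != t) next
        ws <- 0
        vs <- 0
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- i + di
            jj <- j + dj
            if (ii < 1 || ii > n || jj < 1 || jj > m) next
            if (Tm[ii, jj] < t) {
              w <- a^Tm[ii, jj]
              ws <- ws + w
              vs <- vs + w * cur[ii, jj]
            }
          }
        }
        out[i, j] <- vs / ws
      }
    }
  }
  out
}

# Per-pixel window max-min by explicit scan.
oracle_window_range <- function(D, r) {
  n <- nrow(D)
  m <- ncol(D)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rs <- max(1, i - r):min(n, i + r)
      cs <- max(1, j - r):min(m, j + r)
      out[i, j] <- max(D[rs, cs]) - min(D[rs, cs])
    }
  }
  out
}

# Trapezoidal integration of an ROC curve.
oracle_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-length(roc$tpr)]) / 2)
}

# Direct clamped separable bilinear evaluation on pixel-center aligned grids.
oracle_bilinear <- function(m, factor) {
  interp1 <- function(x, u) {
    i0 <- floor(u)
    f <- u - i0
    a <- min(max(i0, 1), length(x))
    b <- min(max(i0 + 1, 1), length(x))
    (1 - f) * x[a] + f * x[b]
  }
  n <- nrow(m) * factor
  p <- ncol(m) * factor
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      u <- (i - 0.5) / factor + 0.5
      v <- (j - 0.5) / factor + 0.5
      rowvals <- vapply(seq_len(ncol(m)),
                        function(cc) interp1(m[, cc], u), numeric(1))
      out[i, j] <- interp1(rowvals, v)
    }
  }
  out
}

# Random reliability mask guaranteed non-empty.
rand_mask <- function(n, m = n, p_reliable = 0.4) {
  mk <- matrix(stats::runif(n * m) < p_reliable, n, m)
  if (!any(mk)) mk[sample.int(n * m, 1)] <- TRUE
  mk
}
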