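# Color quantization and histogram / correlogram / autocorrelogram features.

#' Chessboard (L-infinity) distance between two pixel coordinates
#'
#' @param p1,p2 length-2 integer vectors (row, col).
#' @return `max(|r1 - r2|, |c1 - c2|)`.
#' @export
linf_distance <- function(p1, p2) max(abs(p1 - p2))

#' Quantize an image into m colors
#'
#' For RGB input with `m` a perfect cube, uniform per-channel binning into
#' `m^(1/3)` bins per channel; otherwise a seeded k-means in RGB space.
#' Grayscale input uses `m` uniform bins. Deterministic for a fixed seed.
#'
#' @param image raster in \[0, 1\] (matrix or RGB array).
#' @param m number of colors, >= 2 (default 64 = 4x4x4 RGB bins).
#' @param seed seed for the k-means fallback.
#' @return object of class `"quantized_image"`: integer matrix `labels` with
#'   entries in 1..m, `m`, `palette` (m x 3 matrix of quantized colors).
#' @export
quantize_colors <- function(image, m = 64L, seed = 1L) {
  if (m < 2) stop("m must be >= 2")
  m <- as.integer(m)
  if (is.matrix(image)) {
    lab <- pmin(floor(pmin(pmax(image, 0), 1) * m) + 1L, m)
    centers <- (seq_len(m) - 0.5) / m
    pal <- cbind(centers, centers, centers)
  } else {
    b <- round(m^(1 / 3))
    R <- pmin(pmax(image[, , 1], 0), 1)
    G <- pmin(pmax(image[, , 2], 0), 1)
    B <- pmin(pmax(image[, , 3], 0), 1)
    if (b^3 == m) {
      lr <- pmin(floor(R * b), b - 1)
      lg <- pmin(floor(G * b), b - 1)
      lb <- pmin(floor(B * b), b - 1)
      lab <- lr * b^2 + lg * b + lb + 1L
      ctr <- (seq_len(b) - 0.5) / b
      grid <- expand.grid(b = ctr, g = ctr, r = ctr)  # b fastest, matching label
      pal <- as.matrix(grid[, c("r", "g", "b")])
    } else {
      X <- cbind(as.vector(R), as.vector(G), as.vector(B))
      ux <- unique(X)
      if (nrow(ux) <= m) {
        key <- paste(X[, 1], X[, 2], X[, 3])
        ukey <- paste(ux[, 1], ux[, 2], ux[, 3])
        lab <- match(key, ukey)
        pal <- rbind(ux, matrix(0, m - nrow(ux), 3))
      } else {
        km <- with_seed(seed, stats::kmeans(X, centers = m, nstart = 1,
                                            iter.max = 50))
        lab <- km$cluster
        pal <- km$centers
      }
    }
    lab <- matrix(as.integer(lab), nrow(R), ncol(R))
  }
  structure(list(labels = lab, m = m, palette = pal),
            class = "quantized_image")
}

#' Histogram of quantized colors
#'
#' `h_i` counts the pixels of color `c_i`; the counts sum to the pixel count
#' (n^2 for a square image), so `h_i / (rows * cols)` is the color probability.
#'
#' @param q a [quantize_colors()] result.
#' @return integer vector of length `m`.
#' @export
color_histogram <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  tabulate(q$labels, nbins = q$m)
}

# All (di, dj) offsets at exact L-infinity distance k (the square ring).
ring_offsets <- function(k) {
  g <- expand.grid(di = -k:k, dj = -k:k)
  as.matrix(g[pmax(abs(g$di), abs(g$dj)) == k, , drop = FALSE])
}

#' Color correlogram at a set of distances
#'
#' `gamma[i, j, k]` is the probability that a pixel at L-infinity distance
#' exactly `k` from a pixel of color `c_i` has color `c_j`, estimated by
#' counting all ordered pixel pairs on the distance-k square ring. Ring
#' positions falling outside the image are excluded from numerator and
#' denominator alike; colors absent from the image yield all-zero rows.
#'
#' @param q a [quantize_colors()] result.
#' @param d_set integer distances, each >= 1 (default `c(1, 3, 5, 7)`).
#' @return object of class `"correlogram_table"`: probability array `gamma`
#'   (m x m x |d_set|), raw pair `counts`, histogram `h`, `d_set`, `m`.
#' @export
color_correlogram <- function(q, d_set = c(1L, 3L, 5L, 7L)) {
  stopifnot(inherits(q, "quantized_image"))
  if (any(d_set < 1)) stop("all distances must be >= 1")
  lab <- q$labels
  M <- q$m
  n <- nrow(lab)
  mm <- ncol(lab)
  K <- length(d_set)
  counts <- array(0, dim = c(M, M, K),
                  dimnames = list(NULL, NULL, paste0("k", d_set)))
  for (ki in seq_len(K)) {
    k <- d_set[ki]
    offs <- ring_offsets(k)
    acc <- numeric(M * M)
    for (o in seq_len(nrow(offs))) {
      di <- offs[o, 1]
      dj <- offs[o, 2]
      rs <- max(1, 1 - di):min(n, n - di)
      cs <- max(1, 1 - dj):min(mm, mm - dj)
      if (rs[1] > rs[length(rs)] || cs[1] > cs[length(cs)]) next
      la <- lab[rs, cs, drop = FALSE]
      lb <- lab[rs + di, cs + dj, drop = FALSE]
      acc <- acc + tabulate((la - 1L) * M + lb, nbins = M * M)
    }
    counts[, , ki] <- matrix(acc, M, M, byrow = TRUE)
  }
  denom <- apply(counts, c(1, 3), sum)  # pairs with p1 of color i, per k
  gam <- counts
  for (ki in seq_len(K)) {
    d <- denom[, ki]
    d[d == 0] <- 1
    gam[, , ki] <- counts[, , ki] / d
  }
  structure(list(gamma = gam, counts = counts, h = color_histogram(q),
                 d_set = as.integer(d_set), m = M),
            class = "correlogram_table")
}

#' Autocorrelogram: the correlogram's same-color diagonal
#'
#' `ac[i, k] = gamma[i, i, k]`, requiring only O(m d) storage.
#'
#' @param table a [color_correlogram()] result.
#' @return m x |d_set| matrix.
#' @export
autocorrelogram <- function(table) {
  stopifnot(inherits(table, "correlogram_table"))
  K <- length(table$d_set)
  ac <- sapply(seq_len(K), function(ki) diag(table$gamma[, , ki]))
  ac <- matrix(ac, table$m, K)
  dimnames(ac) <- list(NULL, paste0("k", table$d_set))
  ac
}
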