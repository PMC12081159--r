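# Nonlocal patch manifold: diffusion kernel, graph Laplacian, spectral basis,
# manifold-space contrast adjustment, and graph-frequency energies.

#' Extract all s x s patches of a scalar raster
#'
#' One patch per pixel, centered on it, with mirror (reflect) padding at the
#' borders and row-major unrolling of each patch. Patch rows are indexed by
#' center pixel in R's native column-major order.
#'
#' @param f numeric matrix.
#' @param s odd patch side, `s <= min(dim(f))`.
#' @return object of class `"patch_set"`: `patches` (N x s^2 matrix), `s`,
#'   `dim` of the source raster.
#' @export
extract_patches <- function(f, s = 5L) {
  s <- as.integer(s)
  if (s %% 2L == 0L) stop("patch side must be odd")
  n <- nrow(f)
  m <- ncol(f)
  if (s > min(n, m)) stop("patch larger than image")
  r <- (s - 1L) %/% 2L
  ridx <- c(if (r > 0) (r + 1L):2L, 1:n, if (r > 0) (n - 1L):(n - r))
  cidx <- c(if (r > 0) (r + 1L):2L, 1:m, if (r > 0) (m - 1L):(m - r))
  pad <- f[ridx, cidx, drop = FALSE]
  P <- matrix(0, n * m, s * s)
  for (pi in seq_len(s)) {
    for (pj in seq_len(s)) {
      P[, (pi - 1L) * s + pj] <- as.vector(pad[pi:(pi + n - 1L), pj:(pj + m - 1L)])
    }
  }
  structure(list(patches = P, s = s, dim = c(n, m)), class = "patch_set")
}

#' Nonlocal diffusion kernel between patches
#'
#' `W[i, j] = exp(-||R_i f - R_j f||^2 / (2 sigma^2))`, a symmetric kernel
#' with unit diagonal. When the patch count exceeds `sample_cap`, a seeded
#' uniform subsample of centers defines the graph. The default bandwidth is
#' the median pairwise patch distance over a seeded subsample of at most
#' 1000 pairs (floored at 1e-8 so constant images remain well defined).
#'
#' @param patches an [extract_patches()] result.
#' @param sigma kernel bandwidth > 0, or `NULL` for the median heuristic.
#' @param sample_cap maximum number of graph nodes (default 2048).
#' @param seed seed for subsampling.
#' @return object of class `"patch_graph"`: `W`, `sigma`, `centers` (linear
#'   indices of graph nodes in the source raster), `s`, `dim`.
#' @export
nonlocal_kernel <- function(patches, sigma = NULL, sample_cap = 2048L, seed = 1L) {
  stopifnot(inherits(patches, "patch_set"))
  P <- patches$patches
  N <- nrow(P)
  centers <- seq_len(N)
  if (N > sample_cap) {
    centers <- sort(with_seed(seed, sample.int(N, sample_cap)))
    P <- P[centers, , drop = FALSE]
  }
  dv <- stats::dist(P)
  if (is.null(sigma)) {
    v <- as.vector(dv)
    if (length(v) > 1000L) v <- with_seed(seed + 1L, sample(v, 1000L))
    sigma <- max(stats::median(v), 1e-8)
  }
  if (sigma <= 0) stop("sigma must be > 0")
  W <- exp(-as.matrix(dv)^2 / (2 * sigma^2))
  diag(W) <- 1
  dimnames(W) <- NULL
  structure(list(W = W, sigma = sigma, centers = centers,
                 s = patches$s, dim = patches$dim),
            class = "patch_graph")
}

#' Graph Laplacian of the nonlocal kernel
#'
#' `L = D - W` with `D[i, i] = sum_j W[i, j]`; rows sum to zero and the
#' constant vector lies in the kernel.
#'
#' @param graph a [nonlocal_kernel()] result.
#' @return the graph with elements `degree` and `L` added.
#' @export
build_laplacian <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  graph$degree <- rowSums(graph$W)
  graph$L <- diag(graph$degree) - graph$W
  graph
}

#' Orthogonal spectral basis of the Laplacian
#'
#' Full symmetric eigendecomposition `L = U diag(eta) U^T` with eigenvalues
#' ascending, so small eta are low graph frequencies and `U[, 1]` is the
#' constant eigenvector (eta_1 = 0). Sign convention: the first entry of
#' each eigenvector with magnitude above 1e-12 is made positive.
#'
#' @param graph a [build_laplacian()] result.
#' @return the graph with `U` (orthonormal columns) and `eta` added.
#' @export
spectral_basis <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"), !is.null(graph$L))
  L <- graph$L
  if (max(abs(L - t(L))) > 1e-8) stop("Laplacian must be symmetric")
  e <- eigen(L, symmetric = TRUE)
  ord <- order(e$values)
  U <- e$vectors[, ord, drop = FALSE]
  eta <- e$values[ord]
  for (k in seq_len(ncol(U))) {
    i0 <- which(abs(U[, k]) > 1e-12)[1]
    if (!is.na(i0) && U[i0, k] < 0) U[, k] <- -U[, k]
  }
  graph$U <- U
  graph$eta <- eta
  graph
}

#' Contrast adjustment in the manifold spectral basis
#'
#' Projects the per-center intensity signal onto the first `k_bands`
#' eigenvectors, multiplies each coefficient by its gain, reconstructs, and
#' adds back the unprojected residual. Gains of 1 return the input; gains
#' above 1 on low-frequency bands boost large-scale contrast.
#'
#' @param f scalar raster the graph was built from.
#' @param graph a [spectral_basis()] result.
#' @param gains numeric vector of per-band multipliers, length `k_bands`.
#' @param k_bands number of bands, `<= ncol(U)`.
#' @return adjusted raster (pixels off the subsampled graph are unchanged).
#' @export
spectral_filter <- function(f, graph, gains, k_bands = length(gains)) {
  stopifnot(inherits(graph, "patch_graph"), !is.null(graph$U))
  if (length(gains) != k_bands) stop("gains length must equal k_bands")
  if (k_bands > ncol(graph$U)) stop("k_bands exceeds basis size")
  sig <- f[graph$centers]
  Uk <- graph$U[, seq_len(k_bands), drop = FALSE]
  coef <- drop(crossprod(Uk, sig))
  resid <- sig - drop(Uk %*% coef)
  out <- f
  out[graph$centers] <- resid + drop(Uk %*% (gains * coef))
  out
}

#' Graph-frequency energy spectrum of a raster
#'
#' Squared projection coefficients of the per-center signal onto the first
#' `k_bands` eigenvectors, normalized to sum to 1. A constant signal puts
#' all its energy in band 1 (the zero-frequency band).
#'
#' @param f scalar raster.
#' @param graph a [spectral_basis()] result.
#' @param k_bands number of bands.
#' @return numeric vector of length `k_bands` summing to 1.
#' @export
graph_frequency_energy <- function(f, graph, k_bands = 16L) {
  stopifnot(inherits(graph, "patch_graph"), !is.null(graph$U))
  if (k_bands > ncol(graph$U)) stop("k_bands exceeds basis size")
  sig <- f[graph$centers]
  Uk <- graph$U[, seq_len(k_bands), drop = FALSE]
  en <- drop(crossprod(Uk, sig))^2
  tot <- sum(en)
  if (tot <= 0) return(c(1, numeric(k_bands - 1L)))  # zero signal: pure DC
  en / tot
}
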