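test_that("patch extraction covers every pixel with reflect padding", {
  f <- rand_gray(4)
  ps <- extract_patches(f, 3L)
  expect_equal(dim(ps$patches), c(16L, 9L))

  flat <- matrix(0.2, 5, 5)
  pf <- extract_patches(flat, 3L)
  expect_true(all(pf$patches == 0.2))

  g <- matrix(1:9 / 10, 3, 3)
  pg <- extract_patches(g, 3L)
  center <- 5L                       # column-major center of a 3x3 raster
  expect_equal(pg$patches[center, ], as.vector(t(g)))  # row-major unrolling

  expect_error(extract_patches(f, 2L), "odd")
  expect_error(extract_patches(f, 5L), "larger")
})

test_that("the nonlocal kernel is a symmetric unit-diagonal similarity", {
  flat <- matrix(0.7, 4, 4)
  g <- nonlocal_kernel(extract_patches(flat, 3L), sigma = 1)
  expect_true(all(g$W == 1))          # identical patches

  # two distinct pixel values, s = 1: ||diff||^2 = 2 sigma^2 -> exp(-1)
  two <- matrix(c(0, 0.4, 0, 0.4), 2, 2)
  gk <- nonlocal_kernel(extract_patches(two, 1L), sigma = 0.4 / sqrt(2))
  expect_equal(gk$W[1, 2], exp(-1), tolerance = 1e-12)

  set.seed(19)
  gr <- nonlocal_kernel(extract_patches(rand_gray(6), 3L))
  expect_equal(gr$W, t(gr$W))
  expect_true(all(gr$W > 0 & gr$W <= 1))
  expect_error(nonlocal_kernel(extract_patches(two, 1L), sigma = -1), "sigma")
})

test_that("subsampled graphs are deterministic under a fixed seed", {
  set.seed(23)
  f <- rand_gray(10)
  ps <- extract_patches(f, 3L)
  g1 <- nonlocal_kernel(ps, sample_cap = 40L, seed = 9L)
  g2 <- nonlocal_kernel(ps, sample_cap = 40L, seed = 9L)
  expect_identical(g1$centers, g2$centers)
  expect_identical(g1$W, g2$W)
  expect_length(g1$centers, 40L)
})

test_that("the Laplacian has zero row sums and the 2-node closed form", {
  # two patches at similarity 0.5: L = [[.5,-.5],[-.5,.5]], eigenvalues {0, 1}
  two <- matrix(c(0, 0.4), 1, 2)
  sig <- sqrt(0.4^2 / (2 * log(2)))   # makes exp(-d^2/(2 sig^2)) = 0.5
  g <- build_laplacian(nonlocal_kernel(extract_patches(two, 1L), sigma = sig))
  expect_equal(g$L, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2), tolerance = 1e-12)
  g <- spectral_basis(g)
  expect_equal(g$eta, c(0, 1), tolerance = 1e-12)

  set.seed(37)
  gr <- spectral_basis(build_laplacian(nonlocal_kernel(
    extract_patches(rand_gray(6), 3L))))
  expect_lt(max(abs(rowSums(gr$L))), 1e-10)
  expect_lt(max(abs(gr$L %*% rep(1, nrow(gr$L)))), 1e-10)
})

test_that("the spectral basis is orthonormal, PSD-consistent and reconstructs L", {
  set.seed(43)
  g <- spectral_basis(build_laplacian(nonlocal_kernel(
    extract_patches(rand_gray(7), 3L))))
  expect_lt(max(abs(crossprod(g$U) - diag(ncol(g$U)))), 1e-8)
  expect_gt(min(g$eta), -1e-8)
  expect_lt(abs(g$eta[1]), 1e-8)
  expect_true(all(diff(g$eta) >= -1e-12))
  expect_lt(max(abs(g$L - g$U %*% diag(g$eta) %*% t(g$U))), 1e-6)
  for (k in seq_along(g$eta)) {
    expect_lt(max(abs(g$L %*% g$U[, k] - g$eta[k] * g$U[, k])), 1e-6)
  }
  bad <- g
  bad$L[1, 2] <- bad$L[1, 2] + 1
  expect_error(spectral_basis(bad), "symmetric")
})

test_that("spectral filtering is the identity at unit gains, zero at zero gains", {
  set.seed(53)
  f <- rand_gray(6)
  g <- spectral_basis(build_laplacian(nonlocal_kernel(extract_patches(f, 3L))))
  expect_equal(spectral_filter(f, g, gains = rep(1, 10)), f, tolerance = 1e-8)
  allz <- spectral_filter(f, g, gains = rep(0, ncol(g$U)))
  expect_lt(max(abs(allz)), 1e-8)     # full basis, zero gains: nothing left
  expect_error(spectral_filter(f, g, gains = rep(1, 3), k_bands = 5), "gains")
})

test_that("boosting low frequencies raises between-region contrast", {
  set.seed(61)
  f <- cbind(matrix(0.3, 8, 4), matrix(0.7, 8, 4)) + matrix(rnorm(64, 0, 0.05), 8)
  g <- spectral_basis(build_laplacian(nonlocal_kernel(extract_patches(f, 3L))))
  out <- spectral_filter(f, g, gains = rep(2, 4))
  contrast <- function(x) abs(mean(x[, 5:8]) - mean(x[, 1:4]))
  expect_gt(contrast(out), contrast(f))
})

test_that("graph-frequency energies are a normalized spectrum", {
  flat <- matrix(0.4, 5, 5)
  g <- spectral_basis(build_laplacian(nonlocal_kernel(extract_patches(flat, 3L),
                                                      sigma = 1)))
  en <- graph_frequency_energy(flat, g, 6L)
  expect_equal(en, c(1, rep(0, 5)), tolerance = 1e-12)

  set.seed(67)
  f <- rand_gray(6)
  gf <- spectral_basis(build_laplacian(nonlocal_kernel(extract_patches(f, 3L))))
  e1 <- graph_frequency_energy(f, gf, 8L)
  expect_equal(sum(e1), 1, tolerance = 1e-12)
  # adding a constant only moves DC energy: non-DC ratios are invariant
  e2 <- graph_frequency_energy(f + 0.2, gf, 8L)
  expect_equal(e1[-1] / sum(e1[-1]), e2[-1] / sum(e2[-1]), tolerance = 1e-8)
  # Parseval over the full basis
  coef <- drop(crossprod(gf$U, f[gf$centers]))
  expect_equal(sum(coef^2), sum(f[gf$centers]^2), tolerance = 1e-6)
})
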