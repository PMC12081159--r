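test_that("L-infinity distance is the max coordinate difference", {
  expect_equal(linf_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(linf_distance(c(1, 1), c(2, 3)), 2)
  expect_equal(linf_distance(c(5, 2), c(2, 2)), 3)
})

test_that("color quantization partitions colors deterministically", {
  two <- matrix(c(0.1, 0.9), 4, 4)
  q <- quantize_colors(two, 2L)
  expect_equal(sort(unique(as.vector(q$labels))), c(1L, 2L))
  expect_true(all((two < 0.5) == (q$labels == 1L)))

  flat <- matrix(0.5, 4, 4)
  expect_length(unique(as.vector(quantize_colors(flat, 4L)$labels)), 1L)

  img <- rand_rgb(8)
  expect_identical(quantize_colors(img, 5L, seed = 3L)$labels,
                   quantize_colors(img, 5L, seed = 3L)$labels)
  expect_error(quantize_colors(img, 1L), "m must be")
})

test_that("color histogram counts pixels and conserves mass", {
  mono <- matrix(0.1, 8, 8)
  q <- quantize_colors(mono, 4L)
  h <- color_histogram(q)
  expect_equal(sum(h), 64L)
  expect_equal(max(h), 64L)

  cb <- matrix(c(0.1, 0.9), 4, 4)          # alternating rows = checkerboard cols
  cb <- matrix(rep(c(0.1, 0.9, 0.9, 0.1), 4), 4, 4)
  hcb <- color_histogram(quantize_colors(cb, 2L))
  expect_equal(sort(hcb), c(8L, 8L))

  set.seed(13)
  q3 <- quantize_colors(rand_gray(9, 7), 5L)
  expect_equal(sum(color_histogram(q3)), 63L)
})

test_that("correlogram matches hand-enumerated and brute-force results", {
  mono <- matrix(0.1, 6, 6)
  qm <- quantize_colors(mono, 3L)
  gm <- color_correlogram(qm, c(1L, 2L))
  lab <- qm$labels[1, 1]
  expect_equal(unname(gm$gamma[lab, lab, 1]), 1)
  expect_equal(unname(gm$gamma[lab, lab, 2]), 1)

  cb2 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2)  # 2x2 checkerboard
  qc <- quantize_colors(cb2, 2L)
  gc <- color_correlogram(qc, 1L)
  expect_equal(unname(gc$gamma[1, 1, 1]), 1 / 3)
  expect_equal(unname(gc$gamma[1, 2, 1]), 2 / 3)

  for (rep in 1:3) {
    set.seed(500 + rep)
    q <- quantize_colors(rand_gray(8), 4L)
    got <- color_correlogram(q, c(1L, 2L))
    want <- oracle_correlogram(q$labels, 4L, c(1L, 2L))
    expect_equal(got$counts, want$counts, ignore_attr = TRUE)
    expect_equal(got$gamma, want$gamma, ignore_attr = TRUE)
  }
})

test_that("correlogram rows normalize and pair counts are symmetric", {
  set.seed(29)
  q <- quantize_colors(rand_gray(10), 4L)
  tab <- color_correlogram(q, c(1L, 3L))
  h <- color_histogram(q)
  for (ki in 1:2) {
    cnt <- tab$counts[, , ki]
    expect_equal(cnt, t(cnt))                     # count(i,j,k) = count(j,i,k)
    rows <- rowSums(tab$gamma[, , ki])
    present <- h > 0 & rowSums(cnt) > 0
    expect_equal(rows[present], rep(1, sum(present)), ignore_attr = TRUE)
  }
  # distance beyond the image extent yields all-zero counts
  far <- color_correlogram(q, 50L)
  expect_true(all(far$counts == 0))
})

test_that("autocorrelogram is the correlogram diagonal", {
  mono <- matrix(0.9, 5, 5)
  qm <- quantize_colors(mono, 2L)
  tm <- color_correlogram(qm, c(1L, 2L))
  am <- autocorrelogram(tm)
  expect_equal(am[qm$labels[1, 1], ], c(k1 = 1, k2 = 1))

  cb2 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2)
  ac <- autocorrelogram(color_correlogram(quantize_colors(cb2, 2L), 1L))
  expect_equal(unname(ac[, 1]), c(1 / 3, 1 / 3))

  set.seed(77)
  q <- quantize_colors(rand_gray(8), 4L)
  tab <- color_correlogram(q, c(1L, 2L))
  ac2 <- autocorrelogram(tab)
  for (ki in 1:2) expect_equal(ac2[, ki], diag(tab$gamma[, , ki]),
                               ignore_attr = TRUE)
})
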