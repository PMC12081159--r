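test_that("order field equals the chessboard distance transform", {
  all_rel <- matrix(TRUE, 4, 4)
  expect_true(all(compute_order_field(all_rel)$T == 0L))

  one <- matrix(TRUE, 3, 3)
  one[2, 2] <- FALSE
  expect_equal(compute_order_field(one)$T[2, 2], 1L)

  row7 <- matrix(c(TRUE, rep(FALSE, 5), TRUE), 1, 7)
  expect_equal(as.vector(compute_order_field(row7)$T), c(0, 1, 2, 3, 2, 1, 0))

  for (rep in 1:5) {
    set.seed(300 + rep)
    mk <- rand_mask(12)
    expect_equal(compute_order_field(mk)$T, oracle_chessboard(mk),
                 ignore_attr = TRUE)
  }
  expect_error(compute_order_field(matrix(FALSE, 3, 3)), "reliable")
})

test_that("pair weights match their closed forms and reduction cases", {
  expect_equal(pair_weight_b(c(1, 0, 0), c(1, 0, 0), 0.5, 0.5), 1)
  expect_equal(pair_weight_b(c(0.3, 0.1, 0.9), c(0.8, 0.2, 0.1), 0.11, 0.77,
                             gamma_i = 0, gamma_d = 0), 1)
  # ||I_x - I_y||^2 = 0.01, gamma_i = 100, equal D -> exp(-1)
  expect_equal(pair_weight_b(0.1, 0.2, 0.5, 0.5, gamma_i = 100, gamma_d = 1e4),
               exp(-1), tolerance = 1e-12)
  expect_error(pair_weight_b(0, 0, 0, 0, gamma_i = -1), "gamma")

  expect_equal(pair_weight_g(c(1, 0), c(2, 0), delta = 0), 1)
  expect_equal(pair_weight_g(c(1, 0), c(0, 1), delta = 0), 0)   # orthogonal
  expect_equal(pair_weight_g(c(1, 0), c(-1, 0), delta = 0), 0)  # opposite, floored
  expect_equal(pair_weight_g(c(1, 0), c(-3, 2), delta = 1), 1)  # reduction case
  expect_error(pair_weight_g(c(0, 0), c(1, 0)), "nonzero")
})

test_that("confidence propagation honors the [1,0] anchors and decay", {
  one <- matrix(TRUE, 3, 3)
  one[2, 2] <- FALSE
  ord <- compute_order_field(one)
  D <- matrix(0.5, 3, 3)
  cf <- propagate_confidence(ord, D, D, a = 0.8, gamma_i = 0, gamma_d = 0,
                             delta = 1)
  expect_equal(cf$c_plus[one], rep(1, 8))   # reliable pixels untouched
  expect_equal(cf$c_minus[one], rep(0, 8))
  expect_equal(cf$c_plus[2, 2], 0.8)        # K_C cancels, single step decay

  cf0 <- propagate_confidence(ord, D, D, a = 0)
  expect_equal(cf0$c_plus[2, 2], 0)
})

test_that("propagated confidences are normalized into [0, 1]", {
  for (rep in 1:5) {
    set.seed(400 + rep)
    D <- rand_gray(12)
    mk <- rand_mask(12)
    ord <- compute_order_field(mk)
    cf <- propagate_confidence(ord, D, D)
    expect_true(all(cf$c_plus >= 0 & cf$c_plus <= 1))
    expect_true(all(cf$c_minus >= 0 & cf$c_minus <= 1))
  }
})

test_that("under the reduction, confidence equals a^T", {
  set.seed(17)
  D <- rand_gray(16)
  mk <- rand_mask(16)
  ord <- compute_order_field(mk)
  cf <- propagate_confidence(ord, D, D, a = 0.8, gamma_i = 0, gamma_d = 0,
                             delta = 1)
  expect_equal(cf$c_plus, 0.8^ord$T, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ordered filtering preserves reliable pixels and constants", {
  set.seed(31)
  D <- matrix(0.6, 8, 8)
  mk <- rand_mask(8)
  ord <- compute_order_field(mk)
  cf <- propagate_confidence(ord, D, D)
  expect_equal(ordered_filter(ord, cf, D, D), D)  # constant stays constant

  all_rel <- matrix(TRUE, 8, 8)
  Dr <- rand_gray(8)
  ord2 <- compute_order_field(all_rel)
  cf2 <- propagate_confidence(ord2, Dr, Dr)
  expect_identical(ordered_filter(ord2, cf2, Dr, Dr), Dr)

  # 1x3 row [4, ?, 8] with unit weights -> unweighted mean 6
  row3 <- matrix(c(4, 0, 8) / 10, 1, 3)
  mk3 <- matrix(c(TRUE, FALSE, TRUE), 1, 3)
  ord3 <- compute_order_field(mk3)
  cf3 <- propagate_confidence(ord3, row3, row3, a = 0.999999999,
                              gamma_i = 0, gamma_d = 0, delta = 1)
  out <- ordered_filter(ord3, cf3, row3, row3, gamma_i = 0, gamma_d = 0,
                        delta = 1)
  expect_equal(out[1, 2], 0.6, tolerance = 1e-8)
})

test_that("restoration keeps reliable pixels bit-identical and in range", {
  img <- generate_tissue_image(tissue_spec(seed = 6L))
  low <- degrade_image(img, 2L, noise_sd = 4, seed = 6L)
  r <- restore_image(as_unit(low), 2L)
  up <- init_upsample(as_unit(low), 2L, "bilinear")
  D0 <- luminance(up)
  expect_identical(r$d[r$mask$mask], D0[r$mask$mask])
  expect_true(all(is.finite(r$image)))
  expect_true(all(r$image >= 0 - 1e-9 & r$image <= 1 + 1e-9))
})
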