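test_that("similarity threshold is the mean pairwise affinity", {
  expect_equal(similarity_threshold(matrix(c(0, 0.5), 2, 1)), 0.5)
  # scalar features 0, 0.2, 0.6 -> pair affinities 0.2, 0.6, 0.4 -> mean 0.4
  expect_equal(similarity_threshold(matrix(c(0, 0.2, 0.6), 3, 1)), 0.4)
  expect_equal(similarity_threshold(matrix(1, 4, 3)), 0)
  expect_error(similarity_threshold(matrix(1, 1, 3)), "at least two")
})

test_that("memory-cell training follows the placement and growth rules", {
  # one point per class: the cells are exactly the two (normalized) points
  x <- rbind(c(0, 0), c(1, 2))
  m1 <- memcell(x, c("benign", "malignant"), seed = 1L)
  expect_equal(nrow(m1$cells), 2L)
  expect_setequal(m1$cell_labels, c("benign", "malignant"))

  # duplicate presentations collapse into one cell with summed stimulation
  x2 <- rbind(matrix(c(0, 0), 5, 2, byrow = TRUE), c(1, 1))
  y2 <- c(rep("benign", 5), "malignant")
  m2 <- memcell(x2, y2, seed = 3L)
  expect_equal(sum(m2$cell_labels == "benign"), 1L)
  expect_equal(m2$stimulation[m2$cell_labels == "benign"], 5L)
  expect_equal(m2$stimulation[m2$cell_labels == "malignant"], 1L)

  # two well-separated clusters per class each earn at least one cell
  set.seed(42)
  mk <- function(cx, cy, n = 15) cbind(rnorm(n, cx, 0.02), rnorm(n, cy, 0.02))
  x3 <- rbind(mk(0, 0), mk(1, 1), mk(0, 1), mk(1, 0))
  y3 <- rep(c("benign", "benign", "malignant", "malignant"), each = 15)
  m3 <- memcell(x3, y3, seed = 42L)
  cluster_of <- function(cell) which.min(rowSums((rbind(c(0, 0), c(1, 1),
                                                        c(0, 1), c(1, 0)) -
                                                  matrix(cell, 4, 2,
                                                         byrow = TRUE))^2))
  covered <- vapply(seq_len(nrow(m3$cells)),
                    function(i) cluster_of(m3$cells[i, ]), numeric(1))
  expect_true(all(1:4 %in% covered))

  expect_error(memcell(x, c("a", "a")), "two classes")
})

test_that("capacity eviction drops the least-stimulated cell", {
  set.seed(11)
  x <- matrix(runif(40), 20, 2)
  y <- rep(c("benign", "malignant"), 10)
  m <- memcell(x, y, capacity = 4L, seed = 5L)
  expect_lte(nrow(m$cells), 4L)
  expect_true(all(c("benign", "malignant") %in% m$cell_labels))
})

test_that("prediction is nearest-cell with a two-class distance-ratio score", {
  x <- rbind(c(0, 0), c(1, 1))
  m <- memcell(x, c("benign", "malignant"), seed = 1L)
  pr <- predict(m, x, type = "both")
  expect_equal(pr$class, c("benign", "malignant"))
  expect_equal(pr$score, c(0, 1))               # queries on the cells: extreme

  mid <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(predict(m, mid, type = "score"), 0.5)

  # moving toward the malignant cell never decreases the malignant score
  lam <- seq(0, 1, by = 0.05)
  line <- cbind(lam, lam)
  sc <- predict(m, line, type = "score")
  expect_true(all(diff(sc) >= -1e-12))
  expect_error(predict(m, matrix(0, 1, 5)), "dimension")
})

test_that("print and summary report the model structure", {
  set.seed(2)
  m <- memcell(matrix(runif(40), 20, 2), rep(c("benign", "malignant"), 10))
  expect_output(print(m), "Memory-cell classifier")
  expect_output(summary(m), "cells per class")
})

test_that("models round-trip through plain-text serialization", {
  set.seed(9)
  m <- memcell(matrix(runif(60), 30, 2), rep(c("benign", "malignant"), 15),
               seed = 7L)
  dir <- withr::local_tempdir()
  write_memcell(m, dir)
  m2 <- read_memcell(dir)
  q <- matrix(runif(10), 5, 2)
  expect_equal(predict(m2, q, type = "both"), predict(m, q, type = "both"))
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$cells, m$cells)
})
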