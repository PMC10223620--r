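test_that("grayscale conversion: identity, channel symmetry, weighted-sum oracle", {
  m <- rand_img(5)
  expect_identical(to_grayscale(m), m)

  v <- rand_img(4)
  arr <- array(rep(v, 3), dim = c(4, 4, 3))
  expect_equal(to_grayscale(arr), v)

  set.seed(11)
  rgb <- array(stats::runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_equal(to_grayscale(rgb), oracle_grayscale(rgb), tolerance = 1e-12)

  expect_error(to_grayscale(array(0.5, dim = c(4, 4, 2))), "channel")
})

test_that("mean threshold: tie rule, strict inequality, brute-force oracle", {
  expect_identical(mean_threshold(matrix(c(0, 1, 0, 1), 2)),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2))
  # constant image: no pixel strictly exceeds the mean
  expect_false(any(mean_threshold(matrix(0.4, 6, 6))))

  set.seed(21)
  m <- rand_img(8)
  expect_identical(mean_threshold(m), oracle_mean_threshold(m))
})

test_that("mean threshold mask is invariant under a constant intensity shift", {
  set.seed(22)
  m <- rand_img(10) * 0.5
  expect_identical(mean_threshold(m + 0.3), mean_threshold(m))
})

test_that("Sobel magnitude: zero on constants, step response, convolution oracle", {
  expect_lt(max(sobel_edges(matrix(0.7, 5, 5))), 1e-12)

  step <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  e <- sobel_edges(step)
  expect_equal(unname(e[3, 3]), 4)  # column adjacent to the step
  expect_equal(unname(e[3, 4]), 4)
  expect_true(all(e[, c(1, 6)] == 0))  # far from the edge

  set.seed(31)
  m <- rand_img(5)
  expect_equal(unclass(sobel_edges(m)), oracle_sobel(m),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(sobel_edges(matrix(0.1, 2, 5)), "smaller")
})

test_that("Roberts magnitude: zero on constants, 2x2 definition, oracle", {
  expect_true(all(roberts_edges(matrix(0.3, 4, 4)) == 0))

  m <- matrix(c(0.9, 0.1, 0.4, 0.2), 2, 2, byrow = TRUE)  # a b / c d
  expect_equal(unname(roberts_edges(m)[1, 1]),
               sqrt((0.9 - 0.2)^2 + (0.1 - 0.4)^2))

  set.seed(41)
  r <- rand_img(6)
  expect_equal(unclass(roberts_edges(r)), oracle_roberts(r),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(roberts_edges(matrix(0.5, 1, 5)), "smaller")
})

test_that("sliding window: trivial cases and exhaustive-position oracle", {
  z <- matrix(0, 12, 12)
  expect_false(any(sliding_window_classify(z, window = 4, stride = 4,
                                           edge_threshold = 0.1,
                                           min_edge_count = 1)))

  # one fully-hot window, stride = window: exactly that window foreground
  e <- matrix(0, 12, 12)
  e[5:8, 9:12] <- 1
  got <- sliding_window_classify(e, window = 4, stride = 4,
                                 edge_threshold = 0.5, min_edge_count = 16)
  want <- matrix(FALSE, 12, 12); want[5:8, 9:12] <- TRUE
  expect_identical(got, want)

  set.seed(51)
  for (k in 1:10) {
    sp <- matrix(stats::rbinom(15 * 15, 1, 0.08), 15, 15)
    expect_identical(
      sliding_window_classify(sp, window = 5, stride = 3,
                              edge_threshold = 0.5, min_edge_count = 2),
      oracle_window(sp, 5L, 3L, 0.5, 2)
    )
  }

  expect_error(sliding_window_classify(z, window = 20), "larger")
})

test_that("sliding window output is monotone in the edge threshold", {
  set.seed(52)
  e <- matrix(stats::runif(20 * 20), 20, 20)
  prev <- NULL
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cur <- sliding_window_classify(e, window = 6, stride = 3,
                                   edge_threshold = thr, min_edge_count = 3)
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("morphological closing: trivial cases, gap filling, set-arithmetic oracle", {
  z <- matrix(FALSE, 8, 8)
  expect_identical(morphological_close(z, 3), z)

  # solid square with a 1-pixel interior gap: closing fills it
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE; sq[5, 5] <- FALSE
  expect_true(morphological_close(sq, 1)[5, 5])
  expect_true(all(morphological_close(sq, 1)[sq]))  # extensive

  set.seed(61)
  for (shape in c("disc", "square")) {
    for (k in 1:5) {
      m <- matrix(stats::runif(12 * 12) < 0.35, 12, 12)
      expect_identical(morphological_close(m, 2, shape),
                       oracle_close(m, 2L, shape))
    }
  }
})

test_that("closing is idempotent and extensive on random blob masks", {
  set.seed(62)
  for (k in 1:8) {
    m <- matrix(stats::runif(20 * 20) < 0.3, 20, 20)
    c1 <- morphological_close(m, 3)
    expect_true(all(c1[m]))                       # output contains input
    expect_identical(morphological_close(c1, 3), c1)
  }
})

test_that("dilate/erode match their plane-semantics oracles", {
  set.seed(63)
  for (shape in c("disc", "square")) {
    m <- matrix(stats::runif(14 * 14) < 0.4, 14, 14)
    expect_identical(binary_dilate(m, 2, shape), oracle_dilate(m, 2L, shape))
    expect_identical(binary_erode(m, 2, shape), oracle_erode(m, 2L, shape))
  }
})

test_that("edge maps are zero everywhere iff the input is constant", {
  set.seed(64)
  for (k in 1:5) {
    m <- rand_img(7)
    expect_gt(max(sobel_edges(m)), 0)
    expect_gt(max(roberts_edges(m)), 0)
  }
  expect_lt(max(sobel_edges(matrix(0.2, 7, 7))), 1e-12)
  expect_equal(max(roberts_edges(matrix(0.2, 7, 7))), 0)
})

test_that("intensity normalization handles 8- and 16-bit ranges", {
  m8 <- matrix(c(0L, 128L, 255L), 1, 3)
  expect_equal(normalize_intensity(m8), m8 / 255)
  m16 <- matrix(c(0L, 65535L), 1, 2)
  expect_equal(normalize_intensity(m16), m16 / 65535)
  m <- matrix(c(0, 0.5, 1), 1, 3)
  expect_equal(normalize_intensity(m), m)
})
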