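make_seg <- function(metal, bone, holes) {
  structure(list(implant_metal = metal, bone = bone, holes = holes,
                 params = list()), class = "segmentation_result")
}

mask_of <- function(n, idx) { m <- matrix(FALSE, n, n); m[idx] <- TRUE; m }

test_that("BI formula: boundary cases, arithmetic, undefined state", {
  z <- matrix(FALSE, 10, 10)
  b <- mask_of(10, 1:30)
  h <- mask_of(10, 31:40)

  expect_equal(compute_bi(make_seg(z, z, h))$bi, 0)         # A_Oss = 0
  expect_equal(compute_bi(make_seg(z, b, z))$bi, 1)         # A_Hole = 0
  r <- compute_bi(make_seg(z, b, h))
  expect_equal(r$bi, 30 / 40)
  expect_true(r$defined)

  u <- compute_bi(make_seg(mask_of(10, 1:50), z, z))        # solid implant
  expect_false(u$defined)
  expect_true(is.na(u$bi))
})

test_that("manual and algorithmic BI share one formula", {
  b <- mask_of(12, 5:40); h <- mask_of(12, 60:99)
  alg <- compute_bi(make_seg(matrix(FALSE, 12, 12), b, h))
  man <- bi_from_manual_mask(b, h)
  expect_equal(man$bi, alg$bi)
  expect_identical(man$method, "manual")

  expect_error(bi_from_manual_mask(b, b), "overlap")
  expect_equal(bi_from_manual_mask(matrix(FALSE, 12, 12), h)$bi, 0)
})

test_that("ground-truth masks of a phantom reproduce the designed fraction", {
  ph <- small_phantom("cube", designed_bi = 0.7, seed = 11)
  r <- bi_from_manual_mask(ph$bone, ph$hole)
  expect_equal(r$bi, phantom_bi(ph))
  expect_lte(abs(r$bi - 0.7), 1 / (r$a_oss + r$a_hole) + 1e-12)
})

test_that("agreement: exact identity, constant manual, closed-form OLS oracle", {
  mk <- function(bi_vals, method = "algorithm") {
    lapply(seq_along(bi_vals), function(i) {
      a <- round(bi_vals[i] * 1000)
      osseoquant:::new_bi_result(a, 1000 - a, method, paste0("img", i),
                                 "cube", "week12")
    })
  }
  x <- c(0.12, 0.35, 0.52, 0.71, 0.94)

  same <- agreement(mk(x), mk(x, "manual"))
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(same$r_squared, 1)

  const <- agreement(mk(x), mk(rep(0.5, 5), "manual"))
  expect_equal(const$r_squared, 0)

  y <- c(0.18, 0.30, 0.59, 0.67, 0.99)
  got <- agreement(mk(x), mk(y, "manual"))
  want <- oracle_ols(round(x * 1000) / 1000, round(y * 1000) / 1000)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-12)

  bad <- mk(x); bad[[1]]$image_id <- "other"
  expect_error(agreement(bad, mk(x, "manual")), "unpaired")
  expect_error(agreement(mk(x[1]), mk(x[1], "manual")), "at least 2")
})

test_that("R-squared is ~1 on identical data and low on shuffled data", {
  set.seed(91)
  x <- stats::runif(40, 0.05, 0.95)
  mk <- function(v, m) lapply(seq_along(v), function(i) {
    a <- round(v[i] * 10000)
    osseoquant:::new_bi_result(a, 10000 - a, m, paste0("i", i), "cube", "w12")
  })
  expect_equal(agreement(mk(x, "algorithm"), mk(x, "manual"))$r_squared, 1)
  sh <- sample(x)
  expect_lt(agreement(mk(x, "algorithm"), mk(sh, "manual"))$r_squared, 0.2)
})

test_that("batch report: single result, zero-variance CI, hand-computed t-interval", {
  mk <- function(bi, lt = "cube", tp = "week12") {
    a <- round(bi * 1000)
    osseoquant:::new_bi_result(a, 1000 - a, "algorithm",
                               paste0(lt, tp, bi, stats::runif(1)), lt, tp)
  }
  one <- batch_report(list(mk(0.42)))
  expect_equal(one$n, 1L)
  expect_equal(one$mean_BI_percent, 42)
  expect_true(is.na(one$ci95_half_percent))

  same <- batch_report(lapply(rep(0.3, 5), mk))
  expect_equal(same$ci95_half_percent, 0)

  vals <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.35, 0.45, 0.55, 0.25, 0.65)
  rep10 <- batch_report(lapply(vals, mk))
  pv <- vals * 100
  expect_equal(rep10$mean_BI_percent, mean(pv))
  expect_equal(rep10$ci95_half_percent,
               stats::qt(0.975, 9) * stats::sd(pv) / sqrt(10))

  # undefined BI excluded from group statistics
  solid <- osseoquant:::new_bi_result(0, 0, "algorithm", "s1", "solid", "w12")
  mix <- batch_report(c(lapply(vals, mk), list(solid)))
  expect_false("solid" %in% mix$lattice_type)
})

test_that("BI is invariant to uniform spatial rescaling (areas are mask ratios)", {
  ph <- small_phantom("cube", designed_bi = 0.5, seed = 12)
  up <- function(m) kronecker(m, matrix(TRUE, 2, 2)) > 0  # 2x upsample
  a <- bi_from_manual_mask(ph$bone, ph$hole)
  b <- bi_from_manual_mask(up(ph$bone), up(ph$hole))
  expect_equal(b$bi, a$bi)
})
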