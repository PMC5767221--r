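# thresholding: five masking methods and their contracts

test_that("constant threshold keeps strictly greater pixels on every frame", {
  st <- image_stack(matrix(c(1, 5, 10, 20), 2, 2, byrow = TRUE))
  m <- threshold_constant(st, 5)
  expect_equal(m$frames[, , 1], matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_true(all(threshold_constant(st, 100)$frames == 0))
  # value 0 keeps exactly the positive pixels
  m0 <- threshold_constant(image_stack(matrix(c(0, 2), 1, 2)), 0)
  expect_equal(m0$frames[1, , 1], c(0, 1))
})

test_that("median-ROI threshold tracks each frame independently", {
  # reference pixels 1..9: median 5, strict > keeps 6..9
  m <- matrix(0, 3, 5)
  m[, 1:3] <- 1:9
  m[, 4:5] <- 100
  ref <- region("ref", "rectangle", rbind(c(0, 0), c(3, 3)),
                role = "threshold-reference")
  st <- image_stack(array(c(m, 2 * m), dim = c(3, 5, 2)))
  out <- threshold_median_roi(st, ref)
  expect_identical(out$thresholds, c(5, 10))
  idx <- bretr:::region_index(ref, c(3, 5))
  expect_identical(sum(out$frames[, , 1][idx]), 4)
  # proportional frames give identical masks
  expect_identical(out$frames[, , 1], out$frames[, , 2])
  # all-equal reference region masks itself out (strict >)
  flat <- image_stack(matrix(7, 3, 5))
  mf <- threshold_median_roi(flat, ref)
  expect_true(all(mf$frames[, , 1][idx] == 0))
})

test_that("Otsu matches the exhaustive within-class-variance oracle", {
  # perfectly bimodal two-valued frame
  tv <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  r <- threshold_otsu(tv)
  expect_gt(r$threshold, 10); expect_lt(r$threshold, 200)
  expect_identical(r$mask, (tv == 200) * 1)
  set.seed(51)
  for (i in 1:5) {
    f <- matrix(runif(32 * 32, 0, 255), 32)
    expect_equal(threshold_otsu(f)$threshold, oracle_otsu(f), tolerance = 1e-12)
  }
  # bimodal Gaussian mixture: misclassification < 1 %
  set.seed(52)
  lab <- rep(c(0, 1), each = 2048)
  vals <- ifelse(lab == 0, rnorm(4096, 30, 10), rnorm(4096, 180, 10))
  fr <- matrix(vals, 64, 64)
  msk <- threshold_otsu(fr)$mask
  expect_lt(mean(msk != matrix(lab, 64, 64)), 0.01)
  expect_warning(r0 <- threshold_otsu(matrix(3, 4, 4)), "constant")
  expect_true(all(r0$mask == 0))
})

test_that("Li matches the exhaustive cross-entropy oracle and converges", {
  a <- matrix(c(rep(4, 30), rep(90, 34)), 8, 8)
  r <- threshold_li(a)
  expect_gt(r$threshold, 4); expect_lt(r$threshold, 90)
  expect_identical(r$mask, (a == 90) * 1)
  set.seed(53)
  for (i in 1:5) {
    f <- matrix(runif(32 * 32, 0, 255), 32)
    r <- threshold_li(f)
    expect_equal(r$threshold, oracle_li(f), tolerance = 1e-12)
    expect_lt(r$iterations, 100L)
  }
  expect_error(threshold_li(matrix(c(-1, 2), 1, 2)), "nonnegative")
  expect_warning(threshold_li(matrix(1, 3, 3)), "constant")
})

test_that("Phansalkar agrees with the literal windowed-formula oracle", {
  # constant window: sigma = 0 so t = m * (1 + p e^(-q m) - k); at m = 0.5
  # with defaults t = 0.5 * (1 + 2 e^-5 - 0.25) = 0.37837, center kept.
  # A far-away pixel at twice the plateau sets the normalization max.
  flat <- matrix(50, 15, 15)
  flat[15, 15] <- 100
  r <- threshold_phansalkar(flat, radius = 3)  # normalized to [0, 1] by 100
  t_expected <- 0.5 * (1 + 2 * exp(-10 * 0.5) + 0.25 * (0 / 0.5 - 1))
  expect_equal(r$threshold[5, 5], t_expected, tolerance = 1e-12)
  expect_identical(r$mask[5, 5], 1)  # 0.5 > 0.37837

  set.seed(54)
  f <- matrix(runif(16 * 16, 0, 1000), 16)
  got <- threshold_phansalkar(f, radius = 4)$mask
  expect_identical(got, oracle_phansalkar(f, radius = 4))

  # all-zero frame keeps nothing (strict >)
  expect_true(all(threshold_phansalkar(matrix(0, 8, 8))$mask == 0))
})

test_that("composite mask includes Otsu and preserves surviving values", {
  set.seed(55)
  frames <- list(
    matrix(runif(48 * 48, 0, 500), 48),
    small_phantom(seed = 56, n_frames = 1L, drift = c(0, 0))$donor$frames[, , 1]
  )
  for (f in frames) {
    cm <- threshold_composite(f)
    om <- threshold_otsu(f)$mask
    expect_true(all(cm >= om))           # OR inclusion
    expect_true(all(cm %in% c(0, 1)))
    kept <- cm * f
    expect_identical(kept[cm == 1], f[cm == 1])  # bit-identical survivors
  }
  # a constant frame triggers one warning per degenerate sub-threshold
  w <- testthat::capture_warnings(cm0 <- threshold_composite(matrix(2, 8, 8)))
  expect_match(w, "constant", all = TRUE)
  expect_true(all(cm0 == 0))
  expect_error(threshold_composite(matrix(1, 4, 4), 5, 2), "sigma_low < sigma_high")
})

test_that("composite keeps thin structures that global Otsu drops", {
  ph <- small_phantom(seed = 57, n_frames = 1L, drift = c(0, 0))
  cl <- clean_stacks(ph$donor, ph$acceptor,
                     background = region("bg", "rectangle",
                                         rbind(c(90, 90), c(120, 120)),
                                         role = "background"),
                     align = FALSE)
  f <- cl$donor$frames[, , 1]
  truth <- ph$truth$specimen_mask[, , 1]
  thin <- truth == 1 & ph$truth$ratio_map != 0.50  # neurite + spine pixels
  cm <- threshold_composite(f)
  om <- threshold_otsu(f)$mask
  expect_gt(sum(cm[thin]) / sum(thin), sum(om[thin]) / sum(thin))
  # floor guards against a collapsed (soma-only) mask; the comparative
  # claim above is the substantive one
  expect_gt(sum(cm[thin]) / sum(thin), 0.4)
})

test_that("make_mask_stack adapts per frame where constant cannot", {
  ph <- small_phantom(seed = 58, n_frames = 4L, drift = c(0, 0), noise_sd = 2)
  bg <- region("bg", "rectangle", rbind(c(90, 90), c(120, 120)),
               role = "background")
  cl <- clean_stacks(ph$donor, ph$acceptor, background = bg, align = FALSE)
  donor <- cl$donor
  # constant method: one threshold everywhere
  mc <- make_mask_stack(donor, threshold_config("constant", constant_value =
    threshold_otsu(donor$frames[, , 1])$threshold))
  expect_identical(length(unique(mc$thresholds)), 1L)
  # pixel count under a fixed threshold shrinks as the donor decays
  counts <- apply(mc$frames, 3, sum)
  expect_true(all(diff(counts) <= 0))
  # per-frame composite keeps the soma in both a bright and a halved frame
  half <- donor
  half$frames <- half$frames[, , c(1, 2)]
  half$frames[, , 2] <- half$frames[, , 1] / 2
  mcomp <- make_mask_stack(half, threshold_config("composite"))
  soma <- ph$truth$ratio_map == 0.50
  expect_gt(sum(mcomp$frames[, , 1][soma]) / sum(soma), 0.9)
  expect_gt(sum(mcomp$frames[, , 2][soma]) / sum(soma), 0.9)
})

test_that("apply_mask zeroes discarded pixels and keeps the rest identical", {
  set.seed(59)
  a <- array(runif(8 * 8 * 2, 1, 10), dim = c(8, 8, 2))
  st <- image_stack(a)
  ones <- bretr:::mask_stack(array(1, dim = dim(a)))
  expect_identical(apply_mask(st, ones)$frames, a)
  zeros <- bretr:::mask_stack(array(0, dim = dim(a)))
  expect_true(all(apply_mask(st, zeros)$frames == 0))
  mix <- bretr:::mask_stack(array(rbinom(128, 1, 0.5), dim = dim(a)))
  out <- apply_mask(st, mix)$frames
  expect_identical(out[mix$frames == 1], a[mix$frames == 1])
  expect_true(all(out[mix$frames == 0] == 0))
  expect_error(apply_mask(st, bretr:::mask_stack(array(1, dim = c(4, 4, 2)))),
               "shape")
})

test_that("masks survive the 8-bit 0/255 disk round trip", {
  set.seed(60)
  m <- bretr:::mask_stack(array(rbinom(64, 1, 0.4), dim = c(4, 4, 4)))
  p <- withr::local_tempfile(fileext = ".tif")
  write_mask(m, p)
  r <- read_mask(p)
  expect_identical(r$frames, m$frames)
})
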