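# ratio: masked division, display range, rendering, histogram

test_that("ratio_divide is exact where donor survives and 0 elsewhere", {
  d <- array(c(20, 0, 4, 10), dim = c(2, 2, 1))
  a <- array(c(30, 99, 8, 20), dim = c(2, 2, 1))
  r <- ratio_divide(image_stack(a), image_stack(d))
  expect_equal(r$frames[, , 1], matrix(c(1.5, 0, 2, 2), 2, 2))
  # A = 2 D on masked pixels -> ratio exactly 2
  set.seed(61)
  dm <- array(runif(64, 1, 50) * rbinom(64, 1, 0.6), dim = c(8, 8, 1))
  r2 <- ratio_divide(image_stack(2 * dm), image_stack(dm))
  expect_true(all(r2$frames[dm > 0] == 2))
  expect_true(all(r2$frames[dm == 0] == 0))
  expect_error(ratio_divide(image_stack(matrix(1, 2, 2)),
                            image_stack(matrix(1, 3, 3))), "shapes")
})

test_that("ratio support equals donor support with no non-finite values", {
  set.seed(62)
  for (i in 1:10) {
    d <- array(pmax(rnorm(200, 5, 10), 0), dim = c(10, 10, 2))
    a <- array(runif(200, 0, 30), dim = c(10, 10, 2))
    r <- ratio_divide(image_stack(a), image_stack(d))
    expect_true(all(is.finite(r$frames)))
    expect_identical(r$frames > 0, d > 0 & a > 0)
  }
})

test_that("division commutes with masking", {
  set.seed(63)
  d <- array(runif(128, 1, 40), dim = c(8, 8, 2))
  a <- array(runif(128, 1, 40), dim = c(8, 8, 2))
  mk <- bretr:::mask_stack(array(rbinom(128, 1, 0.5), dim = c(8, 8, 2)))
  # mask donor then divide
  r1 <- ratio_divide(image_stack(a), apply_mask(image_stack(d), mk))
  # divide then mask the ratio
  r0 <- ratio_divide(image_stack(a), image_stack(d))
  r2 <- r0$frames * mk$frames
  expect_equal(r1$frames, r2)
})

test_that("display range uses nearest-rank permilles of nonzero pixels", {
  v <- array(0, dim = c(25, 40, 1))
  v[1:1000] <- sample(1:1000)  # each value once
  r <- structure(list(frames = v), class = "RatioStack")
  dr <- display_range(r)
  expect_identical(dr$low, 5)
  expect_identical(dr$high, 995)
  # zeros never count
  v2 <- array(0, dim = c(25, 40, 2)); v2[1:1000] <- sample(1:1000)
  expect_identical(display_range(structure(list(frames = v2),
                                           class = "RatioStack"))$low, 5)
  # all nonzero equal
  ve <- array(c(0, 7, 7, 7), dim = c(2, 2, 1))
  dre <- display_range(structure(list(frames = ve), class = "RatioStack"))
  expect_identical(c(dre$low, dre$high), c(7, 7))
  expect_error(display_range(structure(list(frames = array(0, c(2, 2, 1))),
                                       class = "RatioStack")), "nonzero")
  expect_error(display_range(r, 900, 100))
})

test_that("pseudocolor binning clamps, centers, and renders zero as black", {
  lut <- lut_cold_hot()
  rng <- manual_range(1, 3)
  fr <- matrix(c(0, 0.5, 1, 2, 2.999, 3, 5, 1.5, 2.5), 3, 3)
  img <- render_pseudocolor(fr, rng, lut)
  px <- function(i, j) img[i, j, ]
  expect_equal(px(1, 1), c(0L, 0L, 0L))            # zero -> black
  expect_equal(px(2, 1), unname(lut[1, ]))                 # below low -> bin 0
  expect_equal(px(3, 1), unname(lut[1, ]))                 # at low -> bin 0
  expect_equal(px(1, 2), unname(lut[9, ]))                 # midpoint -> bin 8
  expect_equal(px(3, 2), unname(lut[16, ]))                # at high -> bin 15
  expect_equal(px(1, 3), unname(lut[16, ]))                # above high -> bin 15
  # scale consistency: (c*v, c*low, c*high) renders identically (generic
  # values; pixels exactly on a bin edge are float-fragile by nature)
  set.seed(65)
  fr2 <- matrix(c(0, runif(15, 0.5, 3.5)), 4, 4)
  imgA <- render_pseudocolor(fr2, rng, lut)
  imgB <- render_pseudocolor(fr2 * 3.7, manual_range(3.7, 3 * 3.7), lut)
  expect_identical(imgB, imgA)
})

test_that("weighted rendering scales brightness by donor intensity", {
  lut <- lut_cold_hot()
  rng <- manual_range(1, 3)
  fr <- matrix(2, 2, 2)       # all midpoint -> bin 8
  dn <- matrix(c(0, 50, 100, 200), 2, 2)
  img <- render_weighted(fr, dn, rng, lut, donor_max = 100)
  expect_equal(img[1, 1, ], c(0L, 0L, 0L))                  # donor 0 -> black
  expect_equal(img[1, 2, ], as.integer(lut[9, ]))           # at max -> full
  expect_equal(img[2, 2, ], as.integer(lut[9, ]))           # above max -> clamped
  expect_equal(img[2, 1, ], as.integer(round(lut[9, ] * 0.5)))  # half max
})

test_that("stack histogram counts exactly the in-range nonzero pixels", {
  set.seed(64)
  v <- array(0, dim = c(20, 20, 3))
  nz <- sample(length(v), 700)
  v[nz] <- runif(700, 1, 2)
  r <- structure(list(frames = v), class = "RatioStack")
  dr <- display_range(r)
  h <- stack_histogram(r, bins = 32)
  inb <- v[v > 0 & v >= dr$low & v <= dr$high]
  expect_identical(sum(h$count), length(inb))
  # zeros never counted: adding zero frames changes nothing
  v2 <- array(0, dim = c(20, 20, 4)); v2[, , 1:3] <- v
  h2 <- stack_histogram(structure(list(frames = v2), class = "RatioStack"),
                        bins = 32)
  expect_identical(h2$count, h$count)
  # uniform values give a flat histogram (chi-square GOF at alpha = 1e-4)
  chi <- sum((h$count - mean(h$count))^2 / mean(h$count))
  expect_lt(chi, qchisq(1 - 1e-4, df = 31))
})

test_that("the default LUT is 16 cold-to-hot entries", {
  lut <- lut_cold_hot()
  expect_identical(dim(lut), c(16L, 3L))
  expect_true(all(lut >= 0 & lut <= 255))
  expect_equal(unname(lut[1, ]), c(0, 0, 255))   # coldest: blue
  expect_equal(unname(lut[16, ]), c(255, 0, 0))  # hottest: red
})

test_that("noiseless phantom ratio is recovered exactly on the support", {
  spec <- phantom_spec(frame_shape = c(96L, 96L), n_frames = 2L,
                       soma = list(center = c(40, 40), radius = 10,
                                   amplitude = 1000, ratio = 0.5),
                       neurites = list(list(from = c(50, 40), to = c(90, 38),
                                            width = 2, amplitude = 60,
                                            ratio = 0.55)),
                       spines = list(list(center = c(70, 34), radius = 2,
                                          amplitude = 40, ratio = 0.65)),
                       donor_decay_tau = 8, drift_per_frame = c(0, 0),
                       camera_offset = 0, noise_sd = 0, seed = 9L)
  ph <- generate_phantom(spec)
  r <- ratio_divide(ph$acceptor, ph$donor)
  sup <- ph$truth$specimen_mask[, , 1] == 1 & ph$truth$ratio_map > 0
  for (t in 1:2) {
    fr <- r$frames[, , t]
    expect_lt(max(abs(fr[sup] - ph$truth$ratio_map[sup])), 1e-2)
  }
})
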