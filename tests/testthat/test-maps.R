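const_dynamic <- function(values_per_frame, dm = c(4, 4, 3)) {
  s <- default_frame_schedule()
  a <- array(rep(values_per_frame, each = prod(dm)), dim = c(dm, 16))
  dynamic_image(a, s)
}

test_that("summation windows select frames by mid-time in [start, end)", {
  di <- const_dynamic(seq_len(16))
  late <- sum_frames(di, c(20, 40))
  expect_equal(attr(late, "frames"), c(15L, 16L))
  early <- sum_frames(di, c(5, 15))
  expect_equal(attr(early, "frames"), c(12L, 13L))
  # duration-weighted mean of frames 15 and 16 (600 s each)
  expect_equal(unique(as.vector(late)), (15 + 16) / 2)
  expect_error(sum_frames(di, c(41, 50)), "no frame")
})

test_that("a constant dynamic image sums to the constant", {
  di <- const_dynamic(rep(3.7, 16))
  expect_equal(unique(as.vector(sum_frames(di, c(0, 40)))), 3.7)
})

test_that("TBR normalization divides by the crescent mean and is scale invariant", {
  set.seed(3)
  img <- array(runif(60, 1, 2), dim = c(5, 4, 3))
  cres <- array(FALSE, dim = dim(img)); cres[1:2, , ] <- TRUE
  tbr <- tbr_normalize(img, cres, "TBR_20_40")
  expect_equal(mean(tbr$voxels[cres]), 1.0)
  expect_equal(attr(tbr, "background_mean"), mean(img[cres]))
  img2 <- img; img2[5, 1, 1] <- 2 * mean(img[cres])
  expect_equal(tbr_normalize(img2, cres)$voxels[5, 1, 1], 2.0)
  tbr_k <- tbr_normalize(7.3 * img, cres, "TBR_20_40")
  expect_equal(tbr_k$voxels, tbr$voxels)
  expect_error(tbr_normalize(img * 0, cres), "crescent")
})

test_that("TTP reports the mid-time of the first frame attaining the maximum", {
  mid <- frame_mid_times(default_frame_schedule())
  inc <- const_dynamic(seq_len(16))
  expect_equal(unique(as.vector(ttp_map(inc)$voxels)), mid[16])
  expect_equal(mid[16], 34 + 2 / 3, tolerance = 1e-12)
  dec <- const_dynamic(rev(seq_len(16)))
  expect_equal(unique(as.vector(ttp_map(dec)$voxels)), mid[1])
  expect_equal(mid[1], 5 / 60)
  tie <- rep(1, 16); tie[c(3, 10)] <- 9
  expect_equal(unique(as.vector(ttp_map(const_dynamic(tie))$voxels)),
               mid[3])
  expect_error(ttp_map(inc, smoothing_window = 4), "odd")
})

test_that("TTP is invariant to positive affine rescaling of the TAC", {
  set.seed(8)
  dm <- c(3, 3, 2)
  a <- array(runif(prod(dm) * 16), dim = c(dm, 16))
  s <- default_frame_schedule()
  t1 <- ttp_map(dynamic_image(a, s))$voxels
  t2 <- ttp_map(dynamic_image(2.5 * a + 7, s))$voxels
  expect_equal(t1, t2)
  # and with smoothing
  t3 <- ttp_map(dynamic_image(a, s), smoothing_window = 3)$voxels
  t4 <- ttp_map(dynamic_image(2.5 * a + 7, s), smoothing_window = 3)$voxels
  expect_equal(t3, t4)
})

test_that("noise-free phenotypes restate the FET-negative definitions", {
  spec <- small_spec(noise_scale = 0)
  iso <- simulate_patient(spec, default_tissue_params("isometabolic"))
  maps <- parametric_maps(iso$dynamic_image, iso$voi_set$crescent_mask)
  tum <- iso$voi_set$tumor_mask; mir <- iso$voi_set$mirrored_mask
  # isometabolic: late TBR within 2% of 1, but kinetically late
  expect_lt(abs(mean(maps$TBR_20_40$voxels[tum]) - 1), 0.02)
  expect_true(all(maps$TTP$voxels[tum] > 30))
  expect_true(all(maps$TTP$voxels[mir] < 10))
  pho <- simulate_patient(spec, default_tissue_params("photopenic"))
  pmaps <- parametric_maps(pho$dynamic_image, pho$voi_set$crescent_mask)
  expect_lt(mean(pmaps$TBR_20_40$voxels[tum]), 1)
  expect_lt(mean(pmaps$TBR_5_15$voxels[tum]), 1)
})
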