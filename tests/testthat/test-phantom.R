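test_that("noise-free homogeneous phantom reproduces the background curve exactly", {
  spec <- small_spec(noise_scale = 0)
  bg <- kinetic_params("background")
  pt <- simulate_patient(spec, list(background = bg, tumor = bg,
                                    ventricle = bg))
  fa <- frame_activity(bg)
  for (f in c(1, 8, 16)) {
    expect_equal(unique(as.vector(pt$dynamic_image$voxels[, , , f])), fa[f])
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- small_spec()
  a <- simulate_patient(spec, seed = 42)
  b <- simulate_patient(spec, seed = 42)
  expect_identical(a$dynamic_image$voxels, b$dynamic_image$voxels)
  expect_identical(a$voi_set$tumor_mask, b$voi_set$tumor_mask)
  c <- simulate_patient(spec, seed = 43)
  expect_false(identical(a$dynamic_image$voxels, c$dynamic_image$voxels))
})

test_that("frame noise has the configured standard deviation", {
  spec <- small_spec(noise_scale = 0.1)
  pt <- simulate_patient(spec, seed = 5)
  # background voxels of the last frame: sd = 0.1 * sqrt(level / 600)
  bgmask <- !(pt$voi_set$tumor_mask | pt$voi_set$ventricle_mask)
  vals <- pt$dynamic_image$voxels[, , , 16][bgmask]
  level <- frame_activity(pt$truth$background)[16]
  expected_sd <- 0.1 * sqrt(level / 600)
  expect_lt(abs(sd(vals[seq_len(1000)]) / expected_sd - 1), 0.1)
})

test_that("phantom masks respect the geometric invariants", {
  pt <- simulate_patient(small_spec(), seed = 2)
  rep_ <- validate_voi_set(pt$voi_set)
  expect_true(rep_$valid)
  # tumor strictly on one side of the plane
  idx <- which(pt$voi_set$tumor_mask, arr.ind = TRUE)
  expect_true(all(idx[, 1] > pt$voi_set$midsagittal_index))
  expect_error(phantom_spec(grid_shape = c(36, 36, 26),
                            tumor_center = c(19, 18, 13)),
               "midsagittal")
})

test_that("cohort plans reproduce the phenotype mix and are deterministic", {
  plan <- cohort_plan(46, c(isometabolic = 29 / 46, photopenic = 17 / 46),
                      base_seed = 7)
  expect_equal(sum(plan$phenotype == "isometabolic"), 29L)
  expect_equal(sum(plan$phenotype == "photopenic"), 17L)
  plan2 <- cohort_plan(46, c(29 / 46, 17 / 46), base_seed = 7)
  expect_identical(plan, plan2)
  one <- cohort_plan(1, c(1, 0), base_seed = 1)
  expect_equal(one$phenotype, "isometabolic")
  expect_error(cohort_plan(10, c(0.5, 0.4)), "summing to 1")
  # jittered parameters stay inside their phenotype envelopes
  expect_true(all(plan$tumor_peak_min > 30))
  iso <- plan$phenotype == "isometabolic"
  expect_true(all(abs(plan$tumor_late_level[iso] - 1) <= 0.04 + 1e-12))
  expect_true(all(plan$tumor_late_level[!iso] < 1))
})

test_that("simulate_cohort materializes the plan", {
  pts <- simulate_cohort(2, c(1, 0), base_seed = 3,
                         spec = small_spec(noise_scale = 0.5))
  expect_length(pts, 2L)
  expect_s3_class(pts[[1]], "synthetic_patient")
  plan <- attr(pts, "plan")
  expect_equal(pts[[1]]$seed, plan$seed[1])
  expect_equal(pts[[2]]$truth$tumor$peak_time_min, plan$tumor_peak_min[2])
})
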