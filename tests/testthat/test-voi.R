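mask_at <- function(dm, coords) {
  m <- array(FALSE, dim = dm)
  m[coords] <- TRUE
  m
}

test_that("mirroring reflects voxels point-wise about the midsagittal plane", {
  dm <- c(11, 7, 5)
  m <- mask_at(dm, cbind(9, 4, 3))  # midplane at 6, k = 3
  out <- mirror_mask(m, 6)
  expect_equal(which(out, arr.ind = TRUE), cbind(row = 3, col = 4, 3),
               ignore_attr = TRUE)
  # half-integer plane between columns
  m2 <- mask_at(c(10, 5, 5), cbind(8, 2, 2))
  out2 <- mirror_mask(m2, 5.5)
  expect_equal(which(out2, arr.ind = TRUE), cbind(3, 2, 2),
               ignore_attr = TRUE)
})

test_that("reflection preserves voxel count and is an involution", {
  set.seed(1)
  dm <- c(16, 9, 9)
  m <- array(FALSE, dim = dm)
  m[10:14, 3:7, 2:6] <- array(runif(5 * 5 * 5) > 0.4, dim = c(5, 5, 5))
  m[10, 5, 4] <- TRUE  # guarantee non-empty
  out <- mirror_mask(m, 8)
  expect_equal(sum(out), sum(m))
  expect_equal(attr(out, "excluded_count"), 0L)
  back <- mirror_mask(out, 8)
  expect_equal(unname(back), unname(m), ignore_attr = TRUE)
})

test_that("exclusion removes exactly the overlapping reflected voxels", {
  dm <- c(12, 6, 6)
  m <- array(FALSE, dim = dm)
  m[9:10, 2:4, 2:4] <- TRUE           # 18 voxels at x 9:10
  excl <- array(FALSE, dim = dm)
  excl[3, 2:4, 2:3] <- TRUE            # hits 5 of the reflected voxels?
  ref <- mirror_mask(m, 6)             # reflected to x 2:3
  overlap <- sum(ref & excl)
  out <- mirror_mask(m, 6, excl)
  expect_equal(attr(out, "excluded_count"), overlap)
  expect_equal(sum(out), sum(m) - overlap)
  expect_false(any(out & excl))
})

test_that("degenerate mirror inputs are rejected", {
  dm <- c(10, 5, 5)
  crossing <- array(FALSE, dim = dm); crossing[4:7, 2, 2] <- TRUE
  expect_error(mirror_mask(crossing, 5.5), "crosses")
  on_plane <- array(FALSE, dim = dm); on_plane[5, 2, 2] <- TRUE
  expect_error(mirror_mask(on_plane, 5), "touches")
  m <- array(FALSE, dim = dm); m[8, 2, 2] <- TRUE
  expect_error(mirror_mask(m, 5, array(TRUE, dim = dm)), "empty")
  expect_error(mirror_mask(array(FALSE, dim = dm), 5), "empty")
  expect_error(mirror_mask(m, 5.2), "whole number")
})

test_that("voi_set validation reports each violated invariant", {
  pt <- simulate_patient(small_spec(noise_scale = 0), seed = 1)
  expect_true(validate_voi_set(pt$voi_set)$valid)

  bad <- voi_set(pt$voi_set$tumor_mask, pt$voi_set$tumor_mask,
                 pt$voi_set$crescent_mask, pt$voi_set$ventricle_mask,
                 pt$voi_set$midsagittal_index)
  v <- validate_voi_set(bad)
  expect_false(v$valid)
  expect_true(any(grepl("overlap", v$violations)))

  empty_cres <- voi_set(pt$voi_set$tumor_mask, pt$voi_set$mirrored_mask,
                        array(FALSE, dim = dim(pt$voi_set$tumor_mask)),
                        pt$voi_set$ventricle_mask,
                        pt$voi_set$midsagittal_index)
  v2 <- validate_voi_set(empty_cres)
  expect_true(any(grepl("crescent_mask is empty", v2$violations)))
})
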