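test_that("extraction yields exactly 93 features in the documented partition", {
  v <- random_voi(21)
  fv <- extract_all(v$image, v$mask)
  expect_length(fv, 93L)
  cls <- table(sub("_.*$", "", names(fv)))
  expect_equal(cls[["firstorder"]], 18L)
  expect_equal(cls[["glcm"]], 24L)
  expect_equal(cls[["glrlm"]], 16L)
  expect_equal(cls[["glszm"]], 16L)
  expect_equal(cls[["gldm"]], 14L)
  expect_equal(cls[["ngtdm"]], 5L)
  expect_true(all(is.finite(fv)))
  # named result features from the analysis exist
  expect_true(all(c("glcm_Idmn", "glcm_ClusterShade",
                    "glszm_SizeZoneNonUniformity",
                    "glszm_SmallAreaHighGrayLevelEmphasis",
                    "gldm_DependenceNonUniformity",
                    "glrlm_HighGrayLevelRunEmphasis",
                    "firstorder_10Percentile") %in% names(fv)))
  expect_identical(fv, extract_all(v$image, v$mask))  # deterministic
})

test_that("count-mode discretization makes texture features scale invariant", {
  v <- random_voi(22)
  v$image <- v$image + 5  # keep intensities positive
  f1 <- extract_all(v$image, v$mask)
  f2 <- extract_all(3.2 * v$image, v$mask)
  tex <- grepl("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-10)
  # histogram-based first-order features unchanged, moments scale
  expect_equal(f1["firstorder_Entropy"], f2["firstorder_Entropy"])
  expect_equal(f1["firstorder_Uniformity"], f2["firstorder_Uniformity"])
  expect_equal(unname(f2["firstorder_Mean"]),
               unname(3.2 * f1["firstorder_Mean"]))
  expect_equal(unname(f2["firstorder_Variance"]),
               unname(3.2^2 * f1["firstorder_Variance"]))
})

test_that("feature maps agree with direct extraction on the window", {
  set.seed(30)
  img <- array(rnorm(7^3), dim = c(7, 7, 7))
  # single in-mask voxel at the center: map value = extract on the 5^3 cube
  msk <- array(FALSE, dim = c(7, 7, 7)); msk[4, 4, 4] <- TRUE
  fm <- feature_map(img, msk, "glcm_Idmn", 5)
  cube <- img[2:6, 2:6, 2:6]
  ref <- extract_all(cube, array(TRUE, dim = c(5, 5, 5)))
  expect_equal(fm[4, 4, 4], unname(ref["glcm_Idmn"]))
  expect_true(all(is.na(fm[-which(msk)])))
  # border voxel: window shrinks to the image bounds
  msk2 <- array(FALSE, dim = c(7, 7, 7)); msk2[1, 1, 1] <- TRUE
  fm2 <- feature_map(img, msk2, "firstorder_Mean", 5)
  expect_equal(fm2[1, 1, 1], mean(img[1:3, 1:3, 1:3]))
})

test_that("constant images give a flat Idmn homogeneity map", {
  img <- array(2, dim = c(5, 5, 5))
  msk <- array(FALSE, dim = c(5, 5, 5)); msk[2:4, 2:4, 3] <- TRUE
  fm <- feature_map(img, msk, "glcm_Idmn", 3)
  expect_equal(unique(fm[msk]), 1)
})

test_that("feature_map validates its inputs", {
  img <- array(1, dim = c(4, 4, 4)); msk <- array(TRUE, dim = c(4, 4, 4))
  expect_error(feature_map(img, msk, "not_a_feature"), "unknown feature")
  expect_error(feature_map(img, msk, "glcm_Idmn", 4), "odd")
})
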