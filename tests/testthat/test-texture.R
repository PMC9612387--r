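test_that("GLCM on a hand-enumerated toy array matches manual counts", {
  # 2x2x1, values by column: x runs within a column
  toy <- array(c(1, 1, 2, 2), dim = c(2, 2, 1))
  lv <- discretize(toy, array(TRUE, dim = c(2, 2, 1)),
                   discretization_config(bin_count = 2))
  dirs <- texture_directions()
  g <- glcm_matrix(lv)
  kx <- which(dirs[, 1] == 1 & dirs[, 2] == 0 & dirs[, 3] == 0)
  # along x: pairs (1,1) and (2,2); symmetric counts double them
  expect_equal(g[[kx]], matrix(c(2, 0, 0, 2), 2))
  ky <- which(dirs[, 1] == 0 & dirs[, 2] == 1 & dirs[, 3] == 0)
  # along y: pairs (1,2) twice, off-diagonal
  expect_equal(g[[ky]], matrix(c(0, 2, 2, 0), 2))
  expect_equal(max(g[[kx]] / sum(g[[kx]])), 0.5)
})

test_that("single-level VOIs hit the documented degenerate conventions", {
  img <- array(5, dim = c(3, 3, 3))
  msk <- array(TRUE, dim = c(3, 3, 3))
  tx <- texture_features(img, msk)
  expect_equal(unname(tx["glcm_JointEnergy"]), 1)
  expect_equal(unname(tx["glcm_Contrast"]), 0)
  expect_equal(unname(tx["glcm_Correlation"]), 1)
  expect_equal(unname(tx["glcm_MCC"]), 1)
  expect_equal(unname(tx["ngtdm_Contrast"]), 0)
  expect_true(all(c("glcm_Correlation", "ngtdm_Contrast") %in%
                    attr(tx, "degenerate")))
  tm <- texture_matrices(discretize(img, msk))
  expect_equal(sum(tm$glszm), 1)       # exactly one zone
  expect_equal(which(tm$glszm[1, ] > 0), 27L)  # of size 27
})

test_that("GLSZM zone sizes partition the VOI voxel count", {
  for (seed in 1:5) {
    v <- random_voi(seed)
    lev <- discretize(v$image, v$mask, discretization_config(bin_count = 6))
    z <- glszm_matrix(lev)
    expect_equal(sum(z * col(z)), sum(v$mask))
  }
})

test_that("vectorized matrices equal brute-force construction on random VOIs", {
  for (seed in 1:6) {
    v <- random_voi(seed + 100)
    lev <- discretize(v$image, v$mask, discretization_config(bin_count = 5))
    fast <- texture_matrices(lev)
    slow <- naive_texture_matrices(lev)
    for (k in 1:13) {
      expect_equal(fast$glcm[[k]], slow$glcm[[k]],
                   info = sprintf("glcm seed %d dir %d", seed, k))
      # run-length: compare on the common column span (trailing zeros aside)
      nc <- ncol(slow$glrlm[[k]])
      expect_equal(fast$glrlm[[k]][, seq_len(nc)], slow$glrlm[[k]],
                   info = sprintf("glrlm seed %d dir %d", seed, k))
      if (ncol(fast$glrlm[[k]]) > nc) {
        expect_true(all(fast$glrlm[[k]][, -seq_len(nc)] == 0))
      }
    }
    expect_equal(fast$glszm, slow$glszm, info = paste("glszm", seed))
    expect_equal(fast$gldm, slow$gldm, info = paste("gldm", seed))
    expect_equal(fast$ngtdm$n, slow$ngtdm$n)
    expect_equal(fast$ngtdm$s, slow$ngtdm$s, tolerance = 1e-12)
    expect_equal(fast$ngtdm$n_valid, slow$ngtdm$n_valid)
  }
})

test_that("texture features are invariant to flips and axis-aligned rotations", {
  v <- random_voi(7)
  f0 <- texture_features(v$image, v$mask)
  flip <- function(a, ax) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- rev(seq_len(dim(a)[ax]))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (ax in 1:3) {
    fi <- texture_features(flip(v$image, ax), flip(v$mask, ax))
    expect_equal(fi, f0, tolerance = 1e-12, ignore_attr = TRUE)
  }
  rot <- function(a) {  # 90 degrees in the xy plane
    b <- aperm(a, c(2, 1, 3))
    flip(b, 1)
  }
  fr <- texture_features(rot(v$image), rot(v$mask))
  expect_equal(fr, f0, tolerance = 1e-12, ignore_attr = TRUE)
})
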