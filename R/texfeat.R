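# Texture feature formulas.
#
# Feature names follow the camel-case convention common to radiomics
# software so tables are comparable across tools. GLCM and GLRLM features
# are computed per direction and averaged over the 13 directions.
# Degenerate conventions (single-gray-level VOI): correlation-type GLCM
# features = 1, information measures and NGTDM contrast/busyness/strength
# = 0; every such evaluation is flagged.

.glcm_features_one <- function(P) {
  Ng <- nrow(P)
  tot <- sum(P)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(p * i)            # symmetric: mu_x = mu_y
  sig2 <- sum(p * (i - mu)^2)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HXY <- ent(p)
  HX <- ent(px)
  pxpy <- outer(px, px)
  nz <- p > 0 & pxpy > 0
  HXY1 <- -sum(p[nz] * log2(pxpy[nz]))
  HXY2 <- ent(pxpy)
  da <- sum(k_diff * p_diff)
  flags <- character(0)
  if (sig2 > 0) {
    correlation <- (sum(p * i * j) - mu^2) / sig2
  } else {
    correlation <- 1
    flags <- c(flags, "glcm_Correlation")
  }
  if (max(HX, 0) > 0) {
    imc1 <- (HXY - HXY1) / HX
    imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  } else {
    imc1 <- 0; imc2 <- 0
    flags <- c(flags, "glcm_Imc1", "glcm_Imc2")
  }
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k)/(px_i px_k)
  act <- which(px > 0)
  if (length(act) > 1) {
    psub <- p[act, act, drop = FALSE]
    pxs <- px[act]
    Q <- matrix(0, length(act), length(act))
    for (kk in seq_along(act)) {
      Q <- Q + outer(psub[, kk] / pxs, psub[, kk] / pxs[kk])
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(ev[2], 0))
  } else {
    mcc <- 1
    flags <- c(flags, "glcm_MCC")
  }
  vals <- c(
    glcm_Autocorrelation = sum(p * i * j),
    glcm_ClusterProminence = sum(p * (i + j - 2 * mu)^4),
    glcm_ClusterShade = sum(p * (i + j - 2 * mu)^3),
    glcm_ClusterTendency = sum(p * (i + j - 2 * mu)^2),
    glcm_Contrast = sum(p * (i - j)^2),
    glcm_Correlation = correlation,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent(p_diff),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    glcm_Id = sum(p_diff / (1 + k_diff)),
    glcm_Idm = sum(p_diff / (1 + k_diff^2)),
    glcm_Idmn = sum(p_diff / (1 + k_diff^2 / Ng^2)),
    glcm_Idn = sum(p_diff / (1 + k_diff / Ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(p_diff[-1] / k_diff[-1]^2),
    glcm_JointAverage = mu,
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = HXY,
    glcm_MaximumProbability = max(p),
    glcm_MCC = mcc,
    glcm_SumAverage = sum(k_sum * p_sum),
    glcm_SumEntropy = ent(p_sum),
    glcm_SumSquares = sig2
  )
  attr(vals, "degenerate") <- flags
  vals
}

#' GLCM features (24), averaged over the 13 directions
#' @param glcms List of per-direction co-occurrence matrices from
#'   [glcm_matrix()].
#' @return Named numeric vector with attribute `degenerate`.
#' @export
glcm_features <- function(glcms) {
  glcms <- Filter(function(m) sum(m) > 0, glcms)
  per <- lapply(glcms, .glcm_features_one)
  out <- Reduce(`+`, per) / length(per)
  attr(out, "degenerate") <-
    unique(unlist(lapply(per, attr, "degenerate")))
  out
}

.rl_features_one <- function(P, n_voxels) {
  nr <- sum(P)
  p <- P / nr
  i <- row(P); r <- col(P)
  mu_i <- sum(p * i)
  mu_r <- sum(p * r)
  pp <- p[p > 0]
  c(
    glrlm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    glrlm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    glrlm_HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    glrlm_LongRunEmphasis = sum(P * r^2) / nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(P * r^2 * i^2) / nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(P * r^2 / i^2) / nr,
    glrlm_LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    glrlm_RunEntropy = -sum(pp * log2(pp)),
    glrlm_RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    glrlm_RunPercentage = nr / n_voxels,
    glrlm_RunVariance = sum(p * (r - mu_r)^2),
    glrlm_ShortRunEmphasis = sum(P / r^2) / nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(P * i^2 / r^2) / nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * r^2)) / nr
  )
}

#' GLRLM features (16), averaged over the 13 directions
#' @param glrlms List of per-direction run-length matrices from
#'   [glrlm_matrix()].
#' @param n_voxels VOI voxel count (run percentage denominator).
#' @return Named numeric vector.
#' @export
glrlm_features <- function(glrlms, n_voxels) {
  per <- lapply(glrlms, .rl_features_one, n_voxels = n_voxels)
  Reduce(`+`, per) / length(per)
}

#' GLSZM features (16)
#' @param P Size-zone count matrix from [glszm_matrix()].
#' @param n_voxels VOI voxel count (zone percentage denominator).
#' @return Named numeric vector.
#' @export
glszm_features <- function(P, n_voxels) {
  nz <- sum(P)
  p <- P / nz
  i <- row(P); s <- col(P)
  mu_i <- sum(p * i)
  mu_s <- sum(p * s)
  pp <- p[p > 0]
  c(
    glszm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nz^2,
    glszm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    glszm_HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    glszm_LargeAreaEmphasis = sum(P * s^2) / nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(P * s^2 * i^2) / nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(P * s^2 / i^2) / nz,
    glszm_LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    glszm_SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    glszm_SmallAreaEmphasis = sum(P / s^2) / nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / s^2) / nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * s^2)) / nz,
    glszm_ZoneEntropy = -sum(pp * log2(pp)),
    glszm_ZonePercentage = nz / n_voxels,
    glszm_ZoneVariance = sum(p * (s - mu_s)^2)
  )
}

#' GLDM features (14)
#' @param P Dependence count matrix from [gldm_matrix()].
#' @return Named numeric vector.
#' @export
gldm_features <- function(P) {
  nz <- sum(P)
  p <- P / nz
  i <- row(P); j <- col(P)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pp <- p[p > 0]
  c(
    gldm_DependenceEntropy = -sum(pp * log2(pp)),
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    gldm_DependenceVariance = sum(p * (j - mu_j)^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    gldm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    gldm_HighGrayLevelEmphasis = sum(P * i^2) / nz,
    gldm_LargeDependenceEmphasis = sum(P * j^2) / nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * j^2 * i^2) / nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    gldm_LowGrayLevelEmphasis = sum(P / i^2) / nz,
    gldm_SmallDependenceEmphasis = sum(P / j^2) / nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz
  )
}

#' NGTDM features (5)
#' @param m NGTDM components from [ngtdm_matrix()].
#' @return Named numeric vector with attribute `degenerate`.
#' @export
ngtdm_features <- function(m) {
  nv <- m$n_valid
  p <- m$n / nv
  s <- m$s
  act <- which(p > 0)
  ngp <- length(act)
  flags <- character(0)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ps <= 0) flags <- c(flags, "ngtdm_Coarseness")
  if (ngp > 1) {
    ii <- act
    pg <- p[act]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pg, pg) * dif2) / (ngp * (ngp - 1)) * sum(s) / nv
    ipi <- ii * pg
    # denominator runs over ordered pairs (i, j), both p > 0
    busy_den <- sum(abs(outer(ipi, ipi, `-`)))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    if (busy_den <= 0) flags <- c(flags, "ngtdm_Busyness")
    absdif <- abs(outer(ii, ii, `-`))
    one <- rep(1, ngp)
    num_c <- outer(pg * s[act], one) + outer(one, pg * s[act])
    den_c <- outer(pg, pg, `+`)
    complexity <- sum(absdif * num_c / den_c) / nv
    strength_num <- sum(den_c * dif2)
    strength <- if (sum(s) > 0) strength_num / sum(s) else 0
    if (sum(s) <= 0) flags <- c(flags, "ngtdm_Strength")
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
    flags <- c(flags, "ngtdm_Contrast", "ngtdm_Busyness", "ngtdm_Complexity",
               "ngtdm_Strength")
  }
  out <- c(ngtdm_Busyness = busyness, ngtdm_Coarseness = coarseness,
           ngtdm_Complexity = complexity, ngtdm_Contrast = contrast,
           ngtdm_Strength = strength)
  attr(out, "degenerate") <- flags
  out
}

#' All 75 texture features of a discretized VOI
#'
#' Builds the five texture matrix families at distance 1 (13 averaged
#' directions for GLCM/GLRLM, 26-connected zones for GLSZM, distance-1
#' dependences and neighborhoods for GLDM/NGTDM) and evaluates
#' 24 + 16 + 16 + 14 + 5 features.
#'
#' @param image 3D numeric array.
#' @param mask Logical 3D array with >= 2 voxels.
#' @param config A [discretization_config()].
#' @return Named numeric vector of 75 features with attribute `degenerate`.
#' @export
texture_features <- function(image, mask, config = discretization_config()) {
  mask <- mask > 0
  if (sum(mask) < 2L) stop("texture features need a mask with >= 2 voxels")
  lev <- discretize(image, mask, config)
  tm <- texture_matrices(lev)
  texture_features_from_matrices(tm)
}

#' Evaluate the 75 texture features from precomputed matrices
#' @param tm Output of [texture_matrices()].
#' @return Named numeric vector of 75 features with attribute `degenerate`.
#' @export
texture_features_from_matrices <- function(tm) {
  f_glcm <- glcm_features(tm$glcm)
  f_ngtdm <- ngtdm_features(tm$ngtdm)
  out <- c(f_glcm,
           glrlm_features(tm$glrlm, tm$n_voxels),
           glszm_features(tm$glszm, tm$n_voxels),
           gldm_features(tm$gldm),
           f_ngtdm)
  attr(out, "degenerate") <- c(attr(f_glcm, "degenerate"),
                               attr(f_ngtdm, "degenerate"))
  out
}
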