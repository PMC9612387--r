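# Texture matrix construction.
#
# All builders operate on a discretized level array (integer, NA outside the
# VOI) at Chebyshev distance 1: 13 unique 3D directions for GLCM/GLRLM (the
# 26-neighborhood modulo sign), the full 26-neighborhood for GLSZM zones,
# GLDM dependences and NGTDM neighborhoods.

#' The 13 unique distance-1 3D directions
#'
#' One representative of each +/- pair of the 26 Chebyshev-distance-1
#' offsets.
#'
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
texture_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# 26-neighborhood offsets (both signs)
.offsets26 <- function() {
  d <- texture_directions()
  rbind(d, -d)
}

# crop level array to the bounding box of non-NA voxels
.crop_levels <- function(lev) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  out <- lev[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
             drop = FALSE]
  array(out, dim = c(rng[2, ] - rng[1, ] + 1L))
}

# values of `a` at position + d, NA outside
.shift3 <- function(a, d) {
  dm <- dim(a)
  out <- array(NA_integer_, dim = dm)
  lo <- pmax(1, 1 + d)
  hi <- pmin(dm, dm + d)
  if (any(lo > hi)) return(out)
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  out[sx - d[1], sy - d[2], sz - d[3]] <- a[sx, sy, sz]
  out
}

#' Gray-level co-occurrence matrices
#'
#' Symmetric distance-1 GLCMs, one per direction.
#'
#' @param lev Discretized level array from [discretize()].
#' @param n_levels Number of gray levels; defaults to the `n_levels`
#'   attribute of `lev`.
#' @return List of 13 `n_levels x n_levels` count matrices (one per row of
#'   [texture_directions()]).
#' @export
glcm_matrix <- function(lev, n_levels = attr(lev, "n_levels")) {
  n_levels <- as.integer(n_levels)
  lev <- .crop_levels(lev)
  dirs <- texture_directions()
  lapply(seq_len(nrow(dirs)), function(k) {
    lj <- .shift3(lev, dirs[k, ])
    ok <- !is.na(lev) & !is.na(lj)
    m <- matrix(0, n_levels, n_levels)
    if (any(ok)) {
      cnt <- tabulate((lev[ok] - 1L) * n_levels + lj[ok],
                      nbins = n_levels * n_levels)
      m <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
    }
    m + t(m)  # symmetric
  })
}

#' Gray-level run-length matrices
#'
#' Runs of equal gray level along each of the 13 directions; out-of-VOI
#' voxels break runs.
#'
#' @inheritParams glcm_matrix
#' @return List of 13 `n_levels x max_run` count matrices.
#' @export
glrlm_matrix <- function(lev, n_levels = attr(lev, "n_levels")) {
  n_levels <- as.integer(n_levels)
  lev <- .crop_levels(lev)
  dm <- dim(lev)
  coords <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                  z = seq_len(dm[3])))
  v <- as.integer(lev)
  dirs <- texture_directions()
  max_run <- max(dm)
  lapply(seq_len(nrow(dirs)), function(k) {
    d <- dirs[k, ]
    m <- sum(d != 0)
    t_par <- coords %*% d                    # increments by m along the line
    key <- coords * m - tcrossprod(t_par, d) # constant along the line
    # encode key triple as one number for ordering
    B <- 8L * max(dm) + 8L
    kid <- (key[, 1] + B) * B^2 + (key[, 2] + B) * B + key[, 3] + B
    ord <- order(kid, t_par)
    vo <- v[ord]
    ko <- kid[ord]
    new_line <- c(TRUE, ko[-1] != ko[-length(ko)])
    # run breaks: new line, level change, or NA
    same <- c(FALSE, !is.na(vo[-1]) & !is.na(vo[-length(vo)]) &
                vo[-1] == vo[-length(vo)])
    run_id <- cumsum(new_line | !same)
    keep <- !is.na(vo)
    if (!any(keep)) return(matrix(0, n_levels, max_run))
    rl <- tapply(rep(1L, sum(keep)), run_id[keep], sum)
    rlev <- tapply(vo[keep], run_id[keep], function(z) z[1])
    cnt <- tabulate((as.integer(rlev) - 1L) * max_run + as.integer(rl),
                    nbins = n_levels * max_run)
    matrix(cnt, n_levels, max_run, byrow = TRUE)
  })
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level; zone sizes
#' partition the VOI voxel count.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels x max_zone_size` count matrix.
#' @export
glszm_matrix <- function(lev, n_levels = attr(lev, "n_levels")) {
  n_levels <- as.integer(n_levels)
  lev <- .crop_levels(lev)
  dm <- dim(lev)
  np <- sum(!is.na(lev))
  m <- matrix(0, n_levels, np)
  offs <- .offsets26()
  lin <- function(cc) (cc[, 3] - 1L) * dm[1] * dm[2] + (cc[, 2] - 1L) * dm[1] + cc[, 1]
  for (g in sort(unique(lev[!is.na(lev)]))) {
    idx <- which(!is.na(lev) & lev == g, arr.ind = TRUE)
    n <- nrow(idx)
    ids <- lin(idx)
    edges <- NULL
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(idx, 2, offs[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      j <- match(lin(nb[ok, , drop = FALSE]), ids)
      i <- which(ok)[!is.na(j)]
      j <- j[!is.na(j)]
      if (length(i)) edges <- rbind(edges, cbind(i, j))
    }
    g_graph <- igraph::graph_from_data_frame(
      if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
      else data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    sizes <- igraph::components(g_graph)$csize
    for (s in sizes) m[g, s] <- m[g, s] + 1
  }
  used <- max(which(colSums(m) > 0))
  m[, seq_len(used), drop = FALSE]
}

#' Gray-level dependence matrix
#'
#' Dependence size of a voxel is 1 (the voxel itself) plus the number of its
#' in-VOI 26-neighbors with identical gray level (distance 1, tolerance
#' alpha = 0).
#'
#' @inheritParams glcm_matrix
#' @return `n_levels x max_dependence` count matrix.
#' @export
gldm_matrix <- function(lev, n_levels = attr(lev, "n_levels")) {
  n_levels <- as.integer(n_levels)
  lev <- .crop_levels(lev)
  offs <- .offsets26()
  dep <- array(0L, dim = dim(lev))
  for (k in seq_len(nrow(offs))) {
    nb <- .shift3(lev, offs[k, ])
    dep <- dep + (!is.na(nb) & !is.na(lev) & nb == lev)
  }
  ok <- !is.na(lev)
  j <- dep[ok] + 1L
  maxd <- max(j)
  cnt <- tabulate((lev[ok] - 1L) * maxd + j, nbins = n_levels * maxd)
  matrix(cnt, n_levels, maxd, byrow = TRUE)
}

#' Neighborhood gray-tone difference matrix components
#'
#' For each gray level i: `n_i` voxels of level i having at least one in-VOI
#' 26-neighbor, and `s_i`, the summed absolute difference between i and the
#' mean level of each such voxel's in-VOI neighbors.
#'
#' @inheritParams glcm_matrix
#' @return List with `n` (counts per level), `s` (difference sums) and
#'   `n_valid` (total voxels with a valid neighborhood).
#' @export
ngtdm_matrix <- function(lev, n_levels = attr(lev, "n_levels")) {
  n_levels <- as.integer(n_levels)
  lev <- .crop_levels(lev)
  offs <- .offsets26()
  ssum <- array(0, dim = dim(lev))
  scnt <- array(0L, dim = dim(lev))
  for (k in seq_len(nrow(offs))) {
    nb <- .shift3(lev, offs[k, ])
    has <- !is.na(nb)
    ssum[has] <- ssum[has] + nb[has]
    scnt <- scnt + has
  }
  ok <- !is.na(lev) & scnt > 0L
  diffs <- abs(lev[ok] - ssum[ok] / scnt[ok])
  li <- lev[ok]
  n <- tabulate(li, n_levels)
  s <- vapply(seq_len(n_levels), function(g) sum(diffs[li == g]), numeric(1))
  list(n = n, s = s, n_valid = sum(ok))
}

#' All texture matrices of a discretized VOI
#'
#' @inheritParams glcm_matrix
#' @return List with elements `glcm`, `glrlm` (lists of per-direction
#'   matrices), `glszm`, `gldm` (count matrices), `ngtdm` (components),
#'   `n_levels` and `n_voxels`.
#' @export
texture_matrices <- function(lev, n_levels = attr(lev, "n_levels")) {
  list(glcm = glcm_matrix(lev, n_levels),
       glrlm = glrlm_matrix(lev, n_levels),
       glszm = glszm_matrix(lev, n_levels),
       gldm = gldm_matrix(lev, n_levels),
       ngtdm = ngtdm_matrix(lev, n_levels),
       n_levels = n_levels,
       n_voxels = sum(!is.na(lev)))
}
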