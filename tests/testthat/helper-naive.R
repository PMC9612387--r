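# Brute-force texture matrix builders: plain nested loops over voxels and
# offsets, written independently of the package's vectorized builders, used
# as the oracle for matrix-construction equivalence.

naive_in <- function(dm, p) all(p >= 1) && all(p <= dm)

naive_glcm <- function(lev, n_levels) {
  dm <- dim(lev)
  dirs <- texture_directions()
  lapply(seq_len(nrow(dirs)), function(k) {
    d <- dirs[k, ]
    m <- matrix(0, n_levels, n_levels)
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      i <- lev[x, y, z]
      if (is.na(i)) next
      p <- c(x, y, z) + d
      if (!naive_in(dm, p)) next
      j <- lev[p[1], p[2], p[3]]
      if (is.na(j)) next
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
    m
  })
}

naive_glrlm <- function(lev, n_levels) {
  dm <- dim(lev)
  dirs <- texture_directions()
  lapply(seq_len(nrow(dirs)), function(k) {
    d <- dirs[k, ]
    m <- matrix(0, n_levels, max(dm))
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      i <- lev[x, y, z]
      if (is.na(i)) next
      prev <- c(x, y, z) - d
      if (naive_in(dm, prev) &&
          !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == i) next  # not a run start
      len <- 1
      p <- c(x, y, z) + d
      while (naive_in(dm, p) && !is.na(lev[p[1], p[2], p[3]]) &&
             lev[p[1], p[2], p[3]] == i) {
        len <- len + 1
        p <- p + d
      }
      m[i, len] <- m[i, len] + 1
    }
    m
  })
}

naive_glszm <- function(lev, n_levels) {
  dm <- dim(lev)
  offs <- rbind(texture_directions(), -texture_directions())
  seen <- array(FALSE, dim = dm)
  np <- sum(!is.na(lev))
  m <- matrix(0, n_levels, np)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    i <- lev[x, y, z]
    if (is.na(i) || seen[x, y, z]) next
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (naive_in(dm, q) && !seen[q[1], q[2], q[3]] &&
            !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == i) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    m[i, size] <- m[i, size] + 1
  }
  used <- max(which(colSums(m) > 0))
  m[, seq_len(used), drop = FALSE]
}

naive_gldm <- function(lev, n_levels) {
  dm <- dim(lev)
  offs <- rbind(texture_directions(), -texture_directions())
  counts <- list()
  maxd <- 1
  rows <- NULL
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    i <- lev[x, y, z]
    if (is.na(i)) next
    dep <- 1
    for (k in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[k, ]
      if (naive_in(dm, p) && !is.na(lev[p[1], p[2], p[3]]) &&
          lev[p[1], p[2], p[3]] == i) dep <- dep + 1
    }
    rows <- rbind(rows, c(i, dep))
    maxd <- max(maxd, dep)
  }
  m <- matrix(0, n_levels, maxd)
  for (r in seq_len(nrow(rows))) {
    m[rows[r, 1], rows[r, 2]] <- m[rows[r, 1], rows[r, 2]] + 1
  }
  m
}

naive_ngtdm <- function(lev, n_levels) {
  dm <- dim(lev)
  offs <- rbind(texture_directions(), -texture_directions())
  n <- numeric(n_levels)
  s <- numeric(n_levels)
  n_valid <- 0
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    i <- lev[x, y, z]
    if (is.na(i)) next
    vals <- c()
    for (k in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[k, ]
      if (naive_in(dm, p) && !is.na(lev[p[1], p[2], p[3]])) {
        vals <- c(vals, lev[p[1], p[2], p[3]])
      }
    }
    if (!length(vals)) next
    n[i] <- n[i] + 1
    s[i] <- s[i] + abs(i - mean(vals))
    n_valid <- n_valid + 1
  }
  list(n = n, s = s, n_valid = n_valid)
}

naive_texture_matrices <- function(lev, n_levels = attr(lev, "n_levels")) {
  list(glcm = naive_glcm(lev, n_levels),
       glrlm = naive_glrlm(lev, n_levels),
       glszm = naive_glszm(lev, n_levels),
       gldm = naive_gldm(lev, n_levels),
       ngtdm = naive_ngtdm(lev, n_levels),
       n_levels = n_levels,
       n_voxels = sum(!is.na(lev)))
}

# random small VOI fixture: image + mask with at least two gray levels
random_voi <- function(seed, max_dim = 8) {
  set.seed(seed)
  dm <- sample(3:max_dim, 3, replace = TRUE)
  img <- array(rnorm(prod(dm)), dim = dm)
  repeat {
    msk <- array(runif(prod(dm)) < 0.7, dim = dm)
    if (sum(msk) >= 4 && length(unique(round(img[msk], 3))) > 1) break
  }
  list(image = img, mask = msk)
}
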