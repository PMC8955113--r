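# Independent brute-force oracles, kept deliberately naive: pixel-by-pixel
# loops that transcribe the published rules directly, used only to check
# the package's vectorized implementations.

# value of the P_i neighbour (clockwise from north) of (r, c); pixels
# outside the grid are background
oracle_p <- function(m, r, c, i) {
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))[[i - 1]]
  r2 <- r + off[1]; c2 <- c + off[2]
  if (r2 < 1 || r2 > nrow(m) || c2 < 1 || c2 > ncol(m)) return(0L)
  as.integer(m[r2, c2])
}

# one thinning sub-iteration by direct rule application, including the
# guard that a sub-iteration never deletes a whole component (the plain
# rules would erase an isolated 2x2 square)
oracle_zs_subiter <- function(m, sub) {
  del <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c]) next
    p <- vapply(2:9, function(i) oracle_p(m, r, c, i), integer(1))
    b <- sum(p)
    if (b < 2 || b > 6) next
    ring <- c(p, p[1])
    a <- sum(ring[-length(ring)] == 0 & ring[-1] == 1)
    if (a != 1) next
    # p is indexed P2..P9 -> positions 1..8
    if (sub == 1) {
      if (p[1] * p[3] * p[5] != 0) next  # P2*P4*P6
      if (p[3] * p[5] * p[7] != 0) next  # P4*P6*P8
    } else {
      if (p[1] * p[3] * p[7] != 0) next  # P2*P4*P8
      if (p[1] * p[5] * p[7] != 0) next  # P2*P6*P8
    }
    del[r, c] <- TRUE
  }
  # component guard, by an independent flood fill from each pixel
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c]) next
    comp <- matrix(FALSE, nrow(m), ncol(m))
    stack <- list(c(r, c)); comp[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nrow(m) || c2 < 1 || c2 > ncol(m)) next
        if (m[r2, c2] && !comp[r2, c2]) {
          comp[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    if (all(del[comp])) {
      first <- which(comp)[1]  # column-major first pixel survives
      del[first] <- FALSE
    }
  }
  m & !del
}

oracle_zhang_suen <- function(m) {
  repeat {
    m2 <- oracle_zs_subiter(oracle_zs_subiter(m, 1), 2)
    if (identical(m2, m)) return(m)
    m <- m2
  }
}

# number of 8-connected components, by repeated seeded flood fill
oracle_n_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || seen[r, c]) next
    n <- n + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
        if (mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  n
}

# exhaustive Otsu: try every midpoint between consecutive distinct values,
# return the one maximizing between-class variance
oracle_otsu <- function(vals) {
  v <- sort(unique(vals))
  cand <- (head(v, -1) + tail(v, -1)) / 2
  bc <- vapply(cand, function(th) {
    lo <- vals <= th
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(vals[lo]) - mean(vals[!lo]))^2
  }, numeric(1))
  cand[which.max(bc)]
}

# bounding-box extents of a mask: c(rows, cols)
mask_extent <- function(mask) {
  if (!any(mask)) return(c(rows = 0L, cols = 0L))
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  c(rows = diff(rr) + 1L, cols = diff(cc) + 1L)
}

# centroid of a mask: c(row, col)
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
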