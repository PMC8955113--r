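#' Binarize a thermal frame
#'
#' Foreground = pixels warmer than a threshold. The default is a fixed
#' threshold at a plausible apparent human temperature; Otsu's criterion
#' (the threshold maximizing between-class variance of the frame's
#' intensity histogram) is available as the adaptive alternative.
#'
#' @param frame numeric temperature matrix.
#' @param mode `"fixed"` or `"otsu"`.
#' @param threshold fixed threshold in degrees C (fixed mode only).
#' @return A logical matrix of the same dimensions, with attributes
#'   `threshold` (the value used) and any `time` attribute of the frame.
#'   Otsu on a constant frame is degenerate: an empty mask is returned
#'   with a warning.
#' @examples
#' fr <- matrix(21, 24, 32); fr[10:14, 10:12] <- 31
#' sum(binarize(fr))
#' @export
binarize <- function(frame, mode = c("fixed", "otsu"), threshold = 28) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(frame))
  if (mode == "fixed") {
    if (!is.finite(threshold)) stop("fixed `threshold` must be finite")
    thr <- threshold
  } else {
    vals <- as.numeric(frame)
    if (length(unique(vals)) < 2) {
      warning("Otsu threshold undefined on a constant frame; ",
              "returning an empty mask")
      out <- matrix(FALSE, nrow(frame), ncol(frame))
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    thr <- otsu_threshold(vals)
  }
  out <- frame > thr
  attr(out, "threshold") <- thr
  attr(out, "time") <- attr(frame, "time")
  out
}

# Otsu's between-class variance criterion, maximized over thresholds
# midway between consecutive distinct values
otsu_threshold <- function(vals) {
  v <- sort(unique(vals))
  cand <- (v[-length(v)] + v[-1]) / 2
  n <- length(vals)
  best <- cand[1]; best_var <- -Inf
  for (th in cand) {
    lo <- vals <= th
    w0 <- sum(lo) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    bc <- w0 * w1 * (mean(vals[lo]) - mean(vals[!lo]))^2
    if (bc > best_var) {
      best_var <- bc
      best <- th
    }
  }
  best
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighbourhood of each pixel as a list of shifted masks, clockwise
# from north: P2..P9 in the thinning literature's numbering
neighbour_stack <- function(m) {
  list(
    p2 = shift_mask(m, -1, 0), p3 = shift_mask(m, -1, 1),
    p4 = shift_mask(m, 0, 1),  p5 = shift_mask(m, 1, 1),
    p6 = shift_mask(m, 1, 0),  p7 = shift_mask(m, 1, -1),
    p8 = shift_mask(m, 0, -1), p9 = shift_mask(m, -1, -1)
  )
}

# count of foreground 8-neighbours per pixel
neighbour_count <- function(m) {
  Reduce(`+`, lapply(neighbour_stack(m), function(x) x * 1L))
}

# label 8-connected components; 0 = background
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# 3x3 binary dilation / erosion (border treated as background)
dilate3 <- function(m) {
  Reduce(`|`, c(list(m), neighbour_stack(m)))
}
erode3 <- function(m) {
  nb <- neighbour_stack(m)
  # a pixel survives only if itself and all in-grid neighbours are set;
  # out-of-grid neighbours count as background, so border pixels erode
  m & Reduce(`&`, nb)
}

#' Clean a binary mask before skeletonization
#'
#' One pass of 3x3 morphological closing (bridging 1-pixel gaps) followed
#' by removal of 8-connected components smaller than `min_component_px`.
#'
#' @param mask logical matrix.
#' @param min_component_px minimum component size kept, in pixels.
#' @return A logical matrix of the same dimensions.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2, 2] <- TRUE; m[4:6, 4:6] <- TRUE
#' sum(clean_mask(m, min_component_px = 3))
#' @export
clean_mask <- function(mask, min_component_px = 3) {
  stopifnot(is.logical(mask), min_component_px >= 0)
  if (!any(mask)) return(mask)
  closed <- erode3(dilate3(mask)) | mask
  lab <- label_components(closed)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_px)
    closed <- matrix(lab %in% keep & lab > 0, nrow(mask), ncol(mask))
  }
  closed
}

# one Zhang-Suen sub-iteration, vectorized over the whole grid;
# sub = 1: delete when P2*P4*P6 == 0 and P4*P6*P8 == 0
# sub = 2: delete when P2*P4*P8 == 0 and P2*P6*P8 == 0
zs_subiter <- function(m, sub) {
  nb <- neighbour_stack(m)
  b <- Reduce(`+`, lapply(nb, function(x) x * 1L))
  ring <- c(nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9")],
            nb["p2"])
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) {
    a <- a + (!ring[[i]] & ring[[i + 1]]) * 1L
  }
  if (sub == 1) {
    cond <- !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
  } else {
    cond <- !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
  }
  del <- m & b >= 2 & b <= 6 & a == 1 & cond
  # degeneracy guard: the plain rules erase an isolated 2x2 square in one
  # sub-iteration; never let a sub-iteration delete a whole component --
  # its first pixel (column-major order) is retained instead
  if (any(del)) {
    lab <- label_components(m)
    for (comp in seq_len(max(lab))) {
      px <- which(lab == comp)
      if (all(del[px])) del[px[1]] <- FALSE
    }
  }
  m & !del
}

#' Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels with the two-sub-iteration
#' Zhang-Suen rule set (neighbour count 2..6, exactly one 0-to-1
#' transition around the pixel, and the directional corner conditions)
#' until a full pass deletes nothing. Pixels outside the grid count as
#' background. The result is the single-pixel-wide center line of each
#' blob, preserving 8-connectivity. One guard handles the rule set's
#' known degeneracy (an isolated 2x2 square satisfies the deletion
#' conditions at all four pixels): a sub-iteration never deletes the
#' last pixels of a component, so component counts are preserved.
#'
#' @param mask logical matrix (a [binarize()] / [clean_mask()] output).
#' @return A logical skeleton matrix of the same dimensions.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' sum(zhang_suen_thin(m))
#' @export
zhang_suen_thin <- function(mask) {
  stopifnot(is.logical(mask))
  m <- mask
  repeat {
    m1 <- zs_subiter(m, 1)
    m2 <- zs_subiter(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

#' Classify skeleton pixels as endpoints, path or branch pixels
#'
#' @param skel logical skeleton matrix.
#' @return Character matrix with `""` on background and `"endpoint"`
#'   (1 neighbour, or an isolated pixel), `"path"` (2 neighbours) or
#'   `"branch"` (3+ neighbours) on skeleton pixels.
#' @export
skeleton_roles <- function(skel) {
  b <- neighbour_count(skel)
  out <- matrix("", nrow(skel), ncol(skel))
  out[skel & b <= 1] <- "endpoint"
  out[skel & b == 2] <- "path"
  out[skel & b >= 3] <- "branch"
  out
}

#' Prune short skeleton spurs
#'
#' Removes branches that run from an endpoint to the nearest branch point
#' in fewer than `max_spur_px` pixels; such spurs carry no connectivity
#' information. Pruning is interleaved with re-thinning until the
#' skeleton stops changing, so the result is again a valid thin skeleton.
#' Components that contain no branch point (pure paths, loops, isolated
#' pixels) are never removed, so the component count is unchanged.
#'
#' @param skel logical skeleton matrix (a [zhang_suen_thin()] output).
#' @param max_spur_px spurs strictly shorter than this are removed.
#' @return A logical skeleton matrix.
#' @export
prune_skeleton <- function(skel, max_spur_px = 2) {
  stopifnot(is.logical(skel), max_spur_px >= 0)
  m <- skel
  repeat {
    pruned <- prune_once(m, max_spur_px)
    pruned <- zhang_suen_thin(pruned)
    if (identical(pruned, m)) break
    m <- pruned
  }
  m
}

# remove every endpoint-to-branch-point path shorter than max_spur_px;
# walks from each endpoint through degree-2 pixels and drops the walked
# pixels when a branch point is reached before the length limit
prune_once <- function(skel, max_spur_px) {
  if (max_spur_px <= 0 || !any(skel)) return(skel)
  b <- neighbour_count(skel)
  endpoints <- which(skel & b == 1)
  drop <- integer(0)
  for (e in endpoints) {
    path <- e
    prev <- -1L
    cur <- e
    repeat {
      if (length(path) >= max_spur_px) {  # long enough to keep
        path <- integer(0); break
      }
      nbrs <- pixel_neighbours(cur, skel)
      nbrs <- nbrs[nbrs != prev]
      if (length(nbrs) == 0) {            # isolated pixel / dead end
        path <- integer(0); break
      }
      nxt <- nbrs[1]
      if (length(nbrs) > 1 || b[nxt] >= 3) break  # junction: spur confirmed
      if (b[nxt] <= 1) {                  # pure path component: keep whole
        path <- integer(0); break
      }
      prev <- cur
      cur <- nxt
      path <- c(path, cur)
    }
    drop <- c(drop, path)
  }
  if (length(drop)) skel[unique(drop)] <- FALSE
  skel
}

#' Write / read a binary mask or skeleton as plain text
#'
#' PBM-style format: an optional `# <timestamp>` comment line, a
#' dimension line `<rows> <cols>`, then one line of space-separated
#' `0`/`1` per row.
#'
#' @param mask logical matrix (a [binarize()] or [zhang_suen_thin()]
#'   output).
#' @param path file path.
#' @param time optional timestamp written to the header.
#' @return `write_mask()` returns `path` invisibly; `read_mask()`
#'   returns the logical matrix with a `time` attribute when present.
#' @export
write_mask <- function(mask, path, time = attr(mask, "time")) {
  stopifnot(is.logical(mask))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(time)) writeLines(paste0("# ", format(time)), con)
  writeLines(paste(nrow(mask), ncol(mask)), con)
  writeLines(apply(mask, 1, function(r)
    paste(as.integer(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  time <- NULL
  if (length(lines) && startsWith(lines[1], "# ")) {
    time <- sub("^# ", "", lines[1])
    lines <- lines[-1]
  }
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  if (length(dims) != 2 || anyNA(dims)) {
    stop("not a mask file: bad dimension line in ", path)
  }
  body <- lines[-1]
  if (length(body) != dims[1]) {
    stop(sprintf("mask file has %d rows, header says %d",
                 length(body), dims[1]))
  }
  m <- do.call(rbind, lapply(strsplit(body, " "), as.integer))
  if (ncol(m) != dims[2] || !all(m %in% c(0L, 1L))) {
    stop("not a mask file: non-binary or ragged rows in ", path)
  }
  out <- m == 1L
  if (!is.null(time)) attr(out, "time") <- time
  out
}

# linear indices of foreground 8-neighbours of linear index p
pixel_neighbours <- function(p, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((p - 1L) %% nr) + 1L
  cc <- ((p - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- cc + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    q <- (c2 - 1L) * nr + r2
    if (mask[q]) out <- c(out, q)
  }
  out
}
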