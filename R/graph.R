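#' Skeleton graphs
#'
#' A `skeleton_graph` represents one frame's skeleton (or a temporal
#' combination of several) as a graph: nodes carry pixel coordinates and
#' a frame index, edges are tagged `intra` (consecutive retained pixels
#' on a skeleton path) or `temporal` (nearest-neighbour links between
#' consecutive frames).
#'
#' @param nodes data frame with columns `id`, `row`, `col`, `frame`.
#' @param edges data frame with columns `from`, `to`, `kind`.
#' @return An object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes = data.frame(id = integer(), row = integer(),
                                              col = integer(),
                                              frame = integer()),
                           edges = data.frame(from = integer(),
                                              to = integer(),
                                              kind = character())) {
  stopifnot(all(c("id", "row", "col", "frame") %in% names(nodes)),
            all(c("from", "to", "kind") %in% names(edges)))
  structure(list(nodes = nodes, edges = edges), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d node(s), %d edge(s) (%d intra, %d temporal), %d frame(s)\n",
    nrow(x$nodes), nrow(x$edges),
    sum(x$edges$kind == "intra"), sum(x$edges$kind == "temporal"),
    length(unique(x$nodes$frame))
  ))
  invisible(x)
}

# adjacency list (by position in `px`) of skeleton pixels
skeleton_adjacency <- function(skel, px) {
  lapply(seq_len(nrow(px)), function(i) {
    dr <- abs(px$row - px$row[i])
    dc <- abs(px$col - px$col[i])
    which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
  })
}

#' Convert a skeleton to a graph by path subsampling
#'
#' Nodes are all endpoints and branch points of the skeleton plus every
#' `stride`-th pixel along each path between them (path ends are always
#' retained); an edge joins two nodes exactly when they are consecutive
#' retained pixels on the same skeleton path. Connected components of the
#' graph therefore equal connected components of the full-resolution
#' skeleton. Pure cycles (no endpoint or branch point) are traced from
#' their lexicographically smallest pixel.
#'
#' @param skel logical skeleton matrix.
#' @param stride subsampling stride along paths (>= 1).
#' @param frame frame index stored on the nodes.
#' @return A [skeleton_graph()].
#' @examples
#' m <- matrix(FALSE, 5, 12); m[3, 2:9] <- TRUE
#' skeleton_to_graph(m, stride = 2)
#' @export
skeleton_to_graph <- function(skel, stride = 2, frame = 1L) {
  stopifnot(is.logical(skel), stride >= 1)
  stride <- as.integer(stride)
  idx <- which(skel)
  if (length(idx) == 0) return(skeleton_graph())
  nr <- nrow(skel)
  px <- data.frame(
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L
  )
  # deterministic pixel order: row-major (row, then col)
  ord <- order(px$row, px$col)
  px <- px[ord, ]
  adj <- skeleton_adjacency(skel, px)
  deg <- lengths(adj)
  n <- nrow(px)

  keep <- logical(n)          # pixels retained as nodes
  seg_from <- integer(0)      # edges between retained pixels (positions)
  seg_to <- integer(0)
  edge_used <- matrix(FALSE, n, n)  # undirected pixel-adjacency already walked

  trace_path <- function(start, nxt) {
    # walk from a retained pixel `start` through degree-2 pixels,
    # retaining every stride-th pixel and the terminal pixel
    path <- c(start, nxt)
    while (deg[path[length(path)]] == 2 &&
           !(length(path) > 1 && path[length(path)] == start)) {
      cur <- path[length(path)]
      prev <- path[length(path) - 1]
      nxt2 <- setdiff(adj[[cur]], prev)
      if (length(nxt2) == 0) break
      path <- c(path, nxt2[1])
    }
    path
  }

  retain_along <- function(path) {
    # mark retained pixels and segment edges along one traced path
    m <- length(path)
    pos <- unique(c(seq(1, m, by = stride), m))
    for (k in seq_along(pos)) keep[path[pos[k]]] <<- TRUE
    for (k in seq_len(length(pos) - 1)) {
      seg_from <<- c(seg_from, path[pos[k]])
      seg_to <<- c(seg_to, path[pos[k + 1]])
    }
    for (k in seq_len(m - 1)) {
      edge_used[path[k], path[k + 1]] <<- TRUE
      edge_used[path[k + 1], path[k]] <<- TRUE
    }
  }

  anchors <- which(deg != 2)            # endpoints, branch points, isolated
  keep[anchors] <- TRUE
  for (a in anchors) {
    for (nb in adj[[a]]) {
      if (edge_used[a, nb]) next
      retain_along(trace_path(a, nb))
    }
  }
  # pure cycles: all pixels degree 2 and not yet visited
  visited <- keep | apply(edge_used, 1, any)
  for (s in seq_len(n)) {
    if (visited[s] || deg[s] != 2) next
    path <- trace_path(s, adj[[s]][1])
    retain_along(path)
    visited[path] <- TRUE
    visited <- visited | apply(edge_used, 1, any)
  }

  node_pos <- which(keep)
  id_of <- integer(n)
  id_of[node_pos] <- seq_along(node_pos)
  nodes <- data.frame(
    id = seq_along(node_pos),
    row = px$row[node_pos],
    col = px$col[node_pos],
    frame = as.integer(frame)
  )
  if (length(seg_from)) {
    e <- unique(data.frame(
      from = pmin(id_of[seg_from], id_of[seg_to]),
      to = pmax(id_of[seg_from], id_of[seg_to])
    ))
    e <- e[e$from != e$to, , drop = FALSE]
    edges <- data.frame(from = e$from, to = e$to,
                        kind = rep("intra", nrow(e)))
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        kind = character())
  }
  skeleton_graph(nodes, edges)
}

#' Combine per-frame graphs into one spatiotemporal graph
#'
#' Takes the node-disjoint union of a window of per-frame graphs and adds
#' one temporal edge from every node in frame *t* to its nearest node (in
#' Euclidean pixel distance) in frame *t+1*, when that frame is
#' non-empty. Ties break deterministically toward the smaller row, then
#' the smaller column.
#'
#' @param graphs list of [skeleton_graph()]s, one per frame, in time
#'   order.
#' @param window number of leading graphs to combine (default: all).
#' @return A single [skeleton_graph()] whose node `frame` column is the
#'   position of the source graph within the window.
#' @export
link_temporal <- function(graphs, window = length(graphs)) {
  stopifnot(window >= 1, window <= length(graphs))
  graphs <- graphs[seq_len(window)]
  offset <- 0L
  all_nodes <- list(); all_edges <- list()
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$nodes) == 0) next
    nd <- g$nodes
    nd$id <- nd$id + offset
    nd$frame <- i
    all_nodes[[length(all_nodes) + 1]] <- nd
    if (nrow(g$edges)) {
      ed <- g$edges
      ed$from <- ed$from + offset
      ed$to <- ed$to + offset
      all_edges[[length(all_edges) + 1]] <- ed
    }
    offset <- offset + nrow(g$nodes)
  }
  if (length(all_nodes) == 0) return(skeleton_graph())
  nodes <- do.call(rbind, all_nodes)
  edges <- if (length(all_edges)) do.call(rbind, all_edges) else
    data.frame(from = integer(), to = integer(), kind = character())
  # forward nearest-neighbour temporal links between consecutive frames
  for (i in seq_len(length(graphs) - 1)) {
    a <- nodes[nodes$frame == i, ]
    b <- nodes[nodes$frame == i + 1, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    ord <- order(b$row, b$col)   # tie-break: smaller row, then smaller col
    b <- b[ord, ]
    tos <- vapply(seq_len(nrow(a)), function(j) {
      d2 <- (b$row - a$row[j])^2 + (b$col - a$col[j])^2
      b$id[which.min(d2)]
    }, integer(1))
    edges <- rbind(edges, data.frame(from = a$id, to = tos,
                                     kind = "temporal"))
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  skeleton_graph(nodes, edges)
}

#' Frame-to-graph processing of a stream with sliding windows
#'
#' Runs the per-frame chain binarize -> clean -> thin -> prune ->
#' subsampled graph, then combines each sliding window of frames into one
#' spatiotemporal graph. Windows whose frames are all empty (no
#' foreground anywhere) are skipped.
#'
#' @param stream a 2D [thermal_stream()].
#' @param window_len window length in frames.
#' @param hop hop between window starts in frames.
#' @param threshold fixed binarization threshold, deg C.
#' @param mode binarization mode, `"fixed"` or `"otsu"`.
#' @param min_component_px small-component removal limit.
#' @param max_spur_px spur pruning limit.
#' @param stride graph subsampling stride.
#' @return A list with `graphs` (one combined [skeleton_graph()] per
#'   non-empty window) and `starts` (start frame index of each).
#' @export
window_stream <- function(stream, window_len = 24, hop = 8,
                          threshold = 28, mode = "fixed",
                          min_component_px = 3, max_spur_px = 2,
                          stride = 2) {
  stopifnot(inherits(stream, "thermal_stream"),
            window_len >= 1, hop >= 1)
  n <- length(stream$frames)
  per_frame <- lapply(seq_len(n), function(i) {
    sk <- prune_skeleton(
      zhang_suen_thin(clean_mask(
        binarize(stream$frames[[i]], mode = mode, threshold = threshold),
        min_component_px
      )),
      max_spur_px
    )
    skeleton_to_graph(sk, stride = stride, frame = i)
  })
  starts <- seq(1, max(1, n - window_len + 1), by = hop)
  graphs <- list(); kept_starts <- integer(0)
  for (s in starts) {
    idx <- s:min(s + window_len - 1, n)
    if (all(vapply(per_frame[idx], function(g) nrow(g$nodes) == 0,
                   logical(1)))) {
      next
    }
    graphs[[length(graphs) + 1]] <- link_temporal(per_frame[idx])
    kept_starts <- c(kept_starts, s)
  }
  list(graphs = graphs, starts = kept_starts)
}

#' Write / read a skeleton graph as an edge-list text file
#'
#' Plain-text format: a header line `# nodes: id row col frame`, one line
#' per node, a `# edges: from to kind` line, then one line per edge.
#'
#' @param g a [skeleton_graph()].
#' @param path file path.
#' @return `write_graph()` returns `path` invisibly; `read_graph()`
#'   returns a [skeleton_graph()].
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "skeleton_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodes: id row col frame", con)
  if (nrow(g$nodes)) {
    writeLines(sprintf("%d %d %d %d", g$nodes$id, g$nodes$row,
                       g$nodes$col, g$nodes$frame), con)
  }
  writeLines("# edges: from to kind", con)
  if (nrow(g$edges)) {
    writeLines(sprintf("%d %d %s", g$edges$from, g$edges$to,
                       g$edges$kind), con)
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  sep <- which(startsWith(lines, "# edges:"))
  if (length(sep) != 1 || !startsWith(lines[1], "# nodes:")) {
    stop("not a skeleton graph file: ", path)
  }
  node_lines <- lines[seq(2, sep - 1, length.out = max(0, sep - 2))]
  edge_lines <- if (sep < length(lines)) lines[(sep + 1):length(lines)] else
    character(0)
  nodes <- if (length(node_lines)) {
    m <- do.call(rbind, strsplit(node_lines, " "))
    data.frame(id = as.integer(m[, 1]), row = as.integer(m[, 2]),
               col = as.integer(m[, 3]), frame = as.integer(m[, 4]))
  } else {
    data.frame(id = integer(), row = integer(), col = integer(),
               frame = integer())
  }
  edges <- if (length(edge_lines)) {
    m <- do.call(rbind, strsplit(edge_lines, " "))
    data.frame(from = as.integer(m[, 1]), to = as.integer(m[, 2]),
               kind = m[, 3])
  } else {
    data.frame(from = integer(), to = integer(), kind = character())
  }
  skeleton_graph(nodes, edges)
}
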