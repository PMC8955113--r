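graph_components <- function(g) {
  n <- nrow(g$nodes)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- find(g$edges$from[r]); b <- find(g$edges$to[r])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

test_that("an empty skeleton yields an empty graph", {
  g <- skeleton_to_graph(matrix(FALSE, 6, 6))
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("a straight path is subsampled with both endpoints retained", {
  m <- matrix(FALSE, 5, 12)
  m[3, 2:9] <- TRUE  # 8-pixel path
  g <- skeleton_to_graph(m, stride = 2)
  # retained positions along the path: 0, 2, 4, 6 and the terminal 7
  expect_equal(sort(g$nodes$col), 2 + c(0, 2, 4, 6, 7))
  expect_equal(nrow(g$edges), 4)
  expect_true(all(g$edges$kind == "intra"))
  expect_equal(graph_components(g), 1)
})

test_that("graph components mirror skeleton components", {
  m <- matrix(FALSE, 8, 12)
  m[2, 2:6] <- TRUE
  m[6, 4:10] <- TRUE
  g <- skeleton_to_graph(m, stride = 2)
  expect_equal(graph_components(g), 2)

  # stride larger than the path still keeps the component connected
  g3 <- skeleton_to_graph(m, stride = 10)
  expect_equal(graph_components(g3), 2)

  # branch points become nodes: a cross keeps its centre
  cross <- matrix(FALSE, 9, 9)
  cross[5, 2:8] <- TRUE; cross[2:8, 5] <- TRUE
  gc <- skeleton_to_graph(cross, stride = 3)
  expect_true(any(gc$nodes$row == 5 & gc$nodes$col == 5))
  expect_equal(graph_components(gc), 1)
})

test_that("a closed loop stays a single closed component", {
  ring <- matrix(FALSE, 7, 7)
  ring[2, 2:6] <- TRUE; ring[6, 2:6] <- TRUE
  ring[2:6, 2] <- TRUE; ring[2:6, 6] <- TRUE
  g <- skeleton_to_graph(ring, stride = 3)
  expect_equal(graph_components(g), 1)
  # every node in a cycle has degree 2
  deg <- table(factor(c(g$edges$from, g$edges$to),
                      levels = g$nodes$id))
  expect_true(all(deg == 2))
})

test_that("temporal linking unions nodes and adds forward NN edges", {
  g1 <- path_graph(3, row = 5L, col0 = 4L)
  # window of one graph: identity
  expect_identical(link_temporal(list(g1), 1)$nodes, g1$nodes)

  # stationary person over two frames: 6 nodes, 4 intra + 3 temporal
  comb <- link_temporal(list(g1, path_graph(3, row = 5L, col0 = 4L)))
  expect_equal(nrow(comb$nodes), 6)
  expect_equal(sum(comb$edges$kind == "intra"), 4)
  expect_equal(sum(comb$edges$kind == "temporal"), 3)
  # each temporal link lands on the node directly below (same position)
  tmp <- comb$edges[comb$edges$kind == "temporal", ]
  for (r in seq_len(nrow(tmp))) {
    a <- comb$nodes[comb$nodes$id == tmp$from[r], ]
    b <- comb$nodes[comb$nodes$id == tmp$to[r], ]
    expect_equal(c(a$row, a$col), c(b$row, b$col))
    expect_equal(b$frame - a$frame, 1)
  }

  # an empty middle frame breaks the temporal chain
  comb2 <- link_temporal(list(g1, skeleton_graph(), path_graph(3)))
  expect_equal(sum(comb2$edges$kind == "temporal"), 0)
  expect_equal(graph_components(comb2), 2)

  # all-empty window is a valid empty graph
  expect_equal(nrow(link_temporal(list(skeleton_graph()))$nodes), 0)
})

test_that("combined node and temporal edge counts follow the linking rule", {
  set.seed(51)
  cfg <- scene_config(seed = 52)
  st <- simulate_sequence(activity_script("fall"), cfg)
  per_frame <- lapply(1:10, function(i) {
    sk <- prune_skeleton(zhang_suen_thin(clean_mask(
      binarize(st$frames[[i]]), 3)), 2)
    skeleton_to_graph(sk, stride = 2, frame = i)
  })
  comb <- link_temporal(per_frame)
  counts <- vapply(per_frame, function(g) nrow(g$nodes), integer(1))
  expect_equal(nrow(comb$nodes), sum(counts))
  # one forward link per node whose successor frame is non-empty
  expected_temporal <- sum(counts[-10] * (counts[-1] > 0))
  expect_equal(sum(comb$edges$kind == "temporal"), expected_temporal)
})

test_that("graph construction is translation-equivariant and deterministic", {
  m <- matrix(FALSE, 14, 14)
  m[3:9, 4] <- TRUE; m[6, 4:9] <- TRUE
  g <- skeleton_to_graph(m, stride = 2)
  shifted <- matrix(FALSE, 14, 14)
  shifted[3:9 + 2, 4 + 3] <- TRUE; shifted[6 + 2, 4:9 + 3] <- TRUE
  g2 <- skeleton_to_graph(shifted, stride = 2)
  expect_equal(g2$nodes$row, g$nodes$row + 2)
  expect_equal(g2$nodes$col, g$nodes$col + 3)
  expect_identical(g2$edges, g$edges)

  expect_identical(skeleton_to_graph(m, 2), skeleton_to_graph(m, 2))
})

test_that("window_stream emits one combined graph per non-empty window", {
  cfg <- scene_config(seed = 53)
  st <- simulate_sequence(activity_script("fall"), cfg)  # 48 frames
  ws <- window_stream(st, window_len = 24, hop = 24)
  expect_equal(length(ws$graphs), 2)
  expect_equal(ws$starts, c(1, 25))

  # person-free stream: no windows at all
  bg <- simulate_background(scene_config(seed = 54), 48)
  expect_equal(length(window_stream(bg, 24, 24)$graphs), 0)
})

test_that("fall windows start vertically extended and end horizontal", {
  cfg <- scene_config(seed = 55)
  st <- simulate_sequence(activity_script("fall"), cfg)
  ws <- window_stream(st, window_len = 24, hop = 8)
  found <- FALSE
  for (g in ws$graphs) {
    early <- g$nodes[g$nodes$frame <= 4, ]
    late <- g$nodes[g$nodes$frame >= max(g$nodes$frame) - 3, ]
    if (nrow(early) > 2 && nrow(late) > 2) {
      tall <- diff(range(early$row)) > diff(range(early$col))
      wide <- diff(range(late$col)) > diff(range(late$row))
      if (tall && wide) found <- TRUE
    }
  }
  expect_true(found)
})

test_that("graph files round-trip through the edge-list format", {
  g <- link_temporal(list(path_graph(3), star_graph(3)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges$from, g$edges$from)
  expect_equal(g2$edges$kind, g$edges$kind)

  # empty graph round-trips too
  write_graph(skeleton_graph(), path)
  expect_equal(nrow(read_graph(path)$nodes), 0)
})
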