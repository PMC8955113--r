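# Shared fixtures, built once per test run and cached. The full study-
# scale corpus (120 falls / 120 non-falls from 10 subjects) is expensive,
# so every test that needs it goes through fall_corpus().

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# study-scale labeled corpus: dataset, window graphs, fitted embedding,
# cross-validated report and a fitted model sharing the same embedding
fall_corpus <- function() {
  fixture("fall_corpus", function() {
    ds <- build_dataset(seed = 0)
    wg <- window_graphs(ds)
    emb <- fit_embedding(wg$graphs, seed = 0)
    report <- cross_validate(wg$graphs, wg$labels, folds = 5, seed = 0,
                             embedding = emb)
    model <- fall_model(wg$graphs, wg$labels, seed = 0, embedding = emb)
    list(dataset = ds, graphs = wg$graphs, labels = wg$labels,
         embedding = emb, report = report, model = model)
  })
}

# small graph constructors used across graph/classifier tests
path_graph <- function(n, frame = 1L, row = 5L, col0 = 1L) {
  nodes <- data.frame(id = seq_len(n), row = row,
                      col = col0 + seq_len(n) - 1L, frame = frame)
  edges <- if (n > 1) {
    data.frame(from = seq_len(n - 1), to = 2:n, kind = "intra")
  } else {
    data.frame(from = integer(), to = integer(), kind = character())
  }
  skeleton_graph(nodes, edges)
}

star_graph <- function(n_leaves, frame = 1L) {
  nodes <- data.frame(id = seq_len(n_leaves + 1),
                      row = c(5L, rep(4L, n_leaves)),
                      col = c(5L, 5L + seq_len(n_leaves)),
                      frame = frame)
  edges <- data.frame(from = 1L, to = 1L + seq_len(n_leaves),
                      kind = "intra")
  skeleton_graph(nodes, edges)
}

triangle_graph <- function(frame = 1L) {
  skeleton_graph(
    data.frame(id = 1:3, row = c(1L, 2L, 2L), col = c(1L, 1L, 2L),
               frame = frame),
    data.frame(from = c(1L, 2L, 1L), to = c(2L, 3L, 3L), kind = "intra")
  )
}

# random small mask with a mix of blobs and speckle
random_mask <- function(nr, nc, p = 0.45) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# a stream whose frames are a constant matrix (shared object, cheap)
constant_stream <- function(n, value = 21, nr = 24, nc = 32, fps = 16) {
  fr <- matrix(value, nr, nc)
  thermal_stream(replicate(n, fr, simplify = FALSE),
                 times = (seq_len(n) - 1) / fps)
}
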