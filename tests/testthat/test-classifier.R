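test_that("WL documents capture structure and nothing else", {
  tri <- triangle_graph()
  d0 <- wl_document(tri, depth = 0)
  expect_length(d0, 3)
  expect_length(unique(d0), 1)  # uniform degree-2 labels, no iteration

  # isomorphic graphs (relabeled node ids) give identical documents
  tri2 <- skeleton_graph(
    data.frame(id = 1:3, row = c(2L, 1L, 2L), col = c(2L, 1L, 1L),
               frame = 1L),
    data.frame(from = c(3L, 1L, 3L), to = c(2L, 2L, 1L), kind = "intra")
  )
  expect_identical(sort(wl_document(tri, 2)), sort(wl_document(tri2, 2)))

  # translation changes nothing: coordinates are not features
  tri_shift <- tri
  tri_shift$nodes$row <- tri_shift$nodes$row + 7L
  tri_shift$nodes$col <- tri_shift$nodes$col + 3L
  expect_identical(wl_document(tri_shift, 3), wl_document(tri, 3))

  # P3 and S3 have the same size but differ at depth 1
  p4 <- path_graph(4)
  s3 <- star_graph(3)
  expect_equal(length(wl_document(p4, 0)), length(wl_document(s3, 0)))
  expect_false(identical(sort(wl_document(p4, 1)),
                         sort(wl_document(s3, 1))))

  # document size is n_nodes * (depth + 1)
  expect_length(wl_document(p4, 3), 4 * 4)
  expect_length(wl_document(skeleton_graph(), 3), 0)
})

test_that("the embedding has k dimensions and is seed-deterministic", {
  graphs <- c(lapply(3:6, path_graph), lapply(2:5, star_graph))
  e1 <- fit_embedding(graphs, k = 30, epochs = 50, seed = 7)
  expect_equal(dim(e1$vectors), c(8, 30))
  e2 <- fit_embedding(graphs, k = 30, epochs = 50, seed = 7)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- fit_embedding(graphs, k = 30, epochs = 50, seed = 8)
  expect_false(identical(e1$vectors, e3$vectors))

  expect_error(fit_embedding(graphs[1]), "at least 2")
  expect_error(fit_embedding(graphs, k = 0), "k")
})

test_that("duplicate graphs embed closer than structurally different ones", {
  graphs <- list(path_graph(8), path_graph(8), star_graph(7))
  emb <- fit_embedding(graphs, k = 8, epochs = 800, seed = 1)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  v <- emb$vectors
  expect_gt(cos(v[1, ], v[2, ]), cos(v[1, ], v[3, ]))
  expect_gt(cos(v[1, ], v[2, ]), cos(v[2, ], v[3, ]))
})

test_that("embedding is invariant to node relabeling and translation", {
  corpus <- fall_corpus()
  g <- corpus$graphs[[1]]
  # relabel node ids (reverse the id space) and translate coordinates
  g2 <- g
  map <- rev(seq_len(nrow(g$nodes)))
  g2$nodes <- data.frame(id = map[g$nodes$id], row = g$nodes$row + 3L,
                         col = g$nodes$col + 2L, frame = g$nodes$frame)
  g2$nodes <- g2$nodes[order(g2$nodes$id), ]
  g2$edges <- data.frame(from = map[g$edges$from], to = map[g$edges$to],
                         kind = g$edges$kind)
  expect_identical(sort(wl_document(g2, 3)), sort(wl_document(g, 3)))
  emb <- corpus$embedding
  expect_equal(embed_graphs(emb, list(g)), embed_graphs(emb, list(g2)))
})

test_that("evaluation metrics satisfy their confusion-count identities", {
  m <- metrics_from_counts(tp = 109, fp = 11, tn = 109, fn = 11)
  expect_equal(m$precision, 100 * 109 / 120, tolerance = 1e-10)
  expect_equal(m$sensitivity, 90.83, tolerance = 1e-3)
  expect_equal(m$specificity, 90.83, tolerance = 1e-3)

  perfect <- metrics_from_counts(120, 0, 120, 0)
  expect_equal(unlist(perfect[c("precision", "sensitivity",
                                "specificity")]),
               c(precision = 100, sensitivity = 100, specificity = 100))

  # an all-positive predictor on balanced data
  allpos <- metrics_from_counts(120, 120, 0, 0)
  expect_equal(allpos$sensitivity, 100)
  expect_equal(allpos$specificity, 0)

  # identities recomputed on a real report
  rep <- fall_corpus()$report
  expect_equal(rep$precision, 100 * rep$tp / (rep$tp + rep$fp))
  expect_equal(rep$sensitivity, 100 * rep$tp / (rep$tp + rep$fn))
  expect_equal(rep$specificity, 100 * rep$tn / (rep$tn + rep$fp))
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, length(rep$labels))
})

test_that("a forest separates linearly separable toy embeddings", {
  set.seed(61)
  x <- rbind(matrix(rnorm(100, -2), 50), matrix(rnorm(100, 2), 50))
  y <- factor(rep(c("non_fall", "fall"), each = 50),
              levels = c("non_fall", "fall"))
  rf <- randomForest::randomForest(x = x, y = y, ntree = 100)
  expect_equal(mean(predict(rf, x) == y), 1)
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  corpus <- fall_corpus()
  rep1 <- cross_validate(corpus$graphs, corpus$labels, folds = 5,
                         seed = 0, embedding = corpus$embedding)
  rep2 <- cross_validate(corpus$graphs, corpus$labels, folds = 5,
                         seed = 0, embedding = corpus$embedding)
  expect_identical(rep1$predictions, rep2$predictions)
  # both classes in every fold
  tab <- table(rep1$fold_of, corpus$labels)
  expect_true(all(tab > 0))

  expect_error(cross_validate(corpus$graphs, corpus$labels, folds = 1),
               "folds")
})

test_that("shuffled labels drive cross-validated accuracy to chance", {
  corpus <- fall_corpus()
  set.seed(99)
  shuffled <- sample(corpus$labels)
  repn <- cross_validate(corpus$graphs, shuffled, folds = 5, seed = 0,
                         embedding = corpus$embedding)
  expect_gt(repn$accuracy, 40)
  expect_lt(repn$accuracy, 60)
})

test_that("the fitted fall model predicts and prints", {
  corpus <- fall_corpus()
  model <- corpus$model
  expect_s3_class(model, "fall_model")
  expect_output(print(model), "out-of-bag", ignore.case = TRUE)

  # predictions on embedding rows reproduce the training labels well
  pred <- predict(model, corpus$embedding$vectors)
  expect_gt(mean(pred == corpus$labels), 0.95)
  prob <- predict(model, corpus$embedding$vectors, type = "prob")
  expect_true(all(prob >= 0 & prob <= 1))

  # single-class labels refuse to train
  expect_error(fall_model(corpus$graphs[1:5], rep("fall", 5)),
               "both classes")
})

test_that("grid search reports every k and picks the best", {
  graphs <- c(lapply(3:8, path_graph), lapply(2:7, star_graph))
  labels <- rep(c("non_fall", "fall"), each = 6)
  gs <- grid_search_k(graphs, labels, k_grid = c(4, 8), folds = 2,
                      epochs = 50, n_trees = 50, seed = 1)
  expect_equal(gs$scores$k, c(4, 8))
  expect_true(all(is.finite(gs$scores$accuracy)))
  expect_true(gs$best_k %in% c(4, 8))
  expect_equal(gs$scores$accuracy[gs$scores$k == gs$best_k],
               max(gs$scores$accuracy))

  gs1 <- grid_search_k(graphs, labels, k_grid = 30, folds = 2,
                       epochs = 50, n_trees = 50, seed = 1)
  expect_equal(gs1$best_k, 30)
})

test_that("model bundles round-trip through the plain-text format", {
  graphs <- c(lapply(3:8, path_graph), lapply(2:7, star_graph))
  labels <- rep(c("non_fall", "fall"), each = 6)
  model <- fall_model(graphs, labels, k = 8, epochs = 60, n_trees = 50,
                      seed = 2)
  dir <- withr::local_tempdir()
  save_fall_model(model, dir)
  expect_true(all(file.exists(file.path(
    dir, c("manifest.json", "vocab.txt", "word_vectors.csv",
           "counts.csv", "graph_vectors.csv")))))
  loaded <- load_fall_model(dir)
  expect_identical(loaded$embedding$vectors, model$embedding$vectors)
  expect_identical(loaded$embedding$vocab, model$embedding$vocab)
  # the refitted forest reproduces the saved model's predictions
  expect_identical(predict(loaded, model$embedding$vectors),
                   predict(model, model$embedding$vectors))
  probe <- list(path_graph(5), star_graph(4))
  expect_equal(predict(loaded, probe, type = "prob"),
               predict(model, probe, type = "prob"))

  expect_error(load_fall_model(withr::local_tempdir()))
})

test_that("alerts carry the protocol fields and respect time order", {
  expect_null(emit_alert(10, 12, "non_fall", clock = 13))
  al <- emit_alert(10, 12, "fall", clock = 13)
  expect_s3_class(al, "fall_alert")
  expect_lte(al$start, al$end)
  expect_lte(al$end, al$notification)
  expect_named(al, c("recipient", "responded", "start", "end",
                     "notification", "comment"))
  expect_error(emit_alert(10, 12, "fall", clock = 9), "precedes")

  # NDJSON log accumulates one line per alert, ordered by start
  log <- withr::local_tempfile(fileext = ".ndjson")
  emit_alert(10, 12, "fall", clock = 13, log_path = log)
  emit_alert(20, 22, "fall", clock = 23, log_path = log)
  lines <- readLines(log)
  expect_length(lines, 2)
  starts <- vapply(lines, function(l) jsonlite::fromJSON(l)$start,
                   numeric(1), USE.NAMES = FALSE)
  expect_equal(starts, c(10, 20))
})
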