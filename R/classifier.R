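#' Weisfeiler-Lehman subtree document of a graph
#'
#' Iteratively refines node labels: the initial label is the node's
#' degree bucket (0, 1, 2, 3+; purely structural, so the document is
#' invariant to node relabeling and to translating pixel coordinates),
#' and each iteration replaces a label with its own label joined to the
#' sorted multiset of neighbour labels. The document is the multiset of
#' all labels over iterations `0..depth`, each prefixed with its
#' iteration index; isomorphic graphs yield identical documents.
#'
#' @param g a [skeleton_graph()].
#' @param depth number of WL iterations (>= 0).
#' @return Character vector of `n_nodes * (depth + 1)` labels (empty for
#'   an empty graph).
#' @export
wl_document <- function(g, depth = 3) {
  stopifnot(inherits(g, "skeleton_graph"), depth >= 0)
  n <- nrow(g$nodes)
  if (n == 0) return(character(0))
  adj <- vector("list", n)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      a <- g$edges$from[i]; b <- g$edges$to[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  deg <- lengths(adj)
  lab <- paste0("d", pmin(deg, 3L))
  doc <- paste0("0:", lab)
  it <- 0L
  while (it < depth) {
    it <- it + 1L
    lab <- vapply(seq_len(n), function(i) {
      nb <- sort(lab[adj[[i]]], method = "radix")
      paste0(lab[i], "(", paste(nb, collapse = ","), ")")
    }, character(1))
    doc <- c(doc, paste0(it, ":", lab))
  }
  doc
}

#' Fit a Graph2Vec-style embedding of a graph set
#'
#' Treats each graph's Weisfeiler-Lehman subtree label multiset as a
#' document and trains one k-dimensional vector per graph PV-DBOW style
#' (the document vector predicts its labels against negative samples
#' drawn from the label unigram distribution). Training is
#' single-threaded and deterministic in `seed`.
#'
#' @param graphs list of [skeleton_graph()]s (>= 2).
#' @param k embedding dimension (default 30, selected by grid search in
#'   this pipeline's design).
#' @param depth WL iterations (default 3).
#' @param epochs training epochs (default 200).
#' @param lr initial learning rate, decayed linearly (default 0.05).
#' @param negative negative samples per positive (default 5).
#' @param seed integer seed.
#' @return An object of class `graph_embedding`: list with `vectors`
#'   (n_graphs x k matrix), `word_vectors`, `vocab`, `counts` and the
#'   hyperparameters.
#' @export
fit_embedding <- function(graphs, k = 30, depth = 3, epochs = 200,
                          lr = 0.05, negative = 5, seed = 0) {
  if (length(graphs) < 2) stop("need at least 2 graphs to embed")
  if (k < 1) stop("`k` must be >= 1")
  docs <- lapply(graphs, wl_document, depth = depth)
  vocab <- unique(unlist(docs, use.names = FALSE))
  if (length(vocab) == 0) stop("all graphs are empty; nothing to embed")
  # documents are multisets: canonical (sorted) token order makes the
  # fit independent of node enumeration order
  tokens <- lapply(docs, function(d) sort(match(d, vocab) - 1L))
  fit <- pvdbow_train_cpp(tokens, length(vocab), as.integer(k),
                          as.integer(epochs), lr, as.integer(negative),
                          as.integer(seed))
  structure(
    list(vectors = fit$doc_vectors, word_vectors = fit$word_vectors,
         vocab = vocab, counts = fit$counts,
         k = as.integer(k), depth = as.integer(depth),
         epochs = as.integer(epochs), lr = lr,
         negative = as.integer(negative), seed = as.integer(seed)),
    class = "graph_embedding"
  )
}

#' @export
print.graph_embedding <- function(x, ...) {
  cat(sprintf(
    "<graph_embedding> %d graph(s) x k=%d, vocab %d WL label(s), depth %d\n",
    nrow(x$vectors), x$k, length(x$vocab), x$depth))
  invisible(x)
}

#' Embed graphs with a fitted embedding model
#'
#' Inference mode: WL labels of each new graph are matched against the
#' training vocabulary (unseen labels are dropped) and a fresh document
#' vector is trained against the frozen label vectors.
#'
#' @param object a `graph_embedding`.
#' @param graphs list of [skeleton_graph()]s.
#' @return Numeric matrix, one k-dimensional row per graph.
#' @export
embed_graphs <- function(object, graphs) {
  stopifnot(inherits(object, "graph_embedding"))
  out <- matrix(0, length(graphs), object$k)
  for (i in seq_along(graphs)) {
    doc <- wl_document(graphs[[i]], object$depth)
    tok <- match(doc, object$vocab)
    tok <- sort(tok[!is.na(tok)] - 1L)  # canonical multiset order
    out[i, ] <- pvdbow_infer_cpp(as.integer(tok), object$word_vectors,
                                 object$counts, object$epochs, object$lr,
                                 object$negative,
                                 object$seed + i)
  }
  out
}

#' Fit a fall / non-fall classifier on spatiotemporal skeleton graphs
#'
#' The core estimator of the fall-detection pipeline: embeds each
#' labeled window graph with a Graph2Vec-style WL-document embedding and
#' fits a random forest on the embedding vectors, with `fall` as the
#' positive class.
#'
#' @param graphs list of [skeleton_graph()]s, one per labeled window
#'   (e.g. from [window_graphs()]).
#' @param labels character or factor of `"fall"` / `"non_fall"` labels,
#'   one per graph; both classes must be present.
#' @param k,depth,epochs,lr,negative embedding hyperparameters, see
#'   [fit_embedding()].
#' @param n_trees random-forest size (default 200).
#' @param seed integer seed controlling embedding and forest.
#' @param embedding optionally, a prefitted `graph_embedding` for these
#'   graphs (skips refitting).
#' @return An object of class `fall_model` with `print`, `summary` and
#'   `predict` methods.
#' @seealso [cross_validate()] for the stratified evaluation,
#'   [grid_search_k()] for selecting `k`.
#' @export
fall_model <- function(graphs, labels, k = 30, depth = 3, epochs = 200,
                       lr = 0.05, negative = 5, n_trees = 200, seed = 0,
                       embedding = NULL) {
  labels <- factor(as.character(labels), levels = c("non_fall", "fall"))
  if (anyNA(labels)) stop("labels must be 'fall' or 'non_fall'")
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present to train the classifier")
  }
  stopifnot(length(graphs) == length(labels))
  emb <- if (is.null(embedding)) {
    fit_embedding(graphs, k = k, depth = depth, epochs = epochs,
                  lr = lr, negative = negative, seed = seed)
  } else {
    embedding
  }
  set.seed(seed)
  forest <- randomForest::randomForest(x = emb$vectors, y = labels,
                                       ntree = n_trees)
  structure(
    list(embedding = emb, forest = forest, labels = labels,
         n_trees = n_trees, seed = seed, threshold = 0.5,
         call = match.call()),
    class = "fall_model"
  )
}

#' @export
print.fall_model <- function(x, ...) {
  oob <- x$forest$err.rate[x$forest$ntree, "OOB"]
  cat("Fall / non-fall classifier on skeleton-graph embeddings\n")
  cat(sprintf("  windows: %d (%d fall, %d non-fall)\n", length(x$labels),
              sum(x$labels == "fall"), sum(x$labels == "non_fall")))
  cat(sprintf("  embedding: k=%d, WL depth %d | forest: %d trees\n",
              x$embedding$k, x$embedding$depth, x$n_trees))
  cat(sprintf("  out-of-bag error: %.1f%%\n", 100 * oob))
  invisible(x)
}

#' @export
summary.fall_model <- function(object, ...) {
  print(object)
  cat("\nOut-of-bag confusion matrix:\n")
  print(object$forest$confusion)
  invisible(object)
}

#' Predict fall / non-fall for new window graphs
#'
#' @param object a [fall_model()].
#' @param newdata list of [skeleton_graph()]s, or a precomputed embedding
#'   matrix with `k` columns.
#' @param type `"class"` for labels, `"prob"` for the fall-class score in
#'   `[0, 1]`.
#' @param ... unused.
#' @return Factor of predicted labels, or numeric fall probabilities.
#' @export
predict.fall_model <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  emb <- if (is.matrix(newdata)) newdata else
    embed_graphs(object$embedding, newdata)
  prob <- stats::predict(object$forest, emb, type = "prob")[, "fall"]
  if (type == "prob") return(unname(prob))
  factor(ifelse(prob > object$threshold, "fall", "non_fall"),
         levels = c("non_fall", "fall"))
}

# stratified fold assignment: within each class, cycle 1..folds over a
# seeded permutation
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Classification metrics from confusion counts
#'
#' Precision `100 TP/(TP+FP)`, sensitivity `100 TP/(TP+FN)` and
#' specificity `100 TN/(TN+FP)`, with `fall` the positive class.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return Named list of percentages plus accuracy.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  list(
    precision = 100 * tp / (tp + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn)
  )
}

#' Stratified cross-validated evaluation of the fall classifier
#'
#' Fits the unsupervised graph embedding once on all windows (labels play
#' no part in it), then evaluates the random forest by stratified k-fold
#' cross-validation on the embedding vectors: each fold's forest is
#' trained without the held-out windows and its predictions pooled into
#' one confusion matrix.
#'
#' @inheritParams fall_model
#' @param folds number of folds (>= 2), stratified so both classes occur
#'   in every fold.
#' @param embedding optionally, a prefitted `graph_embedding` for these
#'   graphs (skips refitting).
#' @return An object of class `fall_eval`: confusion counts, `precision`,
#'   `sensitivity`, `specificity`, `accuracy` (percent), per-window fold
#'   assignment and predictions.
#' @export
cross_validate <- function(graphs, labels, folds = 5, k = 30, depth = 3,
                           epochs = 200, lr = 0.05, negative = 5,
                           n_trees = 200, seed = 0, embedding = NULL) {
  labels <- factor(as.character(labels), levels = c("non_fall", "fall"))
  if (folds < 2) stop("`folds` must be >= 2")
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` windows for stratified CV")
  }
  emb <- if (is.null(embedding)) {
    fit_embedding(graphs, k = k, depth = depth, epochs = epochs, lr = lr,
                  negative = negative, seed = seed)
  } else {
    embedding
  }
  x <- emb$vectors
  fold_of <- stratified_folds(labels, folds, seed)
  pred <- factor(rep(NA_character_, length(labels)),
                 levels = c("non_fall", "fall"))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    set.seed(seed + f)
    rf <- randomForest::randomForest(x = x[tr, , drop = FALSE],
                                     y = labels[tr], ntree = n_trees)
    pred[!tr] <- stats::predict(rf, x[!tr, , drop = FALSE])
  }
  tp <- sum(pred == "fall" & labels == "fall")
  fp <- sum(pred == "fall" & labels == "non_fall")
  tn <- sum(pred == "non_fall" & labels == "non_fall")
  fn <- sum(pred == "non_fall" & labels == "fall")
  mets <- metrics_from_counts(tp, fp, tn, fn)
  structure(
    c(list(tp = tp, fp = fp, tn = tn, fn = fn, folds = folds,
           fold_of = fold_of, predictions = pred, labels = labels,
           seed = seed),
      mets),
    class = "fall_eval"
  )
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validated fall detection\n",
              x$folds))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  precision   %.1f%%\n", x$precision))
  cat(sprintf("  sensitivity %.1f%%\n", x$sensitivity))
  cat(sprintf("  specificity %.1f%%\n", x$specificity))
  invisible(x)
}

#' Grid search over the embedding dimension k
#'
#' Runs [cross_validate()] for each candidate `k` and returns the one
#' with the highest cross-validated accuracy (ties break toward the
#' smallest `k`).
#'
#' @inheritParams cross_validate
#' @param k_grid integer vector of candidate dimensions.
#' @return List with `best_k` and `scores` (data frame of k, accuracy,
#'   precision, sensitivity, specificity).
#' @export
grid_search_k <- function(graphs, labels, k_grid = c(5, 15, 30, 60),
                          folds = 5, depth = 3, epochs = 200, lr = 0.05,
                          negative = 5, n_trees = 200, seed = 0) {
  stopifnot(length(k_grid) >= 1)
  rows <- lapply(k_grid, function(kk) {
    ev <- cross_validate(graphs, labels, folds = folds, k = kk,
                         depth = depth, epochs = epochs, lr = lr,
                         negative = negative, n_trees = n_trees,
                         seed = seed)
    data.frame(k = kk, accuracy = ev$accuracy, precision = ev$precision,
               sensitivity = ev$sensitivity, specificity = ev$specificity)
  })
  scores <- do.call(rbind, rows)
  scores <- scores[order(scores$k), ]
  best_k <- scores$k[which.max(scores$accuracy)]  # first max = smallest k
  list(best_k = best_k, scores = scores)
}

#' Emit a fall alert for a classified window
#'
#' Builds the alert record of the notification protocol -- recipient and
#' response status, start and end timestamps of the potential fall, the
#' notification timestamp, and a free-text analyst comment -- and
#' optionally appends it to an NDJSON alert log. Nothing is emitted for a
#' non-fall prediction.
#'
#' @param window_start,window_end numeric window timestamps (seconds) or
#'   POSIXct.
#' @param prediction `"fall"` or `"non_fall"`.
#' @param clock the notification time; must not precede `window_start`.
#' @param recipient who receives the alert.
#' @param comment analyst comment.
#' @param log_path optional NDJSON file to append the alert to.
#' @return A `fall_alert` list, or `NULL` for a non-fall prediction.
#' @export
emit_alert <- function(window_start, window_end, prediction, clock,
                       recipient = "caregiver", comment = "",
                       log_path = NULL) {
  if (as.numeric(clock) < as.numeric(window_start)) {
    stop("notification clock precedes the window start")
  }
  if (as.character(prediction) != "fall") return(invisible(NULL))
  if (as.numeric(window_end) < as.numeric(window_start)) {
    stop("window end precedes window start")
  }
  alert <- structure(
    list(recipient = recipient, responded = NA,
         start = as.numeric(window_start), end = as.numeric(window_end),
         notification = as.numeric(clock), comment = comment),
    class = "fall_alert"
  )
  if (!is.null(log_path)) {
    line <- jsonlite::toJSON(unclass(alert), auto_unbox = TRUE,
                             null = "null", na = "null")
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  alert
}

#' Save / load a fall model as a plain-text bundle
#'
#' The bundle is a directory of text files: `manifest.json` (format
#' version, hyperparameters, seed, labels), `vocab.txt` (one WL label
#' per line), `word_vectors.csv`, `counts.csv` and `graph_vectors.csv`.
#' The random forest is not serialized; it is refitted deterministically
#' from the stored embedding vectors, labels and seed on load, so a
#' loaded model reproduces the saved model's predictions exactly.
#'
#' @param model a [fall_model()].
#' @param dir bundle directory (created if missing).
#' @return `save_fall_model()` returns `dir` invisibly;
#'   `load_fall_model()` returns a `fall_model`.
#' @export
save_fall_model <- function(model, dir) {
  stopifnot(inherits(model, "fall_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- model$embedding
  manifest <- list(
    format = "thermofall-model v1",
    k = emb$k, depth = emb$depth, epochs = emb$epochs, lr = emb$lr,
    negative = emb$negative, embed_seed = emb$seed,
    n_trees = model$n_trees, seed = model$seed,
    threshold = model$threshold,
    labels = as.character(model$labels)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(emb$vocab, file.path(dir, "vocab.txt"))
  write_matrix(emb$word_vectors, file.path(dir, "word_vectors.csv"))
  write_matrix(matrix(emb$counts, ncol = 1),
               file.path(dir, "counts.csv"))
  write_matrix(emb$vectors, file.path(dir, "graph_vectors.csv"))
  invisible(dir)
}

# exact (17-significant-digit) plain-text matrix round trip
write_matrix <- function(m, path) {
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), path)
}
read_matrix <- function(path) {
  do.call(rbind, lapply(strsplit(readLines(path), ",", fixed = TRUE),
                        as.numeric))
}

#' @rdname save_fall_model
#' @export
load_fall_model <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(mf$format, "thermofall-model v1")) {
    stop("not a thermofall model bundle: ", dir)
  }
  emb <- structure(
    list(
      vectors = read_matrix(file.path(dir, "graph_vectors.csv")),
      word_vectors = read_matrix(file.path(dir, "word_vectors.csv")),
      vocab = readLines(file.path(dir, "vocab.txt")),
      counts = as.numeric(read_matrix(file.path(dir, "counts.csv"))),
      k = mf$k, depth = mf$depth, epochs = mf$epochs, lr = mf$lr,
      negative = mf$negative, seed = mf$embed_seed
    ),
    class = "graph_embedding"
  )
  labels <- factor(mf$labels, levels = c("non_fall", "fall"))
  set.seed(mf$seed)
  forest <- randomForest::randomForest(x = emb$vectors, y = labels,
                                       ntree = mf$n_trees)
  structure(
    list(embedding = emb, forest = forest, labels = labels,
         n_trees = mf$n_trees, seed = mf$seed, threshold = mf$threshold,
         call = quote(load_fall_model(dir))),
    class = "fall_model"
  )
}

#' Detect falls in a frame stream with a fitted model
#'
#' Slides classification windows over the stream, predicts each combined
#' window graph, and emits one alert per window predicted as a fall.
#'
#' @param model a [fall_model()].
#' @param stream a 2D [thermal_stream()].
#' @param window_len,hop,threshold,stride see [window_stream()].
#' @param log_path optional NDJSON alert log.
#' @return Data frame of alerts (possibly 0 rows) with columns `start`,
#'   `end`, `notification`.
#' @export
detect_falls <- function(model, stream, window_len = 24, hop = 8,
                         threshold = 28, stride = 2, log_path = NULL) {
  ws <- window_stream(stream, window_len = window_len, hop = hop,
                      threshold = threshold, stride = stride)
  if (length(ws$graphs) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      notification = numeric()))
  }
  pred <- predict(model, ws$graphs)
  out <- list()
  for (i in seq_along(ws$graphs)) {
    if (pred[i] != "fall") next
    s <- ws$starts[i]
    e <- min(s + window_len - 1, length(stream$frames))
    al <- emit_alert(stream$times[s], stream$times[e], "fall",
                     clock = stream$times[e], log_path = log_path)
    out[[length(out) + 1]] <- data.frame(start = al$start, end = al$end,
                                         notification = al$notification)
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      notification = numeric()))
  }
  do.call(rbind, out)
}

#' Combined window graphs of a labeled dataset
#'
#' Convenience chain from a [build_dataset()] result to one
#' spatiotemporal graph per labeled window.
#'
#' @param dataset a `fall_dataset`.
#' @param threshold,mode,min_component_px,max_spur_px,stride see
#'   [window_stream()].
#' @return List with `graphs` and `labels` (character vector).
#' @export
window_graphs <- function(dataset, threshold = 28, mode = "fixed",
                          min_component_px = 3, max_spur_px = 2,
                          stride = 2) {
  stopifnot(inherits(dataset, "fall_dataset"))
  graphs <- lapply(dataset$windows, function(w) {
    n <- length(w$stream$frames)
    ws <- window_stream(w$stream, window_len = n, hop = n,
                        threshold = threshold, mode = mode,
                        min_component_px = min_component_px,
                        max_spur_px = max_spur_px, stride = stride)
    if (length(ws$graphs)) ws$graphs[[1]] else skeleton_graph()
  })
  list(graphs = graphs,
       labels = vapply(dataset$windows, `[[`, "", "label"))
}
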