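# Class-weighted supervised training of the edge scorer.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs maximum number of passes over the training graphs.
#' @param seed integer seed controlling initialization order, positional-
#'   encoding sign flips and partition growth; runs are bit-reproducible.
#' @param partition_count number of node-disjoint subgraphs each training
#'   graph is split into (one optimizer step per subgraph).
#' @param pos_weight positive-class weight in the BCE loss: `"auto"`
#'   (negative/positive count over the training set) or a fixed positive
#'   number.
#' @param patience early-stopping patience in epochs (validation loss).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, seed = 1L,
                         partition_count = 1L, pos_weight = "auto",
                         patience = 10L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (partition_count < 1L) stop("partition_count must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 partition_count = as.integer(partition_count),
                 pos_weight = pos_weight, patience = as.integer(patience)),
            class = "train_config")
}

#' Partition an assembly graph into node-disjoint subgraphs
#'
#' Seeded BFS-growing partitioner: regions of roughly equal node count are
#' grown breadth-first over the undirected adjacency, seeding each region at
#' the lowest-id unassigned node. Every node lands in exactly one part; each
#' subgraph keeps only its internal edges (cross-partition edges are
#' dropped, their count recorded in attribute `"cut_edges"`).
#'
#' @param graph an `assembly_graph`.
#' @param parts number of parts, `1 <= parts <= n_nodes(graph)`.
#' @return list of parts, each a list with `graph` (reindexed
#'   `assembly_graph`), `node_map` (global 0-based node id per new node) and
#'   `edge_map` (global 0-based edge id per new edge).
#' @export
partition_graph <- function(graph, parts) {
  m <- n_nodes(graph)
  if (parts > m) stop("parts must not exceed the number of nodes")
  if (parts < 1L) stop("parts must be >= 1")
  nbr <- vector("list", m)
  for (i in seq_len(n_edges(graph))) {
    s <- graph$edges$source[i] + 1L
    t <- graph$edges$target[i] + 1L
    nbr[[s]] <- c(nbr[[s]], t)
    nbr[[t]] <- c(nbr[[t]], s)
  }
  assign <- rep(NA_integer_, m)
  target <- ceiling(m / parts)
  for (p in seq_len(parts)) {
    remaining <- which(is.na(assign))
    if (!length(remaining)) break
    if (p == parts) {
      assign[remaining] <- p
      break
    }
    queue <- remaining[1L]
    size <- 0L
    while (size < target) {
      if (!length(queue)) {
        rem <- which(is.na(assign))
        if (!length(rem)) break
        queue <- rem[1L]
      }
      u <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(assign[u])) next
      assign[u] <- p
      size <- size + 1L
      nxt <- nbr[[u]]
      nxt <- nxt[is.na(assign[nxt])]
      queue <- c(queue, sort(nxt))
    }
  }
  cut <- 0L
  out <- vector("list", parts)
  for (p in seq_len(parts)) {
    nid <- which(assign == p)
    nodes <- graph$nodes[nid, , drop = FALSE]
    node_map <- nodes$node_id
    new_of <- rep(NA_integer_, m)
    new_of[nid] <- seq_along(nid) - 1L
    keep <- assign[graph$edges$source + 1L] == p &
      assign[graph$edges$target + 1L] == p
    e <- graph$edges[keep, , drop = FALSE]
    edge_map <- e$edge_id
    nodes$node_id <- seq_along(nid) - 1L
    e$source <- new_of[e$source + 1L]
    e$target <- new_of[e$target + 1L]
    out[[p]] <- list(graph = assembly_graph(nodes, e, sequences = graph$sequences),
                     node_map = node_map, edge_map = edge_map)
  }
  cut <- n_edges(graph) - sum(vapply(out, function(x) length(x$edge_map), integer(1)))
  attr(out, "cut_edges") <- cut
  out
}

#' Class-weighted binary cross-entropy
#'
#' Mean over edges of `-(w * y * log p + (1 - y) * log(1 - p))`. Predictions
#' exactly 0 or 1 are clipped to `1e-7` from the boundary.
#'
#' @param predictions numeric vector of probabilities in `(0, 1)`.
#' @param labels an `edge_labels` object or 0/1 vector aligned to
#'   `predictions`.
#' @param pos_weight positive-class weight `w` (auto mode of the trainer
#'   uses `negative_count / positive_count`).
#' @return scalar loss.
#' @export
weighted_bce <- function(predictions, labels, pos_weight = 1) {
  y <- if (inherits(labels, "edge_labels")) labels$labels else labels
  if (length(predictions) != length(y)) {
    stop("predictions and labels must be aligned")
  }
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  mean(-(pos_weight * y * log(p) + (1 - y) * log(1 - p)))
}

# ---- parameter-tree utilities (Adam) ----------------------------------

tree_zeros <- function(g) {
  if (is.list(g)) lapply(g, tree_zeros) else g * 0
}

tree_axpy <- function(a, b, f) {       # elementwise combine over grad tree
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_axpy(a[[nm]], b[[nm]], f)
    a
  } else f(a, b)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk(params, grads, state$m, state$v)
}

# ---- labeled-graph preparation ----------------------------------------

# positional encodings, zero-padded when the graph has too few nodes
pe_padded <- function(graph, k, normalized) {
  m <- n_nodes(graph)
  if (m <= 2L) return(matrix(0, m, k))
  kk <- min(k, m - 1L)
  pe <- laplacian_pe(graph, kk, normalized = normalized)
  if (kk < k) pe <- cbind(pe, matrix(0, m, k - kk))
  pe
}

#' Prepare a labeled graph for training or scoring
#'
#' Bundles the graph with its raw features, positional encodings and
#' (optionally) ground-truth edge labels.
#'
#' @param graph an `assembly_graph` with sequences.
#' @param reads coordinate-annotated reads for labeling, or `NULL` to skip
#'   labels (scoring only).
#' @param model_config a [gt_config()] (supplies `lappe_k` and the
#'   Laplacian flavour).
#' @return a `labeled_graph` list: `graph`, `features`, `pe`, `labels`.
#' @export
prepare_labeled_graph <- function(graph, reads = NULL,
                                  model_config = gt_config()) {
  features <- extract_features(graph)
  pe <- pe_padded(graph, model_config$lappe_k,
                  model_config$normalized_laplacian)
  labels <- if (!is.null(reads)) label_edges(graph, reads) else NULL
  structure(list(graph = graph, features = features, pe = pe,
                 labels = labels),
            class = "labeled_graph")
}

split_item <- function(item, parts, normalized = TRUE) {
  if (parts <= 1L || parts > n_nodes(item$graph)) return(list(item))
  subs <- partition_graph(item$graph, parts)
  lapply(subs, function(s) {
    lab <- NULL
    if (!is.null(item$labels)) {
      lv <- item$labels$labels[s$edge_map + 1L]
      lab <- structure(list(labels = lv, positive_count = sum(lv == 1L),
                            negative_count = sum(lv == 0L)),
                       class = "edge_labels")
    }
    structure(list(graph = s$graph,
                   features = list(
                     node_raw = item$features$node_raw[s$node_map + 1L, , drop = FALSE],
                     edge_raw = item$features$edge_raw[s$edge_map + 1L, , drop = FALSE]),
                   pe = pe_padded(s$graph, ncol(item$pe),
                                  normalized = normalized),
                   labels = lab),
              class = "labeled_graph")
  })
}

eval_items <- function(model, items, pos_weight) {
  preds <- numeric(0); ys <- integer(0)
  for (it in items) {
    sc <- score_edges(it$graph, it$features, model, pe = it$pe)
    preds <- c(preds, sc)
    ys <- c(ys, it$labels$labels)
  }
  loss <- weighted_bce(preds, ys, pos_weight)
  yhat <- as.integer(preds >= 0.5)
  acc <- mean(yhat == ys)
  tp <- sum(yhat == 1L & ys == 1L)
  fp <- sum(yhat == 1L & ys == 0L)
  fn <- sum(yhat == 0L & ys == 1L)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(loss = loss, accuracy = acc, f1 = f1)
}

#' Simulate one labeled training graph under the package's study conditions
#'
#' Convenience wrapper producing a `labeled_graph` from a fresh synthetic
#' genome. The defaults are the package's reference conditions for
#' label-recovery experiments: an error-free 50 kb genome at 12x coverage
#' with 3.5 +/- 2 kb reads and a 2.5 kb minimum overlap. The high overlap
#' threshold relative to the read length makes short reads regularly
#' dead-end into tips, so graphs carry a substantial minority (typically
#' 10--25 %) of negative one-sided edges alongside the positive backbone.
#'
#' @param seed integer seed (genome and reads derive from it).
#' @param genome_length,coverage,mean_length,length_sd,error_rate,min_overlap
#'   simulator settings, see [generate_genome()], [simulate_reads()] and
#'   [build_overlap_graph()].
#' @param model_config a [gt_config()] (for positional-encoding width).
#' @return a `labeled_graph` with the genome attached as attribute
#'   `"genome"` and the reads as `"reads"`.
#' @export
simulate_labeled_graph <- function(seed, genome_length = 50000L,
                                   coverage = 12, mean_length = 3500,
                                   length_sd = 2000, error_rate = 0,
                                   min_overlap = 2500L,
                                   model_config = gt_config()) {
  genome <- generate_genome(genome_length, 0, seed = seed)
  reads <- simulate_reads(genome, coverage, mean_length = mean_length,
                          length_sd = length_sd, error_rate = error_rate,
                          seed = seed + 1L)
  graph <- build_overlap_graph(reads, min_overlap = min_overlap)
  item <- prepare_labeled_graph(graph, reads, model_config)
  attr(item, "genome") <- genome
  attr(item, "reads") <- reads
  item
}

#' Train the graph-transformer edge scorer
#'
#' Full-batch Adam per subgraph with class-weighted binary cross-entropy.
#' Positional-encoding eigenvector signs are flipped randomly each step
#' during training. The checkpoint with the best validation loss is
#' retained; training is bit-reproducible given `config$seed`.
#'
#' @param train_items,val_items lists of `labeled_graph` objects (see
#'   [prepare_labeled_graph()]); labels required. At least one of each.
#' @param model_config a [gt_config()].
#' @param config a [train_config()].
#' @param verbose print per-epoch metrics.
#' @return list with `model` (best-validation `gt_model`), `final_model`,
#'   `metrics` (per-epoch data.frame), `pos_weight`, and `cut_edges`
#'   (edges dropped from the loss by partitioning).
#' @export
train_gt <- function(train_items, val_items, model_config = gt_config(),
                     config = train_config(), verbose = FALSE) {
  if (!length(train_items)) stop("at least one training graph required")
  if (!length(val_items)) stop("validation set must not be empty")
  if (any(vapply(c(train_items, val_items),
                 function(x) is.null(x$labels), logical(1)))) {
    stop("all graphs must carry edge labels")
  }
  set.seed(config$seed)
  model <- init_gt_model(model_config, seed = config$seed)

  steps <- unlist(lapply(train_items, split_item,
                         parts = config$partition_count,
                         normalized = model_config$normalized_laplacian),
                  recursive = FALSE)
  steps <- Filter(function(s) n_edges(s$graph) > 0L, steps)
  cut_edges <- sum(vapply(train_items, function(it) n_edges(it$graph), integer(1))) -
    sum(vapply(steps, function(s) n_edges(s$graph), integer(1)))

  pw <- config$pos_weight
  if (identical(pw, "auto")) {
    pos <- sum(vapply(steps, function(s) s$labels$positive_count, integer(1)))
    neg <- sum(vapply(steps, function(s) s$labels$negative_count, integer(1)))
    if (pos == 0L) stop("training set has no positive edges")
    pw <- max(neg, 1L) / pos
  }

  metrics <- data.frame()
  best_loss <- Inf
  best_params <- model$params
  adam <- NULL
  t <- 0L
  stale <- 0L

  for (epoch in seq_len(config$epochs)) {
    ep_loss <- 0
    for (s in steps) {
      signs <- sample(c(-1, 1), ncol(s$pe), replace = TRUE)
      pe <- sweep(s$pe, 2L, signs, "*")
      src1 <- s$graph$edges$source + 1L
      tgt1 <- s$graph$edges$target + 1L
      fw <- gt_forward(model, s$features$node_raw, s$features$edge_raw, pe,
                       src1, tgt1, training = TRUE)
      model$params <- fw$params_bn   # updated BatchNorm running stats
      y <- s$labels$labels
      z <- fw$logits
      p <- 1 / (1 + exp(-z))
      n <- length(z)
      loss <- mean(pw * y * log1p(exp(-z)) + (1 - y) * log1p(exp(z)))
      if (!is.finite(loss)) stop("non-finite training loss")
      dlogits <- (-pw * y * (1 - p) + (1 - y) * p) / n
      grads <- gt_backward(model, fw$cache, dlogits)
      if (is.null(adam)) {
        adam <- list(m = tree_zeros(grads), v = tree_zeros(grads))
      }
      t <- t + 1L
      upd <- adam_step(model$params, grads, adam, config$learning_rate, t)
      model$params <- upd$p
      adam$m <- upd$m
      adam$v <- upd$v
      ep_loss <- ep_loss + loss
    }
    ev <- eval_items(model, val_items, pw)
    metrics <- rbind(metrics, data.frame(
      epoch = epoch, train_loss = ep_loss / length(steps),
      val_loss = ev$loss, val_accuracy = ev$accuracy, val_f1 = ev$f1))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / length(steps), ev$loss, ev$accuracy))
    }
    if (ev$loss < best_loss - 1e-9) {
      best_loss <- ev$loss
      best_params <- model$params
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }

  best <- model
  best$params <- best_params
  list(model = best, final_model = model, metrics = metrics,
       pos_weight = pw, cut_edges = cut_edges)
}
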