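# Position-derived ground-truth edge labels. An edge is positive when it is
# traversed by both a forward BFS from the lowest-start node and a backward
# BFS from the highest-end node of the visited region; edges only reachable
# one way (tips, dead-end branches) are negative training examples.

node_read_index <- function(graph, reads) {
  idx <- match(graph$nodes$read_id, reads$read_id)
  if (anyNA(idx)) {
    stop("labeling error: node(s) without coordinate annotation: ",
         paste(head(graph$nodes$read_id[is.na(idx)], 3), collapse = ", "))
  }
  idx
}

#' Position-based edge retention mask
#'
#' An edge `A -> B` is retained when both reads lie on the same strand and
#' their true coordinates form a proper dovetail: `start(A) < start(B)`,
#' `end(A) > start(B)` and `end(B) > end(A)`. Everything else (strand
#' mismatches, containments, disjoint pairs) is masked out and will be
#' labeled negative.
#'
#' @param graph an `assembly_graph` over coordinate-annotated reads.
#' @param reads a `simulated_reads` data.frame carrying `start`, `end`,
#'   `strand` for every `read_id` in the graph.
#' @return logical vector, one entry per edge in `edge_id` order.
#' @export
retain_edges <- function(graph, reads) {
  idx <- node_read_index(graph, reads)
  s <- idx[graph$edges$source + 1L]
  t <- idx[graph$edges$target + 1L]
  reads$strand[s] == reads$strand[t] &
    reads$start[s] < reads$start[t] &
    reads$end[s] > reads$start[t] &
    reads$end[t] > reads$end[s]
}

# BFS over a subset of edges; returns visited-node logical vector and the
# ids of edges examined from visited nodes. adj: list of edge-id vectors per
# node (1-based list index), endpoint: for each edge, the node it leads to.
bfs_sweep <- function(seed_node, adj, endpoint) {
  m <- length(adj)
  visited <- logical(m)
  visited[seed_node + 1L] <- TRUE
  queue <- seed_node
  edges_seen <- integer(0)
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (e in adj[[u + 1L]]) {
      edges_seen <- c(edges_seen, e)
      v <- endpoint[e + 1L]
      if (!visited[v + 1L]) {
        visited[v + 1L] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  list(visited = visited, edges = edges_seen)
}

#' Label assembly-graph edges from read positions
#'
#' Repeats until every node has been swept: seed a forward BFS over retained
#' edges at the not-yet-visited node with the lowest start coordinate (ties
#' broken by `read_id`); from the visited node with the highest end
#' coordinate, run a backward BFS against edge direction. Edges traversed in
#' both sweeps are positive (label 1); edges seen in only one sweep, never
#' reached, or not retained are negative (label 0).
#'
#' @param graph an `assembly_graph`.
#' @param reads coordinate-annotated reads (see [retain_edges()]).
#' @param retained optional logical retention mask; computed with
#'   [retain_edges()] when missing.
#' @param highest one of `"end"` (default) or `"start"`: coordinate used to
#'   pick the backward-BFS seed among forward-visited nodes.
#' @return An `edge_labels` object: list with `labels` (integer 0/1 per
#'   edge), `positive_count`, `negative_count`.
#' @export
label_edges <- function(graph, reads, retained = NULL,
                        highest = c("end", "start")) {
  highest <- match.arg(highest)
  if (is.null(retained)) retained <- retain_edges(graph, reads)
  m <- n_nodes(graph)
  n <- n_edges(graph)
  idx <- node_read_index(graph, reads)
  node_start <- reads$start[idx]
  node_end <- reads$end[idx]
  node_read <- graph$nodes$read_id

  kept <- graph$edges[retained, , drop = FALSE]
  lev <- 0:(m - 1L)
  adj_out <- split(kept$edge_id, factor(kept$source, levels = lev))
  adj_in <- split(kept$edge_id, factor(kept$target, levels = lev))
  e_target <- integer(n); e_source <- integer(n)
  e_target[graph$edges$edge_id + 1L] <- graph$edges$target
  e_source[graph$edges$edge_id + 1L] <- graph$edges$source

  fwd <- logical(n)
  bwd <- logical(n)
  swept <- logical(m)
  while (!all(swept)) {
    open <- which(!swept) - 1L
    seed <- open[order(node_start[open + 1L], node_read[open + 1L])][1L]
    f <- bfs_sweep(seed, adj_out, e_target)
    fwd[f$edges + 1L] <- TRUE
    vis <- which(f$visited) - 1L
    pos <- if (highest == "end") node_end else node_start
    top <- vis[order(-pos[vis + 1L], node_read[vis + 1L])][1L]
    b <- bfs_sweep(top, adj_in, e_source)
    bwd[b$edges + 1L] <- TRUE
    swept <- swept | f$visited | b$visited
  }

  labels <- as.integer(retained & fwd & bwd)
  structure(list(labels = labels,
                 positive_count = sum(labels == 1L),
                 negative_count = sum(labels == 0L)),
            class = "edge_labels")
}

#' @export
print.edge_labels <- function(x, ...) {
  cat("edge_labels:", x$positive_count, "positive,",
      x$negative_count, "negative\n")
  invisible(x)
}

#' Positive-to-negative class balance of edge labels
#'
#' Used as the automatic positive-class weight during training; the
#' denominator is guarded so an all-positive graph yields a finite ratio.
#'
#' @param labels an `edge_labels` object.
#' @return `positive_count / max(negative_count, 1)`.
#' @export
class_balance <- function(labels) {
  total <- labels$positive_count + labels$negative_count
  if (total == 0L) stop("empty graph: no edges to balance")
  labels$positive_count / max(labels$negative_count, 1L)
}

#' Write edge labels as a two-column table
#' @param labels an `edge_labels` object
#' @param path output path (TSV: edge_id, label)
#' @return `path`, invisibly
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(edge_id = seq_along(labels$labels) - 1L, label = labels$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
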