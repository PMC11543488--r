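# Iterative N-start bidirectional greedy path search over the scored graph,
# and path-to-contig concatenation.

#' Greedily extend a path from a starting edge
#'
#' From the start edge, repeatedly move to the highest-scoring admissible
#' edge: forward extension follows out-edges of the current head, backward
#' extension follows in-edges of the current tail. Edges leading into
#' already-visited nodes (the `visited` set or nodes already on the path)
#' are skipped; ties are broken by lowest `edge_id`. Extension stops when no
#' admissible edge remains.
#'
#' @param graph an `assembly_graph`.
#' @param scores numeric per-edge scores in `edge_id` order.
#' @param start_edge 0-based `edge_id`; its endpoints must not be visited.
#' @param visited logical vector over nodes (`node_id + 1` indexing), or
#'   `NULL` for none.
#' @param direction `"forward"` or `"backward"`.
#' @return list with `nodes` and `edges` (0-based ids, path order; the
#'   start edge is included).
#' @export
greedy_extend <- function(graph, scores, start_edge, visited = NULL,
                          direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  m <- n_nodes(graph)
  if (is.null(visited)) visited <- logical(m)
  e <- graph$edges
  s0 <- e$source[start_edge + 1L]
  t0 <- e$target[start_edge + 1L]
  if (visited[s0 + 1L] || visited[t0 + 1L]) {
    stop("start edge endpoints must not be visited")
  }
  adj <- adjacency(graph)
  onpath <- logical(m)
  onpath[c(s0, t0) + 1L] <- TRUE
  nodes <- c(s0, t0)
  edges <- start_edge
  cur <- if (direction == "forward") t0 else s0
  repeat {
    cand <- if (direction == "forward") adj$out[[cur + 1L]] else adj$`in`[[cur + 1L]]
    if (length(cand)) {
      nxt <- if (direction == "forward") e$target[cand + 1L] else e$source[cand + 1L]
      ok <- !visited[nxt + 1L] & !onpath[nxt + 1L]
      cand <- cand[ok]
      nxt <- nxt[ok]
    }
    if (!length(cand)) break
    pick <- order(-scores[cand + 1L], cand)[1L]
    cur <- nxt[pick]
    onpath[cur + 1L] <- TRUE
    if (direction == "forward") {
      nodes <- c(nodes, cur)
      edges <- c(edges, cand[pick])
    } else {
      nodes <- c(cur, nodes)
      edges <- c(cand[pick], edges)
    }
  }
  list(nodes = nodes, edges = edges)
}

path_bases <- function(graph, path) {
  sum(graph$nodes$read_length[path$nodes + 1L]) -
    sum(graph$edges$overlap_length[path$edges + 1L])
}

#' Decode assembly paths from a scored graph
#'
#' Iterative greedy search: each round picks the `N` highest-scoring edges
#' whose endpoints are unvisited (ties resolved by seeded random
#' tie-breaking), extends each bidirectionally with [greedy_extend()], and
#' keeps the candidate whose implied contig (sum of read lengths minus sum
#' of overlaps) is longest. Only the winner's nodes are marked visited;
#' iteration stops when the best candidate has fewer than `min_path_reads`
#' nodes. Emitted paths are node-disjoint.
#'
#' @param graph an `assembly_graph`.
#' @param scores numeric per-edge scores, `edge_id` order.
#' @param N number of candidate starting edges per round.
#' @param min_path_reads stop once the best path has fewer reads than this.
#' @param seed integer seed for tie-breaking.
#' @return list of `assembly_path` objects (`nodes`, `edges`, `bases`).
#' @export
decode <- function(graph, scores, N = 16L, min_path_reads = 3L, seed = 1L) {
  if (N < 1L) stop("N must be >= 1")
  if (n_edges(graph) != length(scores)) {
    stop("scores must have one value per edge")
  }
  m <- n_nodes(graph)
  if (m == 0L || n_edges(graph) == 0L) return(list())
  set.seed(seed)
  tiebreak <- runif(n_edges(graph))
  visited <- logical(m)
  e <- graph$edges
  paths <- list()
  repeat {
    ok <- !visited[e$source + 1L] & !visited[e$target + 1L]
    if (!any(ok)) break
    cand_ids <- e$edge_id[ok]
    ord <- order(-scores[cand_ids + 1L], tiebreak[cand_ids + 1L])
    starts <- cand_ids[head(ord, N)]
    best <- NULL
    best_len <- -1L
    for (se in starts) {
      fwd <- greedy_extend(graph, scores, se, visited, "forward")
      # the backward sweep must not re-enter nodes the forward sweep took
      vis_b <- visited
      ends <- c(e$source[se + 1L], e$target[se + 1L])
      vis_b[setdiff(fwd$nodes, ends) + 1L] <- TRUE
      bwd <- greedy_extend(graph, scores, se, vis_b, "backward")
      # join: backward prefix + start edge + forward suffix (the start
      # edge's two nodes appear exactly once)
      path <- list(nodes = c(head(bwd$nodes, -2L), fwd$nodes),
                   edges = c(head(bwd$edges, -1L), fwd$edges))
      len <- path_bases(graph, path)
      if (len > best_len) {
        best <- path
        best_len <- len
      }
    }
    if (is.null(best) || length(best$nodes) < min_path_reads) break
    best$bases <- best_len
    class(best) <- "assembly_path"
    paths[[length(paths) + 1L]] <- best
    visited[best$nodes + 1L] <- TRUE
  }
  paths
}

#' Concatenate reads along assembly paths into contigs
#'
#' A contig is the first read's oriented sequence followed by each
#' subsequent read minus its `overlap_length` prefix. In error-free mode the
#' contig length is exactly the sum of read lengths minus the sum of
#' overlap lengths along the path.
#'
#' @param paths list of `assembly_path` objects from [decode()].
#' @param graph the `assembly_graph` the paths refer to.
#' @param read_sequences named character vector `read_id -> sequence`;
#'   defaults to the graph's stored sequences.
#' @return a `contig_set`: data.frame with `name`, `sequence`, `n_reads`,
#'   `length`, plus the node paths in attribute `"paths"`.
#' @export
paths_to_contigs <- function(paths, graph, read_sequences = graph$sequences) {
  seqs <- node_sequences(graph, read_sequences)
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    pieces <- seqs[p$nodes[1L] + 1L]
    if (length(p$nodes) > 1L) {
      for (j in seq_along(p$edges)) {
        nxt <- seqs[p$nodes[j + 1L] + 1L]
        ol <- graph$edges$overlap_length[p$edges[j] + 1L]
        if (ol >= nchar(nxt)) {
          stop("malformed path: overlap length >= next read length")
        }
        pieces <- c(pieces, substring(nxt, ol + 1L))
      }
    }
    paste(pieces, collapse = "")
  })
  contigs <- data.frame(
    name = sprintf("contig_%04d", seq_along(paths)),
    sequence = unlist(out, use.names = FALSE),
    n_reads = vapply(paths, function(p) length(p$nodes), integer(1)),
    stringsAsFactors = FALSE)
  contigs$length <- nchar(contigs$sequence)
  attr(contigs, "paths") <- paths
  class(contigs) <- c("contig_set", "data.frame")
  contigs
}

#' Write contigs to FASTA
#' @param contigs a `contig_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contig_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  names(ss) <- contigs$name
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
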