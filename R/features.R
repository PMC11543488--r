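# Raw node/edge features and their fully-connected embedding.
#
# Node feature vector: [out-degree, in-degree]. Edge feature vector:
# [overlap length, overlap similarity]. Both are lifted to dimension d by a
# 3-layer fully-connected map with ReLU between layers.

#' Overlap similarity of an edge
#'
#' `max(0, (overlap_length - edit_distance) / overlap_length)`: the fraction
#' of the overlap window not explained by edit operations, clamped to keep a
#' valid `[0, 1]` feature when the edit distance exceeds the overlap.
#'
#' @param overlap_length overlap length(s) in bp, strictly positive.
#' @param edit_distance non-negative Levenshtein distance(s) between the
#'   two overlap windows.
#' @return numeric vector in `[0, 1]`.
#' @export
overlap_similarity <- function(overlap_length, edit_distance) {
  if (any(overlap_length <= 0)) stop("overlap_length must be positive")
  if (any(edit_distance < 0)) stop("edit_distance must be non-negative")
  pmax(0, (overlap_length - edit_distance) / overlap_length)
}

#' Levenshtein distance between two strings
#'
#' Exact global edit distance (unit-cost substitution/insertion/deletion),
#' computed in C++. Vectorized over pairs.
#'
#' @param a,b character vectors of equal length.
#' @return integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  levenshtein_cpp(as.character(a), as.character(b))
}

#' Edit distance over an edge's overlap windows
#'
#' Compares the source node's oriented-sequence suffix of length
#' `overlap_length` against the target node's oriented-sequence prefix of
#' the same length, the two windows the suffix--prefix overlap claims to
#' align.
#'
#' @param graph an `assembly_graph`.
#' @param read_sequences named character vector `read_id -> sequence`;
#'   defaults to the sequences stored in the graph.
#' @param edge_ids 0-based edge ids to compute (default: all edges).
#' @return integer vector of Levenshtein distances aligned to `edge_ids`.
#' @export
edge_edit_distance <- function(graph, read_sequences = graph$sequences,
                               edge_ids = graph$edges$edge_id) {
  seqs <- node_sequences(graph, read_sequences)
  e <- graph$edges[match(edge_ids, graph$edges$edge_id), , drop = FALSE]
  src_seq <- seqs[e$source + 1L]
  tgt_seq <- seqs[e$target + 1L]
  if (any(nchar(src_seq) < e$overlap_length) ||
      any(nchar(tgt_seq) < e$overlap_length)) {
    stop("read sequence shorter than the edge overlap length")
  }
  suf <- substring(src_seq, nchar(src_seq) - e$overlap_length + 1L)
  pre <- substring(tgt_seq, 1L, e$overlap_length)
  edit_distance(suf, pre)
}

#' Extract raw node and edge features of an assembly graph
#'
#' @param graph an `assembly_graph`.
#' @param read_sequences sequences used for the overlap-similarity feature;
#'   when `NULL` and the graph stores none, similarity is set to 1 (exact
#'   overlaps assumed) with a message.
#' @return A `feature_set`: list with `node_raw` (m x 2 matrix: out-degree,
#'   in-degree) and `edge_raw` (n x 2 matrix: overlap length, overlap
#'   similarity), rows in `node_id` / `edge_id` order.
#' @export
extract_features <- function(graph, read_sequences = graph$sequences) {
  deg <- degrees(graph)
  node_raw <- cbind(out_degree = deg$out_degree, in_degree = deg$in_degree)
  ol <- graph$edges$overlap_length
  if (is.null(read_sequences)) {
    message("no read sequences: overlap similarity set to 1 for all edges")
    os <- rep(1, length(ol))
  } else {
    ed <- edge_edit_distance(graph, read_sequences)
    os <- if (length(ol)) overlap_similarity(ol, ed) else numeric(0)
  }
  structure(list(node_raw = node_raw,
                 edge_raw = cbind(overlap_length = as.numeric(ol),
                                  overlap_similarity = os)),
            class = "feature_set")
}

#' Initialize weights of the 3-layer feature embedding
#'
#' Three affine maps `d_in -> d -> d -> d` with ReLU after the first two,
#' He-initialized.
#'
#' @param d_in input feature width (2 for both node and edge features).
#' @param d embedding dimension (64 by default throughout the package).
#' @return list of `W1, b1, W2, b2, W3, b3`.
#' @export
init_embed_weights <- function(d_in, d = 64L) {
  he <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  list(W1 = he(d_in, d), b1 = numeric(d),
       W2 = he(d, d), b2 = numeric(d),
       W3 = he(d, d), b3 = numeric(d))
}

#' Embed raw features with a 3-layer fully-connected map
#'
#' Applied row-wise: `ReLU(ReLU(X W1 + b1) W2 + b2) W3 + b3`.
#'
#' @param raw numeric matrix (m x d_in), finite.
#' @param weights weights from [init_embed_weights()].
#' @return numeric matrix (m x d).
#' @export
embed_features <- function(raw, weights) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("raw features must be finite")
  h1 <- pmax(sweep(raw %*% weights$W1, 2L, weights$b1, "+"), 0)
  h2 <- pmax(sweep(h1 %*% weights$W2, 2L, weights$b2, "+"), 0)
  sweep(h2 %*% weights$W3, 2L, weights$b3, "+")
}

# forward with cache, for backprop
embed_forward <- function(raw, w) {
  z1 <- sweep(raw %*% w$W1, 2L, w$b1, "+"); a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% w$W2, 2L, w$b2, "+"); a2 <- pmax(z2, 0)
  out <- sweep(a2 %*% w$W3, 2L, w$b3, "+")
  list(out = out, cache = list(raw = raw, z1 = z1, a1 = a1, z2 = z2, a2 = a2))
}

embed_backward <- function(dout, w, cache) {
  dW3 <- t(cache$a2) %*% dout; db3 <- colSums(dout)
  da2 <- dout %*% t(w$W3)
  dz2 <- da2 * (cache$z2 > 0)
  dW2 <- t(cache$a1) %*% dz2; db2 <- colSums(dz2)
  da1 <- dz2 %*% t(w$W2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- t(cache$raw) %*% dz1; db1 <- colSums(dz1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3),
       din = dz1 %*% t(w$W1))
}
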