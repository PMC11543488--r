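# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal method available (quadratic DP, exhaustive
# scans, hand simulation) and never call the code paths they check.

# plain dynamic-programming Levenshtein, O(nm), no tricks
dp_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (av[i] != bv[j]),
                         prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random DAG over m nodes: edges only from lower to higher node id
random_dag <- function(m, p = 0.35, min_len = 40L) {
  pairs <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  lens <- sample(100:200, m, replace = TRUE)
  nodes <- data.frame(node_id = 0:(m - 1L), read_id = sprintf("r%02d", 1:m),
                      orientation = "+", read_length = lens)
  if (nrow(pairs)) {
    ol <- pmin(lens[pairs[, 1]], lens[pairs[, 2]]) - sample(min_len, nrow(pairs), replace = TRUE)
    ok <- ol > 0
    edges <- data.frame(source = pairs[ok, 1] - 1L, target = pairs[ok, 2] - 1L,
                        overlap_length = ol[ok])
  } else {
    edges <- data.frame(source = integer(0), target = integer(0),
                        overlap_length = integer(0))
  }
  suppressWarnings(assembly_graph(nodes, edges))
}

# step-wise exhaustive greedy oracle: at every step scan the *entire* edge
# table for admissible continuations and apply the greedy rule literally
oracle_extend <- function(graph, scores, start_edge, visited, direction) {
  e <- graph$edges
  s0 <- e$source[start_edge + 1L]
  t0 <- e$target[start_edge + 1L]
  nodes <- c(s0, t0)
  edges <- start_edge
  cur <- if (direction == "forward") t0 else s0
  repeat {
    if (direction == "forward") {
      adm <- which(e$source == cur & !(e$target %in% nodes) &
                     !visited[e$target + 1L])
    } else {
      adm <- which(e$target == cur & !(e$source %in% nodes) &
                     !visited[e$source + 1L])
    }
    if (!length(adm)) break
    best <- adm[order(-scores[adm], e$edge_id[adm])][1L]
    if (direction == "forward") {
      cur <- e$target[best]
      nodes <- c(nodes, cur)
      edges <- c(edges, e$edge_id[best])
    } else {
      cur <- e$source[best]
      nodes <- c(cur, nodes)
      edges <- c(e$edge_id[best], edges)
    }
  }
  list(nodes = nodes, edges = edges)
}

# literal Nx scan: try every block length as the answer
oracle_nx <- function(lengths, denom) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  for (i in seq_along(s)) {
    if (sum(s[seq_len(i)]) >= denom / 2) return(s[i])
  }
  0
}

# coverage-vector union oracle for genome fraction
oracle_fraction <- function(starts, ends, ref_len) {
  cov <- logical(ref_len)
  for (i in seq_along(starts)) {
    s <- max(0L, starts[i]); e <- min(ref_len, ends[i])
    if (e > s) cov[(s + 1L):e] <- TRUE
  }
  100 * sum(cov) / ref_len
}

# tiny labeled chain graph with coordinates, used by several tests:
# reads laid head-to-tail with fixed overlaps plus an optional tip read
chain_reads <- function(starts, ends, strand = "+") {
  n <- length(starts)
  data.frame(read_id = sprintf("r%02d", seq_len(n)),
             sequence = vapply(ends - starts, function(l) {
               paste(rep("A", l), collapse = "")
             }, character(1)),
             start = starts, end = ends,
             strand = rep(strand, length.out = n),
             stringsAsFactors = FALSE)
}

graph_from_pairs <- function(reads, pairs_ol) {
  nodes <- data.frame(node_id = seq_len(nrow(reads)) - 1L,
                      read_id = reads$read_id, orientation = reads$strand,
                      read_length = reads$end - reads$start)
  edges <- data.frame(source = pairs_ol[, 1], target = pairs_ol[, 2],
                      overlap_length = pairs_ol[, 3])
  assembly_graph(nodes, edges)
}
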