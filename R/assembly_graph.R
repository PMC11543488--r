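#' @useDynLib contigraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

#' Construct an assembly graph
#'
#' An assembly graph is a directed graph whose vertices are oriented long
#' reads and whose edges record suffix--prefix overlaps between them. It is
#' the central container consumed by feature extraction, edge scoring,
#' labeling and layout.
#'
#' @param nodes data.frame with columns `node_id` (0-based, contiguous),
#'   `read_id` (character), `orientation` (`"+"` or `"-"`) and
#'   `read_length` (positive integer, base pairs).
#' @param edges data.frame with columns `edge_id` (0-based, contiguous),
#'   `source`, `target` (node ids), `overlap_length` (bp) and optionally
#'   `cigar` (character). Edges whose overlap is not strictly inside
#'   `(0, min(read lengths))`, or that are self loops, are dropped with a
#'   warning and the remaining edges are re-indexed.
#' @param sequences optional named character vector mapping `read_id` to its
#'   DNA sequence (forward orientation).
#'
#' @return An object of class `assembly_graph`.
#' @export
assembly_graph <- function(nodes, edges, sequences = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req_n <- c("node_id", "read_id", "orientation", "read_length")
  if (!all(req_n %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req_n, collapse = ", "))
  }
  if (nrow(edges) == 0L) {
    edges <- data.frame(edge_id = integer(0), source = integer(0),
                        target = integer(0), overlap_length = integer(0),
                        cigar = character(0), stringsAsFactors = FALSE)
  }
  req_e <- c("source", "target", "overlap_length")
  if (!all(req_e %in% names(edges))) {
    stop("edges must have columns: ", paste(req_e, collapse = ", "))
  }
  if (is.null(edges$cigar)) edges$cigar <- rep(NA_character_, nrow(edges))

  nodes$node_id <- as.integer(nodes$node_id)
  nodes$read_length <- as.integer(nodes$read_length)
  if (nrow(nodes) > 0L && !identical(nodes$node_id, seq_len(nrow(nodes)) - 1L)) {
    stop("node_id must be contiguous from 0 in row order")
  }
  if (any(nodes$read_length <= 0L)) stop("read_length must be > 0")
  if (!all(nodes$orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'")
  }

  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  edges$overlap_length <- as.integer(edges$overlap_length)
  if (nrow(edges) > 0L) {
    if (any(edges$source < 0L | edges$source >= nrow(nodes)) ||
        any(edges$target < 0L | edges$target >= nrow(nodes))) {
      stop("edge endpoint refers to unknown node_id")
    }
    len_s <- nodes$read_length[edges$source + 1L]
    len_t <- nodes$read_length[edges$target + 1L]
    bad <- edges$source == edges$target |
      edges$overlap_length <= 0L |
      edges$overlap_length >= pmin(len_s, len_t)
    if (any(bad)) {
      warning(sum(bad), " edge(s) dropped: self loop or overlap length not ",
              "strictly inside (0, min(read lengths))")
      edges <- edges[!bad, , drop = FALSE]
    }
  }
  edges$edge_id <- seq_len(nrow(edges)) - 1L
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  edges <- edges[, c("edge_id", "source", "target", "overlap_length", "cigar")]

  structure(list(nodes = nodes, edges = edges, sequences = sequences),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges of an assembly graph
#' @param graph an `assembly_graph`
#' @return integer count
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Per-node adjacency of an assembly graph
#'
#' @param graph an `assembly_graph`
#' @return list with elements `out` and `in`, each a list (indexed by
#'   `node_id + 1`) of 0-based `edge_id` vectors.
#' @export
adjacency <- function(graph) {
  m <- n_nodes(graph)
  out <- split(graph$edges$edge_id, factor(graph$edges$source, levels = 0:(m - 1L)))
  inn <- split(graph$edges$edge_id, factor(graph$edges$target, levels = 0:(m - 1L)))
  list(out = out, `in` = inn)
}

#' Out- and in-degree of every node
#'
#' Degrees are the two raw node features of the edge scorer: a vertex at a
#' dead end (out-degree 0) is the tell-tale of a tip.
#'
#' @param graph an `assembly_graph`
#' @return data.frame with columns `node_id`, `out_degree`, `in_degree`,
#'   ordered by `node_id`. Column sums of the two degree columns both equal
#'   the edge count.
#' @export
degrees <- function(graph) {
  m <- n_nodes(graph)
  data.frame(
    node_id = graph$nodes$node_id,
    out_degree = tabulate(graph$edges$source + 1L, nbins = m),
    in_degree = tabulate(graph$edges$target + 1L, nbins = m)
  )
}

# Source-consumed length of a GFA overlap CIGAR (SAM query convention:
# M/=/X/I consume the source, D does not). Only M/I/D/=/X are accepted.
parse_cigar_overlap <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) return(NA_integer_)
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR string: '", cigar, "'")
  }
  ops <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  if (!all(ops %in% c("M", "I", "D", "=", "X"))) {
    stop("unsupported CIGAR operator in '", cigar, "' (only M/I/D/=/X)")
  }
  sum(lens[ops %in% c("M", "I", "=", "X")])
}

#' Read an assembly graph from a GFA 1.0 file
#'
#' Accepts the Hifiasm-style dialect: `S` lines carry segments (reads) with a
#' sequence or an `LN:i:` length tag, `L` lines carry overlaps with a CIGAR
#' whose source-consumed length (`M`/`I`/`=`/`X` operators) is taken as the
#' overlap length. Each `(segment, orientation)` pair referenced becomes one
#' node; every segment contributes its `+` node, and `-` nodes are created on
#' first reference by an `L` line.
#'
#' @param path path to a GFA 1.0 file.
#' @return An `assembly_graph`. Edge probability scores stored as `ps:f:`
#'   tags and ground-truth labels stored as `gt:i:` tags are attached as
#'   attributes `scores` / `labels` when present on every L line.
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  seg_names <- character(0)
  seg_len <- integer(0)
  seqs <- character(0)
  l_rec <- list()

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3L) stop("malformed S record at line ", i)
      nm <- f[2]
      sq <- f[3]
      len <- if (sq != "*") nchar(sq) else NA_integer_
      for (tag in f[-(1:3)]) {
        if (startsWith(tag, "LN:i:")) len <- as.integer(substring(tag, 6L))
      }
      if (is.na(len)) stop("segment '", nm, "' at line ", i,
                           " has neither sequence nor LN:i: tag")
      seg_names <- c(seg_names, nm)
      seg_len <- c(seg_len, len)
      if (sq != "*") seqs[nm] <- sq
    } else if (f[1] == "L") {
      if (length(f) < 6L) stop("malformed L record at line ", i)
      ol <- tryCatch(parse_cigar_overlap(f[6]),
                     error = function(e) stop("line ", i, ": ", conditionMessage(e)))
      score <- NA_real_
      label <- NA_integer_
      for (tag in f[-(1:6)]) {
        if (startsWith(tag, "ps:f:")) score <- as.numeric(substring(tag, 6L))
        if (startsWith(tag, "gt:i:")) label <- as.integer(substring(tag, 6L))
      }
      l_rec[[length(l_rec) + 1L]] <- list(
        from = f[2], from_or = f[3], to = f[4], to_or = f[5],
        cigar = f[6], ol = ol, score = score, label = label, line = i)
    }
  }

  if (anyDuplicated(seg_names)) stop("duplicate segment name in GFA")
  len_of <- setNames(seg_len, seg_names)

  # nodes: all '+' segments in S order, then '-' nodes in first-reference order
  key <- paste0(seg_names, "\t+")
  node_read <- seg_names
  node_or <- rep("+", length(seg_names))
  for (r in l_rec) {
    for (side in list(c(r$from, r$from_or), c(r$to, r$to_or))) {
      if (!side[1] %in% seg_names) {
        stop("line ", r$line, ": L record references unknown segment '",
             side[1], "'")
      }
      k <- paste0(side[1], "\t", side[2])
      if (!k %in% key) {
        key <- c(key, k)
        node_read <- c(node_read, side[1])
        node_or <- c(node_or, side[2])
      }
    }
  }
  nodes <- data.frame(node_id = seq_along(key) - 1L, read_id = node_read,
                      orientation = node_or,
                      read_length = as.integer(len_of[node_read]),
                      stringsAsFactors = FALSE)

  idx_of <- setNames(nodes$node_id, key)
  if (length(l_rec)) {
    edges <- data.frame(
      edge_id = seq_along(l_rec) - 1L,
      source = vapply(l_rec, function(r) idx_of[[paste0(r$from, "\t", r$from_or)]], integer(1)),
      target = vapply(l_rec, function(r) idx_of[[paste0(r$to, "\t", r$to_or)]], integer(1)),
      overlap_length = vapply(l_rec, function(r) r$ol, integer(1)),
      cigar = vapply(l_rec, function(r) r$cigar, character(1)),
      stringsAsFactors = FALSE)
    scores <- vapply(l_rec, function(r) r$score, numeric(1))
    labels <- vapply(l_rec, function(r) r$label, integer(1))
  } else {
    edges <- data.frame(source = integer(0), target = integer(0),
                        overlap_length = integer(0), cigar = character(0))
    scores <- numeric(0)
    labels <- integer(0)
  }

  g <- assembly_graph(nodes, edges, sequences = if (length(seqs)) seqs else NULL)
  if (length(scores) && !anyNA(scores)) attr(g, "scores") <- scores
  if (length(labels) && !anyNA(labels)) attr(g, "labels") <- labels
  g
}

#' Write an assembly graph to a GFA 1.0 file
#'
#' @param graph an `assembly_graph`.
#' @param path output file path.
#' @param scores optional numeric vector of per-edge probability scores
#'   (aligned to `edge_id` order); written as `ps:f:` tags on L lines.
#' @param labels optional integer vector of per-edge ground-truth labels;
#'   written as `gt:i:` tags.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path, scores = NULL, labels = NULL) {
  n <- n_edges(graph)
  if (!is.null(scores) && length(scores) != n) {
    stop("scores must have one value per edge")
  }
  if (!is.null(labels) && length(labels) != n) {
    stop("labels must have one value per edge")
  }
  out <- "H\tVN:Z:1.0"
  reads <- unique(graph$nodes$read_id)
  len_of <- setNames(graph$nodes$read_length, graph$nodes$read_id)
  for (r in reads) {
    sq <- if (!is.null(graph$sequences) && r %in% names(graph$sequences)) {
      graph$sequences[[r]]
    } else "*"
    out <- c(out, sprintf("S\t%s\t%s\tLN:i:%d", r, sq, len_of[[r]]))
  }
  if (n > 0L) {
    e <- graph$edges
    s <- graph$nodes[e$source + 1L, ]
    t <- graph$nodes[e$target + 1L, ]
    cig <- ifelse(is.na(e$cigar), paste0(e$overlap_length, "M"), e$cigar)
    ll <- sprintf("L\t%s\t%s\t%s\t%s\t%s", s$read_id, s$orientation,
                  t$read_id, t$orientation, cig)
    if (!is.null(scores)) ll <- paste0(ll, sprintf("\tps:f:%.6g", scores))
    if (!is.null(labels)) ll <- paste0(ll, sprintf("\tgt:i:%d", as.integer(labels)))
    out <- c(out, ll)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Oriented sequence of every node
#'
#' Looks up each node's read sequence and reverse-complements it for
#' `-`-oriented nodes.
#'
#' @param graph an `assembly_graph`
#' @param read_sequences named character vector `read_id -> forward sequence`;
#'   defaults to the sequences stored in the graph.
#' @return character vector of length `n_nodes(graph)` in `node_id` order.
#' @export
node_sequences <- function(graph, read_sequences = graph$sequences) {
  if (is.null(read_sequences)) stop("no read sequences available")
  missing <- setdiff(graph$nodes$read_id, names(read_sequences))
  if (length(missing)) {
    stop("missing sequence for read(s): ", paste(head(missing, 3), collapse = ", "))
  }
  sq <- unname(read_sequences[graph$nodes$read_id])
  rc <- graph$nodes$orientation == "-"
  if (any(rc)) sq[rc] <- dna_revcomp(sq[rc])
  sq
}

#' Reverse-complement DNA strings
#' @param x character vector of DNA sequences (A/C/G/T)
#' @return character vector of reverse complements
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
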