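# Synthetic genome + coordinate-annotated HiFi-like read simulation.
# Every read records its true genome interval, so overlap-graph topology,
# edge labels and evaluation all come from known coordinates and the whole
# pipeline runs hermetically.

#' Generate a synthetic genome with controlled repeat content
#'
#' Draws a uniform-random DNA background and then pastes copies of randomly
#' chosen donor segments at non-overlapping destination slots until
#' approximately `repeat_fraction` of the genome is annotated as repeat.
#'
#' @param length genome length in bp.
#' @param repeat_fraction fraction of the genome covered by repeat copies,
#'   in `[0, 1)`.
#' @param repeat_unit_length length of each repeat copy in bp.
#' @param seed integer seed; the genome is deterministic given the seed.
#' @return An object of class `synthetic_genome`: list with `sequence`
#'   (character scalar) and `repeat_annotations` (data.frame `start`, `end`,
#'   `copy_of`, 0-based half-open destination/donor starts).
#' @export
generate_genome <- function(length, repeat_fraction = 0,
                            repeat_unit_length = 2000L, seed = 1L) {
  length <- as.integer(length)
  if (length <= 0L) stop("genome length must be positive")
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    stop("repeat_fraction must be in [0, 1)")
  }
  if (repeat_fraction > 0 && length < 10L * repeat_unit_length) {
    stop("genome too short for requested repeat packing: need length >= ",
         "10 * repeat_unit_length")
  }
  set.seed(seed)
  seq_v <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  ann <- data.frame(start = integer(0), end = integer(0), copy_of = integer(0))
  if (repeat_fraction > 0) {
    unit <- as.integer(repeat_unit_length)
    k <- max(1L, round(length * repeat_fraction / unit))
    slots <- seq(0L, length - unit, by = unit)
    if (k > length(slots) - 1L) stop("infeasible repeat packing")
    dest <- sort(sample(slots, k))
    for (d in dest) {
      src <- sample(setdiff(slots, d), 1L)
      seq_v[(d + 1L):(d + unit)] <- seq_v[(src + 1L):(src + unit)]
      ann <- rbind(ann, data.frame(start = d, end = d + unit, copy_of = src))
    }
  }
  structure(list(sequence = paste(seq_v, collapse = ""),
                 repeat_annotations = ann),
            class = "synthetic_genome")
}

# truncated-normal read lengths (simple rejection, bounded below)
rtrunc_norm_len <- function(k, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < k) {
    x <- round(rnorm(k, mean, sd))
    x <- x[x >= lo & x <= hi]
    out <- c(out, as.integer(x))
  }
  out[seq_len(k)]
}

inject_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_err <- rbinom(1L, length(chars), error_rate)
  if (n_err == 0L) return(seq)
  pos <- sort(sample(length(chars), n_err))
  type <- sample(c("sub", "ins", "del"), n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  # apply right-to-left so earlier positions stay valid
  for (i in rev(seq_len(n_err))) {
    p <- pos[i]
    if (type[i] == "sub") {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (type[i] == "ins") {
      chars <- append(chars, sample(bases, 1L), after = p)
    } else {
      chars <- chars[-p]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate coordinate-annotated HiFi-like reads
#'
#' Read start positions are uniform over valid positions, lengths are
#' truncated-normal, and substitution/insertion/deletion errors are injected
#' i.i.d. at `error_rate` in a 1:1:1 ratio. Each read records its true
#' 0-based half-open genome interval and strand; with `error_rate = 0` every
#' read is an exact substring of the genome at its recorded coordinates.
#'
#' @param genome a `synthetic_genome` (or plain character sequence).
#' @param coverage target fold coverage; reads are drawn until total read
#'   bases reach `coverage * genome length` (within a few percent).
#' @param mean_length,length_sd truncated-normal read-length parameters (bp).
#'   Lengths are bounded below at `max(200, mean/10)` and above at the
#'   genome length.
#' @param error_rate per-base error probability in `[0, 0.5)`; HiFi-like
#'   data sits at or below `0.001`.
#' @param rc_fraction fraction of reads emitted as reverse-complement
#'   (`-` strand); default 0, forward-only.
#' @param seed integer seed.
#' @return data.frame of class `simulated_reads`: `read_id`, `sequence`,
#'   `start`, `end`, `strand`. Coordinates always refer to the forward
#'   genome; a `-`-strand read's `sequence` is the reverse complement of the
#'   interval.
#' @export
simulate_reads <- function(genome, coverage, mean_length = 3000,
                           length_sd = 1500, error_rate = 0,
                           rc_fraction = 0, seed = 1L) {
  gseq <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  glen <- nchar(gseq)
  if (coverage <= 0) stop("coverage must be positive")
  if (mean_length >= glen) stop("mean_length must be below the genome length")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  set.seed(seed)
  target <- coverage * glen
  lo <- as.integer(max(200, mean_length / 10))
  lens <- integer(0)
  while (sum(lens) < target) {
    k <- max(8L, ceiling((target - sum(lens)) / mean_length))
    lens <- c(lens, rtrunc_norm_len(k, mean_length, length_sd, lo, glen))
  }
  # keep the shortest prefix of draws reaching the coverage target
  n_reads <- which(cumsum(lens) >= target)[1L]
  lens <- lens[seq_len(n_reads)]

  starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1L) - 1L, integer(1))
  ends <- starts + lens
  strand <- ifelse(runif(n_reads) < rc_fraction, "-", "+")
  seqs <- substring(gseq, starts + 1L, ends)
  if (any(strand == "-")) {
    seqs[strand == "-"] <- dna_revcomp(seqs[strand == "-"])
  }
  if (error_rate > 0) {
    seqs <- vapply(seqs, inject_errors, character(1), error_rate = error_rate,
                   USE.NAMES = FALSE)
  }
  reads <- data.frame(
    read_id = sprintf("read_%05d", seq_len(n_reads)),
    sequence = seqs, start = starts, end = ends, strand = strand,
    stringsAsFactors = FALSE)
  class(reads) <- c("simulated_reads", "data.frame")
  reads
}

#' Build the overlap graph of simulated reads from true coordinates
#'
#' Creates a directed edge `u -> v` for every same-strand read pair with
#' `start(u) < start(v)`, `end(u) > start(v)` and `end(v) > end(u)`
#' (a genuine dovetail: contained reads get no edge), whose overlap
#' `end(u) - start(v)` is at least `min_overlap`. The edge's
#' `overlap_length` is taken from the true coordinates. The resulting graph
#' is acyclic because edges strictly increase the start coordinate.
#'
#' @param reads a `simulated_reads` data.frame.
#' @param min_overlap minimum overlap length in bp for an edge to be kept.
#' @return An `assembly_graph` whose node order follows the row order of
#'   `reads`, with read sequences attached.
#' @export
build_overlap_graph <- function(reads, min_overlap = 500L) {
  m <- nrow(reads)
  nodes <- data.frame(node_id = seq_len(m) - 1L, read_id = reads$read_id,
                      orientation = reads$strand,
                      read_length = nchar(reads$sequence),
                      stringsAsFactors = FALSE)
  ord <- order(reads$start, reads$end)
  st <- reads$start[ord]
  en <- reads$end[ord]
  src <- integer(0); tgt <- integer(0); ol <- integer(0)
  for (a in seq_len(m)) {
    # candidate successors: strictly later start, overlapping, not contained
    j <- a + 1L
    cand <- integer(0)
    while (j <= m && st[j] < en[a]) {
      cand <- c(cand, j)
      j <- j + 1L
    }
    if (!length(cand)) next
    ok <- st[cand] > st[a] & en[cand] > en[a] &
      (en[a] - st[cand]) >= min_overlap &
      reads$strand[ord[cand]] == reads$strand[ord[a]]
    cand <- cand[ok]
    if (!length(cand)) next
    src <- c(src, rep(ord[a] - 1L, length(cand)))
    tgt <- c(tgt, ord[cand] - 1L)
    ol <- c(ol, en[a] - st[cand])
  }
  edges <- data.frame(source = src, target = tgt, overlap_length = ol,
                      stringsAsFactors = FALSE)
  assembly_graph(nodes, edges,
                 sequences = setNames(reads$sequence, reads$read_id))
}

#' Write simulated reads to FASTA with coordinates in the headers
#'
#' Headers take the form `id start end strand`, which [read_annotated_fasta()]
#' parses back.
#'
#' @param reads a `simulated_reads` data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- sprintf("%s %d %d %s", reads$read_id, reads$start, reads$end,
                       reads$strand)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @rdname write_annotated_fasta
#' @return for `read_annotated_fasta`: a `simulated_reads` data.frame.
#' @export
read_annotated_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), " +")
  if (any(lengths(parts) < 4L)) {
    stop("FASTA headers must be 'id start end strand'")
  }
  reads <- data.frame(
    read_id = vapply(parts, `[`, character(1), 1L),
    sequence = as.character(ss),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[`, character(1), 3L)),
    strand = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  class(reads) <- c("simulated_reads", "data.frame")
  reads
}

#' Write a genome to FASTA
#' @param genome a `synthetic_genome`
#' @param path output path
#' @param name sequence name
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path, name = "synthetic_genome") {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
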