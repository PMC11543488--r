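# QUAST-style contiguity and accuracy metrics against the known synthetic
# reference: aligned blocks via exact k-mer anchoring, NA50/NGA50, genome
# fraction and misassembly junctions.

#' Align contigs to the reference as maximal collinear blocks
#'
#' Desk-scale aligner: every contig position contributes a k-mer anchor
#' wherever its k-mer occurs uniquely in the reference; anchors are chained
#' while they stay collinear (same diagonal within `junction_dist` and no
#' gap beyond it). A contig whose anchors split into several discordant
#' chains contributes one misassembly per junction. Contigs that are exact
#' substrings of the reference short-circuit to a single full-length block.
#'
#' @param contigs a `contig_set` (or data.frame with `name`, `sequence`).
#' @param reference a `synthetic_genome` or plain character sequence.
#' @param k anchor k-mer size.
#' @param stride spacing between sampled contig k-mers (bp).
#' @param junction_dist maximum diagonal jump or gap within one block (bp);
#'   larger jumps open a new block and count a misassembly junction.
#' @return data.frame with one row per block: `contig`, `contig_start`,
#'   `contig_end`, `ref_start`, `ref_end` (0-based half-open), `length`;
#'   attribute `"misassemblies"` holds the junction count.
#' @export
aligned_blocks <- function(contigs, reference, k = 21L, stride = 50L,
                           junction_dist = 1000L) {
  ref <- if (inherits(reference, "synthetic_genome")) reference$sequence else reference
  rlen <- nchar(ref)
  blocks <- data.frame(contig = character(0), contig_start = integer(0),
                       contig_end = integer(0), ref_start = integer(0),
                       ref_end = integer(0), length = integer(0))
  mis <- 0L
  if (nrow(contigs) == 0L) {
    attr(blocks, "misassemblies") <- 0L
    return(blocks)
  }
  # unique reference k-mers
  rk <- substring(ref, seq_len(rlen - k + 1L), seq_len(rlen - k + 1L) + k - 1L)
  dup <- duplicated(rk) | duplicated(rk, fromLast = TRUE)
  rk_pos <- which(!dup)                     # 1-based k-mer start
  rk_uni <- rk[!dup]

  add_block <- function(contig, cs, ce, rs, re) {
    rs <- max(0L, rs); re <- min(rlen, re)
    blocks <<- rbind(blocks, data.frame(
      contig = contig, contig_start = cs, contig_end = ce,
      ref_start = rs, ref_end = re, length = re - rs))
  }

  for (i in seq_len(nrow(contigs))) {
    cseq <- contigs$sequence[i]
    cname <- contigs$name[i]
    clen <- nchar(cseq)
    # fast path: exact substring
    hit <- regexpr(cseq, ref, fixed = TRUE)
    if (hit > 0L) {
      add_block(cname, 0L, clen, hit - 1L, hit - 1L + clen)
      next
    }
    if (clen < k) next
    cpos <- unique(c(seq(1L, clen - k + 1L, by = stride), clen - k + 1L))
    ck <- substring(cseq, cpos, cpos + k - 1L)
    m <- match(ck, rk_uni)
    keep <- !is.na(m)
    if (!any(keep)) next
    cp <- cpos[keep]
    rp <- rk_pos[m[keep]]
    ord <- order(cp)
    cp <- cp[ord]; rp <- rp[ord]
    diagb <- rp - cp
    # chain: break when diagonal jumps or the contig gap exceeds the bound
    brk <- which(abs(diff(diagb)) > junction_dist | diff(cp) > 4L * junction_dist)
    startsb <- c(1L, brk + 1L)
    endsb <- c(brk, length(cp))
    for (b in seq_along(startsb)) {
      ii <- startsb[b]:endsb[b]
      cs <- cp[ii[1L]] - 1L
      ce <- cp[ii[length(ii)]] + k - 1L
      d <- round(mean(diagb[ii]))
      # extend the block to the contig ends along the block diagonal
      rs <- (d - 1L) + 0L
      re <- (d - 1L) + clen
      cs0 <- 0L; ce0 <- clen
      if (b > 1L) { cs0 <- cs; rs <- d - 1L + cs }
      if (b < length(startsb)) { ce0 <- ce; re <- d - 1L + ce }
      add_block(cname, cs0, ce0, rs, re)
    }
    mis <- mis + (length(startsb) - 1L)
  }
  rownames(blocks) <- NULL
  attr(blocks, "misassemblies") <- mis
  blocks
}

#' Nx-style statistic over aligned block lengths
#'
#' Sorts the lengths in descending order, accumulates them, and returns the
#' first length at which the running total reaches half of `denominator`
#' (NA50 uses the total assembly length, NGA50 the reference length);
#' returns 0 when the blocks never reach it.
#'
#' @param block_lengths numeric vector of block lengths (bp).
#' @param denominator positive reference total (bp).
#' @return the statistic in bp.
#' @export
nx_statistic <- function(block_lengths, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (!length(block_lengths)) return(0)
  s <- sort(block_lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= denominator / 2)[1L]
  if (is.na(i)) 0 else s[i]
}

#' Fraction of the reference covered by aligned blocks
#'
#' @param blocks block table from [aligned_blocks()] (uses `ref_start`,
#'   `ref_end`).
#' @param reference_length reference genome length in bp.
#' @return percentage in `[0, 100]` of reference bases inside the union of
#'   block intervals.
#' @export
genome_fraction <- function(blocks, reference_length) {
  if (nrow(blocks) == 0L) return(0)
  s <- pmax(0, blocks$ref_start)
  e <- pmin(reference_length, blocks$ref_end)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(0)
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  covered <- 0
  cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] > cur_e) {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else {
      cur_e <- max(cur_e, e[i])
    }
  }
  covered <- covered + (cur_e - cur_s)
  100 * covered / reference_length
}

#' Evaluate an assembly against the known reference
#'
#' @param contigs a `contig_set`.
#' @param reference a `synthetic_genome` or character sequence.
#' @param ... passed to [aligned_blocks()].
#' @return an `assembly_report`: list with `contig_count`, `largest_contig`,
#'   `total_length`, `genome_fraction` (percent), `na50`, `nga50`,
#'   `misassembly_count`, and the block table in `$blocks`.
#' @export
evaluate_assembly <- function(contigs, reference, ...) {
  ref <- if (inherits(reference, "synthetic_genome")) reference$sequence else reference
  rlen <- nchar(ref)
  blocks <- aligned_blocks(contigs, reference, ...)
  total <- sum(nchar(contigs$sequence))
  structure(list(
    contig_count = nrow(contigs),
    largest_contig = if (nrow(contigs)) max(nchar(contigs$sequence)) else 0L,
    total_length = total,
    genome_fraction = genome_fraction(blocks, rlen),
    na50 = if (total > 0) nx_statistic(blocks$length, total) else 0,
    nga50 = nx_statistic(blocks$length, rlen),
    misassembly_count = attr(blocks, "misassemblies"),
    blocks = blocks), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembly report\n")
  cat(sprintf("  contigs          %d\n", x$contig_count))
  cat(sprintf("  largest contig   %d bp\n", x$largest_contig))
  cat(sprintf("  total length     %d bp\n", x$total_length))
  cat(sprintf("  genome fraction  %.3f %%\n", x$genome_fraction))
  cat(sprintf("  NA50             %d bp\n", as.integer(x$na50)))
  cat(sprintf("  NGA50            %d bp\n", as.integer(x$nga50)))
  cat(sprintf("  misassemblies    %d\n", x$misassembly_count))
  invisible(x)
}

#' Write an assembly report as CSV
#' @param report an `assembly_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_csv <- function(report, path) {
  df <- data.frame(
    metric = c("contigs", "largest_contig", "total_length",
               "genome_fraction", "na50", "nga50", "misassemblies"),
    value = c(report$contig_count, report$largest_contig,
              report$total_length, report$genome_fraction, report$na50,
              report$nga50, report$misassembly_count))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
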