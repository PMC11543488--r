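test_that("genome generation is seeded and annotates repeats as requested", {
  g1 <- generate_genome(1000, 0, seed = 7)
  g2 <- generate_genome(1000, 0, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence), 1000L)
  expect_equal(nrow(g1$repeat_annotations), 0L)
  expect_true(all(strsplit(g1$sequence, "")[[1]] %in% c("A", "C", "G", "T")))

  gr <- generate_genome(50000, 0.2, 2000, seed = 7)
  ann <- gr$repeat_annotations
  expect_true(all(ann$start >= 0 & ann$end <= 50000))
  frac <- sum(ann$end - ann$start) / 50000
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
  # annotated copies really are copies of their donors
  for (i in seq_len(nrow(ann))) {
    expect_identical(substring(gr$sequence, ann$start[i] + 1, ann$end[i]),
                     substring(gr$sequence, ann$copy_of[i] + 1,
                               ann$copy_of[i] + (ann$end[i] - ann$start[i])))
  }
})

test_that("error-free reads are exact substrings at their coordinates", {
  g <- generate_genome(20000, 0, seed = 3)
  reads <- simulate_reads(g, coverage = 5, mean_length = 1000,
                          length_sd = 400, error_rate = 0, seed = 3)
  expect_true(all(reads$end - reads$start == nchar(reads$sequence)))
  for (i in seq_len(nrow(reads))) {
    expect_identical(reads$sequence[i],
                     substring(g$sequence, reads$start[i] + 1, reads$end[i]))
  }
})

test_that("total read bases track the requested coverage", {
  g <- generate_genome(100000, 0, seed = 5)
  reads <- simulate_reads(g, coverage = 30, mean_length = 3000,
                          length_sd = 1200, seed = 5)
  total <- sum(nchar(reads$sequence))
  expect_gte(total, 2.7e6)
  expect_lte(total, 3.3e6)
})

test_that("injected errors land near the requested rate", {
  g <- generate_genome(50000, 0, seed = 9)
  reads <- simulate_reads(g, coverage = 4, mean_length = 2500,
                          length_sd = 800, error_rate = 0.001, seed = 9)
  ed <- sum(edit_distance(
    reads$sequence,
    substring(g$sequence, reads$start + 1, reads$end)))
  expected <- 0.001 * sum(reads$end - reads$start)
  # binomial sampling slack: 5 sigma plus indel/substitution cancellation
  expect_gt(ed, expected - 5 * sqrt(expected) - 10)
  expect_lt(ed, expected + 5 * sqrt(expected) + 10)
})

test_that("simulation is reproducible bit for bit", {
  g <- generate_genome(30000, 0, seed = 21)
  r1 <- simulate_reads(g, 6, 2000, 700, error_rate = 0.002, seed = 13)
  r2 <- simulate_reads(g, 6, 2000, 700, error_rate = 0.002, seed = 13)
  expect_identical(r1, r2)
})

test_that("overlap-graph edges follow the dovetail conditions", {
  reads <- chain_reads(c(0, 50), c(100, 150))
  g <- build_overlap_graph(reads, min_overlap = 10)
  expect_equal(n_edges(g), 1L)
  expect_equal(g$edges$overlap_length, 50L)
  expect_equal(g$edges$source, 0L)
  expect_equal(g$edges$target, 1L)

  # disjoint reads: no edge
  g2 <- build_overlap_graph(chain_reads(c(0, 120), c(100, 200)), 10)
  expect_equal(n_edges(g2), 0L)

  # containment: end(B) > end(A) fails, no edge
  g3 <- build_overlap_graph(chain_reads(c(0, 50), c(200, 150)), 10)
  expect_equal(n_edges(g3), 0L)

  # opposite strands: no edge
  g4 <- build_overlap_graph(chain_reads(c(0, 50), c(100, 150),
                                        strand = c("+", "-")), 10)
  expect_equal(n_edges(g4), 0L)

  # overlap below threshold: no edge
  g5 <- build_overlap_graph(chain_reads(c(0, 95), c(100, 195)), 10)
  expect_equal(n_edges(g5), 0L)
})

test_that("clean coverage >= 5 graphs are connected, acyclic and spell the genome", {
  skip_if_not_installed("igraph")
  g <- generate_genome(20000, 0, seed = 11)
  reads <- simulate_reads(g, coverage = 6, mean_length = 1500,
                          length_sd = 400, error_rate = 0, seed = 11)
  gr <- build_overlap_graph(reads, min_overlap = 50)
  ig <- igraph::graph_from_edgelist(
    cbind(gr$edges$source, gr$edges$target) + 1L, directed = TRUE)
  ig <- igraph::add_vertices(ig, max(0, n_nodes(gr) - igraph::vcount(ig)))
  expect_true(igraph::is_dag(ig))
  expect_equal(igraph::count_components(ig, mode = "weak"), 1)

  # stitching reads in start order reconstructs the genome exactly
  ord <- order(reads$start, reads$end)
  genome_hat <- reads$sequence[ord[1]]
  pos_end <- reads$end[ord[1]]
  for (i in ord[-1]) {
    if (reads$end[i] <= pos_end) next  # contained
    genome_hat <- paste0(genome_hat,
                         substring(reads$sequence[i], pos_end - reads$start[i] + 1))
    pos_end <- reads$end[i]
  }
  expect_identical(genome_hat,
                   substring(g$sequence, min(reads$start) + 1, pos_end))
})

test_that("annotated FASTA round trips reads with coordinates", {
  g <- generate_genome(10000, 0, seed = 2)
  reads <- simulate_reads(g, 3, 800, 200, seed = 2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_annotated_fasta(reads, f)
  back <- read_annotated_fasta(f)
  expect_identical(back, reads)
})
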