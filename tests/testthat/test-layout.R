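test_that("greedy extension stops at dead ends and follows best scores", {
  # chain 0->1->2 with decreasing scores plus a low-scoring branch
  g <- graph_from_pairs(chain_reads(c(0, 60, 120), c(100, 160, 220)),
                        cbind(c(0, 1), c(1, 2), c(40, 40)))
  p <- greedy_extend(g, c(0.9, 0.8), 0L, direction = "forward")
  expect_equal(p$nodes, c(0L, 1L, 2L))
  expect_equal(p$edges, c(0L, 1L))

  # head has no out-edges: path is the start edge alone
  p2 <- greedy_extend(g, c(0.9, 0.8), 1L, direction = "forward")
  expect_equal(p2$nodes, c(1L, 2L))
  expect_equal(p2$edges, 1L)

  # backward from the last edge walks the chain back
  p3 <- greedy_extend(g, c(0.9, 0.8), 1L, direction = "backward")
  expect_equal(p3$nodes, c(0L, 1L, 2L))
})

test_that("greedy extension matches the exhaustive step-wise oracle", {
  set.seed(59)
  for (trial in 1:60) {
    m <- sample(4:12, 1)
    g <- random_dag(m, p = 0.4)
    if (n_edges(g) == 0L) next
    scores <- round(runif(n_edges(g)), 2)   # duplicated scores exercise ties
    start <- sample(g$edges$edge_id, 1)
    for (dir in c("forward", "backward")) {
      got <- greedy_extend(g, scores, start, direction = dir)
      want <- oracle_extend(g, scores, start, logical(m), dir)
      expect_identical(got, want)
    }
  }
})

test_that("decoding a single chain emits one covering path", {
  g <- graph_from_pairs(chain_reads(seq(0, 240, by = 60),
                                    seq(100, 340, by = 60)),
                        cbind(0:3, 1:4, rep(40, 4)))
  paths <- decode(g, rep(0.9, 4), N = 4, min_path_reads = 2, seed = 1)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$nodes, 0:4)
})

test_that("disjoint chains come out longest-first and node-disjoint", {
  # chain A: 10 reads, chain B: 3 reads, far apart on the genome
  starts <- c(seq(0, 540, by = 60), seq(5000, 5120, by = 60))
  ends <- starts + 100
  reads <- chain_reads(starts, ends)
  g <- build_overlap_graph(reads, min_overlap = 10)
  paths <- decode(g, rep(1, n_edges(g)), N = 4, min_path_reads = 2, seed = 2)
  expect_length(paths, 2L)
  expect_gt(length(paths[[1]]$nodes), length(paths[[2]]$nodes))
  expect_length(intersect(paths[[1]]$nodes, paths[[2]]$nodes), 0L)
})

test_that("emitted paths are node-disjoint on random graphs", {
  set.seed(61)
  for (trial in 1:25) {
    g <- random_dag(sample(6:14, 1), p = 0.45)
    if (n_edges(g) == 0L) next
    scores <- runif(n_edges(g))
    paths <- decode(g, scores, N = 3, min_path_reads = 2, seed = trial)
    all_nodes <- unlist(lapply(paths, `[[`, "nodes"))
    expect_equal(anyDuplicated(all_nodes), 0L)
    total <- sum(vapply(paths, function(p) p$bases, numeric(1)))
    expect_lte(total, sum(g$nodes$read_length))
  }
})

test_that("decoding is deterministic under a fixed seed", {
  set.seed(67)
  g <- random_dag(12, p = 0.5)
  scores <- rep(0.5, n_edges(g))    # all tied: only the seed disambiguates
  p1 <- decode(g, scores, N = 3, min_path_reads = 2, seed = 99)
  p2 <- decode(g, scores, N = 3, min_path_reads = 2, seed = 99)
  expect_identical(p1, p2)
})

test_that("contig concatenation trims each overlap once", {
  seqs <- c(r01 = random_dna(100), r02 = random_dna(100))
  nodes <- data.frame(node_id = 0:1, read_id = c("r01", "r02"),
                      orientation = "+", read_length = 100L)
  edges <- data.frame(source = 0, target = 1, overlap_length = 40L)
  g <- assembly_graph(nodes, edges, sequences = seqs)
  path <- structure(list(nodes = 0:1, edges = 0L, bases = 160),
                    class = "assembly_path")
  ctg <- paths_to_contigs(list(path), g)
  expect_equal(ctg$length, 160L)
  expect_equal(ctg$sequence,
               paste0(seqs[["r01"]], substring(seqs[["r02"]], 41)))

  single <- structure(list(nodes = 0L, edges = integer(0), bases = 100),
                      class = "assembly_path")
  ctg1 <- paths_to_contigs(list(single), g)
  expect_equal(ctg1$sequence, unname(seqs["r01"]))

  bad <- structure(list(nodes = 0:1, edges = 0L, bases = 0),
                   class = "assembly_path")
  g_bad <- g
  g_bad$edges$overlap_length <- 200L
  g_bad$sequences <- seqs
  expect_error(paths_to_contigs(list(bad), g_bad), "malformed path")
})

test_that("oracle scores on a clean simulation reproduce the genome", {
  genome <- generate_genome(20000, 0, seed = 71)
  reads <- simulate_reads(genome, 8, 1500, 500, error_rate = 0, seed = 71)
  g <- build_overlap_graph(reads, min_overlap = 100)
  lab <- label_edges(g, reads)
  paths <- decode(g, as.numeric(lab$labels), N = 8, min_path_reads = 3,
                  seed = 5)
  contigs <- paths_to_contigs(paths, g)
  # the longest contig is an exact substring of the genome
  expect_true(grepl(contigs$sequence[which.max(contigs$length)],
                    genome$sequence, fixed = TRUE))
  # conservation: length equals sum of reads minus sum of overlaps
  for (i in seq_along(paths)) {
    expect_equal(contigs$length[i], paths[[i]]$bases)
  }
})
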