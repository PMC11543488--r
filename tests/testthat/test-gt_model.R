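make_small <- function(seed = 3) {
  set.seed(seed)
  nodes <- data.frame(node_id = 0:4, read_id = paste0("r", 1:5),
                      orientation = "+", read_length = 100L)
  edges <- data.frame(source = c(0, 1, 2, 0, 3), target = c(1, 2, 3, 2, 4),
                      overlap_length = c(30, 40, 20, 25, 35))
  assembly_graph(nodes, edges)
}

test_that("config validation enforces head divisibility and clamp", {
  expect_error(gt_config(d = 10, H = 4), "divisible")
  expect_error(gt_config(clamp = 0), "positive")
  expect_error(gt_config(mlp_hidden = c(8, 2)), "width 1")
  cfg <- gt_config(d = 64, H = 8)
  expect_equal(cfg$d_k, 8L)
})

test_that("Laplacian positional encodings are orthonormal eigenvectors", {
  g <- make_small()
  pe <- laplacian_pe(g, 3)
  expect_equal(dim(pe), c(5L, 3L))
  gram <- crossprod(pe)
  expect_equal(gram, diag(3), tolerance = 1e-6)
  # deterministic sign convention
  expect_identical(pe, laplacian_pe(g, 3))
  expect_error(laplacian_pe(g, 5), "smaller")
})

test_that("path-graph eigenvalues match the closed form (unnormalized)", {
  nodes <- data.frame(node_id = 0:3, read_id = paste0("p", 1:4),
                      orientation = "+", read_length = 50L)
  edges <- data.frame(source = 0:2, target = 1:3, overlap_length = 10L)
  g <- assembly_graph(nodes, edges)
  pe <- laplacian_pe(g, 2, normalized = FALSE)
  vals <- attr(pe, "values")
  expect_equal(vals, 2 - 2 * cos(pi * (1:2) / 4), tolerance = 1e-6)
})

test_that("disconnected graphs have one zero eigenvalue per component", {
  nodes <- data.frame(node_id = 0:5, read_id = paste0("q", 1:6),
                      orientation = "+", read_length = 50L)
  edges <- data.frame(source = c(0, 1, 3, 4), target = c(1, 2, 4, 5),
                      overlap_length = 10L)
  g <- assembly_graph(nodes, edges)
  pe <- laplacian_pe(g, 4, normalized = FALSE)
  vals <- attr(pe, "values")   # trivial first zero already dropped
  expect_lt(abs(vals[1]), 1e-8)
  expect_gt(vals[2], 1e-8)
})

test_that("attention weights sum to one over each in-neighbourhood", {
  g <- make_small()
  cfg <- gt_config(d = 8, H = 2, L = 1, lappe_k = 2,
                   mlp_hidden = c(8, 4, 1))
  model <- init_gt_model(cfg, seed = 11)
  h <- matrix(rnorm(5 * 8), 5, 8)
  e <- matrix(rnorm(5 * 8), 5, 8)
  out <- attention_layer(h, e, model$params$layers[[1]], g, cfg)
  A <- out$attention
  sums <- rowsum(A, g$edges$target)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(is.finite(out$h)) && all(is.finite(out$e)))
})

test_that("a single attention head over one edge passes V h_a through", {
  nodes <- data.frame(node_id = 0:1, read_id = c("a", "b"),
                      orientation = "+", read_length = 10L)
  edges <- data.frame(source = 0, target = 1, overlap_length = 5L)
  g <- assembly_graph(nodes, edges)
  cfg <- gt_config(d = 1, H = 1, L = 1, lappe_k = 1, mlp_hidden = c(1, 1))
  model <- init_gt_model(cfg, seed = 1)
  P <- model$params$layers[[1]]
  P$Wv <- matrix(0.7)
  h <- matrix(c(2, -1), 2, 1)
  e <- matrix(0.3, 1, 1)
  lf <- contigraph:::layer_forward(h, e, P, 1L, 2L, cfg, training = FALSE)
  # softmax over the single in-neighbour is 1, so the aggregated message
  # into node b is exactly V %*% h_a
  expect_equal(lf$cache$agg[2, 1], 0.7 * 2)
  expect_equal(lf$cache$agg[1, 1], 0)      # node a has no in-neighbours
  expect_equal(unname(lf$attention[1, 1]), 1)
})

test_that("zero edge projections reduce attention to uniform averaging", {
  g <- make_small()
  cfg <- gt_config(d = 4, H = 2, L = 1, lappe_k = 2, mlp_hidden = c(4, 1))
  model <- init_gt_model(cfg, seed = 13)
  P <- model$params$layers[[1]]
  P$We <- matrix(0, 4, 4)   # multiplicative gate nulls every logit
  h <- matrix(rnorm(20), 5, 4)
  e <- matrix(rnorm(20), 5, 4)
  out <- attention_layer(h, e, P, g, cfg)
  A <- out$attention
  indeg <- degrees(g)$in_degree[g$edges$target + 1L]
  expect_equal(unname(A), matrix(1 / indeg, ncol = 2, nrow = 5),
               tolerance = 1e-12)
})

test_that("graphs with isolated nodes score finitely and in (0,1)", {
  nodes <- data.frame(node_id = 0:3, read_id = paste0("r", 1:4),
                      orientation = "+", read_length = 100L)
  edges <- data.frame(source = 0, target = 1, overlap_length = 30L)
  g <- assembly_graph(nodes, edges)   # nodes 2 and 3 isolated
  cfg <- gt_config(d = 8, H = 2, L = 2, lappe_k = 2, mlp_hidden = c(8, 4, 1))
  model <- init_gt_model(cfg, seed = 17)
  fs <- suppressMessages(extract_features(g, read_sequences = NULL))
  sc <- score_edges(g, fs, model)
  expect_length(sc, 1L)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("sigmoid head maps logits to the documented scores", {
  expect_equal(1 / (1 + exp(0)), 0.5)
  g <- make_small()
  cfg <- gt_config(d = 4, H = 1, L = 1, lappe_k = 2, mlp_hidden = c(4, 1))
  model <- init_gt_model(cfg, seed = 19)
  # zero final head weights force logit 0 -> score 0.5 for every edge
  model$params$head$W2 <- model$params$head$W2 * 0
  model$params$head$b2 <- model$params$head$b2 * 0
  fs <- suppressMessages(extract_features(g, read_sequences = NULL))
  sc <- score_edges(g, fs, model)
  expect_equal(sc, rep(0.5, 5))
  model$params$head$b2 <- model$params$head$b2 + 5
  sc5 <- score_edges(g, fs, model)
  expect_equal(sc5, rep(1 / (1 + exp(-5)), 5), tolerance = 1e-9)
})

test_that("the scorer is permutation-equivariant", {
  set.seed(23)
  g <- random_dag(15, p = 0.3)
  cfg <- gt_config(d = 8, H = 2, L = 2, lappe_k = 4, mlp_hidden = c(8, 4, 1))
  model <- init_gt_model(cfg, seed = 23)
  fs <- suppressMessages(extract_features(g, read_sequences = NULL))
  pe <- laplacian_pe(g, 4)
  sc <- score_edges(g, fs, model, pe = pe)

  perm <- sample(n_nodes(g))
  inv <- order(perm)
  nodes2 <- g$nodes[inv, ]
  nodes2$node_id <- seq_len(nrow(nodes2)) - 1L
  edges2 <- g$edges
  edges2$source <- perm[g$edges$source + 1L] - 1L
  edges2$target <- perm[g$edges$target + 1L] - 1L
  g2 <- assembly_graph(nodes2, edges2)
  fs2 <- list(node_raw = fs$node_raw[inv, , drop = FALSE],
              edge_raw = fs$edge_raw)
  sc2 <- score_edges(g2, fs2, model, pe = pe[inv, , drop = FALSE])
  expect_equal(sc2, sc, tolerance = 1e-6)
})

test_that("analytic gradients match central differences", {
  set.seed(29)
  g <- make_small()
  cfg <- gt_config(d = 4, H = 2, L = 2, lappe_k = 2, mlp_hidden = c(4, 2, 1))
  model <- init_gt_model(cfg, seed = 31)
  node_raw <- cbind(degrees(g)$out_degree, degrees(g)$in_degree)
  edge_raw <- cbind(g$edges$overlap_length / 50, runif(5))
  pe <- laplacian_pe(g, 2)
  src1 <- g$edges$source + 1L
  tgt1 <- g$edges$target + 1L
  y <- c(1, 0, 1, 1, 0)
  pw <- 1.5
  lossfn <- function(m) {
    f <- contigraph:::gt_forward(m, node_raw, edge_raw, pe, src1, tgt1,
                                 training = TRUE)
    z <- f$logits
    mean(pw * y * log1p(exp(-z)) + (1 - y) * log1p(exp(z)))
  }
  f <- contigraph:::gt_forward(model, node_raw, edge_raw, pe, src1, tgt1,
                               training = TRUE)
  p <- 1 / (1 + exp(-f$logits))
  dlog <- (-pw * y * (1 - p) + (1 - y) * p) / length(y)
  gr <- contigraph:::gt_backward(model, f$cache, dlog)

  paths <- list(c("head", "W1"), c("head", "b3"),
                list("layers", 1L, "Wq"), list("layers", 2L, "We"),
                list("layers", 1L, "Wo_e"), list("layers", 2L, "Wf1"),
                list("layers", 1L, "Wg2"), list("layers", 2L, "bn1h", "gamma"),
                list("layers", 1L, "bn2e", "beta"),
                c("node_embed", "W2"), c("edge_embed", "W3"), "W_pe")
  for (path in paths) {
    w <- model$params
    gw <- gr
    for (k in path) {
      w <- w[[k]]
      gw <- gw[[k]]
    }
    ii <- sample.int(length(w), min(2L, length(w)))
    for (i in ii) {
      h <- 1e-5
      mset <- function(val) {
        mm <- model
        expr <- "mm$params"
        for (k in path) {
          expr <- if (is.character(k)) paste0(expr, "[[\"", k, "\"]]")
          else paste0(expr, "[[", k, "]]")
        }
        wv <- w
        wv[i] <- val
        eval(parse(text = paste0(expr, " <- wv")))
        mm
      }
      num <- (lossfn(mset(w[i] + h)) - lossfn(mset(w[i] - h))) / (2 * h)
      expect_equal(gw[i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round trip through a single file", {
  cfg <- gt_config(d = 4, H = 1, L = 1, lappe_k = 2, mlp_hidden = c(4, 1))
  model <- init_gt_model(cfg, seed = 37)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back, model)
  saveRDS(list(1), f)
  expect_error(load_checkpoint(f), "not a gt_model")
})
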