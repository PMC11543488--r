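# Edge-aware graph-transformer scorer.
#
# Node features h and edge features e are updated jointly per layer. For
# head k over each directed edge j -> i (attention of node i over its
# in-neighbours j):
#
#   s_ij  = (Q h_i  *  K h_j) / sqrt(d_k) * (E e_ij)      (elementwise, d_k)
#   s_ij  = clamp(s_ij, -c, c)
#   a_ij  = softmax_j( clamp(sum(s_ij), -c, c) )
#   h_i'  = O_h [ concat_k  sum_j a_ij^k (V h_j)_k ]
#   e_ij' = O_e [ concat_k  s_ij^k ]
#
# with the logit clamp (default c = 5) stabilizing the exponentials. Both
# streams then pass residual + BatchNorm, a 2d-wide ReLU FFN, and a second
# residual + BatchNorm. Scores come from a 3-layer MLP + sigmoid over
# [h_source, h_target, e_edge]. Backpropagation through every block is
# implemented analytically below and checked against numerical gradients in
# the test suite.

#' Graph-transformer configuration
#'
#' @param d hidden dimension (divisible by `H`).
#' @param H number of attention heads.
#' @param L number of stacked transformer layers.
#' @param lappe_k number of Laplacian eigenvectors used as positional
#'   encodings; must stay below the node count of every scored graph.
#' @param clamp attention-logit clamp bound (positive).
#' @param mlp_hidden widths of the score head; the final width must be 1.
#' @param edge_gate how the edge projection modulates the scaled node
#'   dot-product: `"multiplicative"` (elementwise product, default) or
#'   `"additive"` (ablation variant).
#' @param normalized_laplacian use the symmetric normalized Laplacian for
#'   positional encodings (default) or the unnormalized one.
#' @return a `gt_config` list.
#' @export
gt_config <- function(d = 64L, H = 8L, L = 4L, lappe_k = 16L, clamp = 5,
                      mlp_hidden = c(64L, 32L, 1L),
                      edge_gate = c("multiplicative", "additive"),
                      normalized_laplacian = TRUE) {
  edge_gate <- match.arg(edge_gate)
  if (d %% H != 0L) stop("d must be divisible by H")
  if (clamp <= 0) stop("clamp must be positive")
  if (tail(mlp_hidden, 1L) != 1L) stop("score head must end in width 1")
  structure(list(d = as.integer(d), H = as.integer(H), L = as.integer(L),
                 d_k = as.integer(d / H), lappe_k = as.integer(lappe_k),
                 clamp = clamp, mlp_hidden = as.integer(mlp_hidden),
                 edge_gate = edge_gate,
                 normalized_laplacian = normalized_laplacian),
            class = "gt_config")
}

xavier <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

#' Initialize a graph-transformer edge scorer
#'
#' @param config a [gt_config()].
#' @param seed integer seed for weight initialization.
#' @return a `gt_model`: list with `config` and `params` (feature
#'   embeddings, positional-encoding projection, per-layer attention/FFN/
#'   BatchNorm parameters, score-head MLP).
#' @export
init_gt_model <- function(config = gt_config(), seed = 1L) {
  set.seed(seed)
  d <- config$d
  layers <- lapply(seq_len(config$L), function(l) {
    list(Wq = xavier(d, d), Wk = xavier(d, d), Wv = xavier(d, d),
         We = xavier(d, d), Wo_h = xavier(d, d), Wo_e = xavier(d, d),
         Wf1 = xavier(d, 2L * d), Wf2 = xavier(2L * d, d),
         Wg1 = xavier(d, 2L * d), Wg2 = xavier(2L * d, d),
         bn1h = bn_init(d), bn2h = bn_init(d),
         bn1e = bn_init(d), bn2e = bn_init(d))
  })
  widths <- c(3L * d, config$mlp_hidden)
  head_w <- list()
  for (i in seq_len(length(widths) - 1L)) {
    head_w[[paste0("W", i)]] <- xavier(widths[i], widths[i + 1L])
    head_w[[paste0("b", i)]] <- numeric(widths[i + 1L])
  }
  params <- list(node_embed = init_embed_weights(2L, d),
                 edge_embed = init_embed_weights(2L, d),
                 W_pe = xavier(config$lappe_k, d),
                 layers = layers, head = head_w)
  structure(list(config = config, params = params), class = "gt_model")
}

#' Laplacian positional encodings of an assembly graph
#'
#' Eigenvectors of the Laplacian of the undirected simple version of the
#' graph, taken in ascending eigenvalue order with the trivial first
#' eigenvector dropped. Signs follow a deterministic convention (the entry
#' of largest magnitude is made positive); training randomly re-flips them.
#'
#' @param graph an `assembly_graph` with at least 2 nodes.
#' @param k number of eigenvectors, `k < n_nodes(graph)`.
#' @param normalized use the symmetric normalized Laplacian
#'   `I - D^{-1/2} A D^{-1/2}` (default) or the unnormalized `D - A`.
#' @return m x k matrix with the corresponding eigenvalues in attribute
#'   `"values"`.
#' @export
laplacian_pe <- function(graph, k, normalized = TRUE) {
  m <- n_nodes(graph)
  if (m < 2L) stop("graph must have at least 2 nodes")
  if (k >= m) stop("lappe_k must be smaller than the number of nodes")
  A <- matrix(0, m, m)
  if (n_edges(graph) > 0L) {
    idx <- cbind(graph$edges$source + 1L, graph$edges$target + 1L)
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  diag(A) <- 0
  deg <- rowSums(A)
  if (normalized) {
    dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    Lap <- diag(m) - (dinv %o% dinv) * A
    Lap[deg == 0, ] <- 0
    Lap[, deg == 0] <- 0
    diag(Lap)[deg == 0] <- 0
  } else {
    Lap <- diag(deg) - A
  }
  eg <- eigen(Lap, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  sel <- seq(2L, k + 1L)
  pe <- vecs[, sel, drop = FALSE]
  # deterministic sign: largest-|entry| coordinate positive
  for (j in seq_len(ncol(pe))) {
    i_max <- which.max(abs(pe[, j]))
    if (pe[i_max, j] < 0) pe[, j] <- -pe[, j]
  }
  attr(pe, "values") <- vals[sel]
  pe
}

clamp_mat <- function(x, c) pmin(pmax(x, -c), c)

bn_forward <- function(x, st, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    new_st <- st
    new_st$run_mean <- (1 - momentum) * st$run_mean + momentum * mu
    new_st$run_var <- (1 - momentum) * st$run_var + momentum * v
  } else {
    mu <- st$run_mean
    v <- st$run_var
    new_st <- st
  }
  ivstd <- 1 / sqrt(v + eps)
  xh <- sweep(sweep(x, 2L, mu), 2L, ivstd, "*")
  out <- sweep(sweep(xh, 2L, st$gamma, "*"), 2L, st$beta, "+")
  list(out = out, cache = list(xh = xh, ivstd = ivstd, training = training),
       state = new_st)
}

bn_backward <- function(dy, st, cache) {
  xh <- cache$xh
  dgamma <- colSums(dy * xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2L, st$gamma, "*")
  if (!cache$training) {
    dx <- sweep(dxh, 2L, cache$ivstd, "*")
  } else {
    B <- nrow(xh)
    s1 <- colSums(dxh)
    s2 <- colSums(dxh * xh)
    dx <- sweep(B * dxh - matrix(s1, B, ncol(xh), byrow = TRUE) -
                  xh * matrix(s2, B, ncol(xh), byrow = TRUE),
                2L, cache$ivstd / B, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# one transformer layer; src1/tgt1 are 1-based endpoint indices per edge
layer_forward <- function(Hin, Ein, P, src1, tgt1, cfg, training) {
  m <- nrow(Hin)
  n <- nrow(Ein)
  d <- cfg$d
  headcol <- rep(seq_len(cfg$H), each = cfg$d_k)
  sc <- 1 / sqrt(cfg$d_k)
  cache <- list(Hin = Hin, Ein = Ein, src1 = src1, tgt1 = tgt1, n = n)
  newP <- P

  if (n > 0L) {
    Qm <- Hin %*% P$Wq; Km <- Hin %*% P$Wk; Vm <- Hin %*% P$Wv
    Em <- Ein %*% P$We
    dot <- Qm[tgt1, , drop = FALSE] * Km[src1, , drop = FALSE] * sc
    if (cfg$edge_gate == "multiplicative") {
      S <- dot * Em
    } else {
      S <- dot + Em
    }
    Sc <- clamp_mat(S, cfg$clamp)
    mS <- (S > -cfg$clamp & S < cfg$clamp)
    Lmat <- vapply(seq_len(cfg$H), function(h) {
      rowSums(Sc[, headcol == h, drop = FALSE])
    }, numeric(n))
    Lmat <- matrix(Lmat, nrow = n)
    Lc <- clamp_mat(Lmat, cfg$clamp)
    mL <- (Lmat > -cfg$clamp & Lmat < cfg$clamp)
    expL <- exp(Lc)
    rs <- rowsum(expL, tgt1)
    grp <- match(tgt1, as.integer(rownames(rs)))
    A <- expL / rs[grp, , drop = FALSE]
    Aexp <- A[, headcol, drop = FALSE]
    Vs <- Vm[src1, , drop = FALSE]
    wV <- Vs * Aexp
    agg <- matrix(0, m, d)
    aggr <- rowsum(wV, tgt1)
    agg[as.integer(rownames(aggr)), ] <- aggr
    hatH <- agg %*% P$Wo_h
    hatE <- Sc %*% P$Wo_e
    cache <- c(cache, list(Qm = Qm, Km = Km, Vm = Vm, Em = Em, dot = dot,
                           S = S, Sc = Sc, mS = mS, mL = mL, A = A,
                           Aexp = Aexp, Vs = Vs, agg = agg, grp = grp,
                           headcol = headcol, sc = sc))
  } else {
    hatH <- matrix(0, m, d)
    hatE <- Ein
  }

  r1 <- Hin + hatH
  bn1 <- bn_forward(r1, P$bn1h, training)
  newP$bn1h <- bn1$state
  n1 <- bn1$out
  zf <- n1 %*% P$Wf1; af <- pmax(zf, 0); ff <- af %*% P$Wf2
  r2 <- n1 + ff
  bn2 <- bn_forward(r2, P$bn2h, training)
  newP$bn2h <- bn2$state
  Hout <- bn2$out

  if (n > 0L) {
    e1 <- Ein + hatE
    bne1 <- bn_forward(e1, P$bn1e, training)
    newP$bn1e <- bne1$state
    ne1 <- bne1$out
    zg <- ne1 %*% P$Wg1; ag <- pmax(zg, 0); gg <- ag %*% P$Wg2
    e2 <- ne1 + gg
    bne2 <- bn_forward(e2, P$bn2e, training)
    newP$bn2e <- bne2$state
    Eout <- bne2$out
    cache <- c(cache, list(bne1 = bne1$cache, bne2 = bne2$cache,
                           ne1 = ne1, zg = zg, ag = ag))
  } else {
    Eout <- Ein
  }
  cache <- c(cache, list(bn1 = bn1$cache, bn2 = bn2$cache,
                         n1 = n1, zf = zf, af = af))
  list(H = Hout, E = Eout, cache = cache, P = newP,
       attention = if (n > 0L) cache$A else NULL)
}

layer_backward <- function(dHout, dEout, P, cfg, cache) {
  g <- list()
  n <- cache$n
  # node stream
  b2 <- bn_backward(dHout, P$bn2h, cache$bn2)
  g$bn2h <- list(gamma = b2$dgamma, beta = b2$dbeta)
  dr2 <- b2$dx
  dff <- dr2
  g$Wf2 <- t(cache$af) %*% dff
  daf <- dff %*% t(P$Wf2)
  dzf <- daf * (cache$zf > 0)
  g$Wf1 <- t(cache$n1) %*% dzf
  dn1 <- dr2 + dzf %*% t(P$Wf1)
  b1 <- bn_backward(dn1, P$bn1h, cache$bn1)
  g$bn1h <- list(gamma = b1$dgamma, beta = b1$dbeta)
  dr1 <- b1$dx
  dHin <- dr1
  dhatH <- dr1

  if (n == 0L) {
    d <- cfg$d
    zero <- function(x) array(0, dim = dim(x))
    g$Wq <- zero(P$Wq); g$Wk <- zero(P$Wk); g$Wv <- zero(P$Wv)
    g$We <- zero(P$We); g$Wo_h <- zero(P$Wo_h); g$Wo_e <- zero(P$Wo_e)
    g$Wg1 <- zero(P$Wg1); g$Wg2 <- zero(P$Wg2)
    g$bn1e <- list(gamma = numeric(d), beta = numeric(d))
    g$bn2e <- list(gamma = numeric(d), beta = numeric(d))
    return(list(grads = g, dHin = dHin, dEin = dEout))
  }

  # edge stream
  be2 <- bn_backward(dEout, P$bn2e, cache$bne2)
  g$bn2e <- list(gamma = be2$dgamma, beta = be2$dbeta)
  de2 <- be2$dx
  dgg <- de2
  g$Wg2 <- t(cache$ag) %*% dgg
  dag <- dgg %*% t(P$Wg2)
  dzg <- dag * (cache$zg > 0)
  g$Wg1 <- t(cache$ne1) %*% dzg
  dne1 <- de2 + dzg %*% t(P$Wg1)
  be1 <- bn_backward(dne1, P$bn1e, cache$bne1)
  g$bn1e <- list(gamma = be1$dgamma, beta = be1$dbeta)
  de1 <- be1$dx
  dEin <- de1
  dhatE <- de1

  src1 <- cache$src1; tgt1 <- cache$tgt1
  m <- nrow(cache$Hin)
  headcol <- cache$headcol

  g$Wo_h <- t(cache$agg) %*% dhatH
  dagg <- dhatH %*% t(P$Wo_h)
  g$Wo_e <- t(cache$Sc) %*% dhatE
  dSc <- dhatE %*% t(P$Wo_e)

  dwV <- dagg[tgt1, , drop = FALSE]
  dVs <- dwV * cache$Aexp
  dA_full <- dwV * cache$Vs
  dA <- vapply(seq_len(cfg$H), function(h) {
    rowSums(dA_full[, headcol == h, drop = FALSE])
  }, numeric(n))
  dA <- matrix(dA, nrow = n)
  t1 <- cache$A * dA
  rs <- rowsum(t1, tgt1)
  gs <- rs[cache$grp, , drop = FALSE]
  dLc <- t1 - cache$A * gs
  dLm <- dLc * cache$mL
  dSc <- dSc + dLm[, headcol, drop = FALSE]
  dS <- dSc * cache$mS

  if (cfg$edge_gate == "multiplicative") {
    dEm <- dS * cache$dot
    ddot <- dS * cache$Em
  } else {
    dEm <- dS
    ddot <- dS
  }
  dQt <- ddot * cache$Km[src1, , drop = FALSE] * cache$sc
  dKs <- ddot * cache$Qm[tgt1, , drop = FALSE] * cache$sc

  scatter <- function(x, idx1, m) {
    out <- matrix(0, m, ncol(x))
    rs <- rowsum(x, idx1)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  dQm <- scatter(dQt, tgt1, m)
  dKm <- scatter(dKs, src1, m)
  dVm <- scatter(dVs, src1, m)

  g$Wq <- t(cache$Hin) %*% dQm
  g$Wk <- t(cache$Hin) %*% dKm
  g$Wv <- t(cache$Hin) %*% dVm
  g$We <- t(cache$Ein) %*% dEm
  dHin <- dHin + dQm %*% t(P$Wq) + dKm %*% t(P$Wk) + dVm %*% t(P$Wv)
  dEin <- dEin + dEm %*% t(P$We)

  list(grads = g, dHin = dHin, dEin = dEin)
}

#' Apply one graph-transformer layer
#'
#' Exposed for inspection and testing: updates node and edge feature
#' matrices through the attention, FFN, residual and BatchNorm blocks of a
#' single layer. Nodes with no incoming edges receive no attention message;
#' their pre-norm representation is the residual input unchanged.
#'
#' @param h m x d node feature matrix.
#' @param e n x d edge feature matrix (rows in `edge_id` order).
#' @param params one element of `model$params$layers`.
#' @param graph the `assembly_graph` the features belong to.
#' @param config the model's [gt_config()].
#' @param training use batch statistics (TRUE) or running statistics
#'   (FALSE) in the normalization layers.
#' @return list with updated `h`, `e`, and `attention` (n x H matrix of
#'   softmax weights over each node's in-neighbourhood; each
#'   (target, head) group sums to 1).
#' @export
attention_layer <- function(h, e, params, graph, config, training = FALSE) {
  out <- layer_forward(h, e, params, graph$edges$source + 1L,
                       graph$edges$target + 1L, config, training)
  list(h = out$H, e = out$E, attention = out$attention)
}

head_forward <- function(X, w, n_layers) {
  cache <- list(a = list(X))
  a <- X
  for (i in seq_len(n_layers)) {
    z <- sweep(a %*% w[[paste0("W", i)]], 2L, w[[paste0("b", i)]], "+")
    cache$z[[i]] <- z
    a <- if (i < n_layers) pmax(z, 0) else z
    cache$a[[i + 1L]] <- a
  }
  list(out = a, cache = cache)
}

head_backward <- function(dout, w, cache, n_layers) {
  g <- list()
  da <- dout
  for (i in rev(seq_len(n_layers))) {
    dz <- if (i < n_layers) da * (cache$z[[i]] > 0) else da
    g[[paste0("W", i)]] <- t(cache$a[[i]]) %*% dz
    g[[paste0("b", i)]] <- colSums(dz)
    da <- dz %*% t(w[[paste0("W", i)]])
  }
  list(grads = g, dX = da)
}

# full forward pass; pe already sign-resolved (and sign-flipped in training)
gt_forward <- function(model, node_raw, edge_raw, pe, src1, tgt1,
                       training = FALSE) {
  p <- model$params
  cfg <- model$config
  ne <- embed_forward(node_raw, p$node_embed)
  ee <- embed_forward(edge_raw, p$edge_embed)
  H <- ne$out + pe %*% p$W_pe
  E <- ee$out
  caches <- vector("list", cfg$L)
  newP <- p
  for (l in seq_len(cfg$L)) {
    lf <- layer_forward(H, E, p$layers[[l]], src1, tgt1, cfg, training)
    H <- lf$H; E <- lf$E
    caches[[l]] <- lf$cache
    newP$layers[[l]] <- lf$P
  }
  n <- length(src1)
  X <- cbind(H[src1, , drop = FALSE], H[tgt1, , drop = FALSE], E)
  nh <- length(cfg$mlp_hidden)
  hd <- head_forward(X, p$head, nh)
  logits <- as.numeric(hd$out)
  # saturated sigmoids round to exactly 0/1 in double precision; keep the
  # scores strictly inside (0,1) as the downstream log-losses require
  scores <- pmin(pmax(1 / (1 + exp(-logits)), 1e-12), 1 - 1e-12)
  list(logits = logits, scores = scores,
       cache = list(ne = ne$cache, ee = ee$cache, pe = pe, H = H, E = E,
                    layers = caches, head = hd$cache, X = X,
                    src1 = src1, tgt1 = tgt1, nh = nh),
       params_bn = newP)
}

gt_backward <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$config
  n <- length(dlogits)
  d <- cfg$d
  hb <- head_backward(matrix(dlogits, ncol = 1L), p$head, cache$head, cache$nh)
  dX <- hb$dX
  m <- nrow(cache$H)
  dH <- matrix(0, m, d)
  dE <- dX[, (2L * d + 1L):(3L * d), drop = FALSE]
  src1 <- cache$src1; tgt1 <- cache$tgt1
  if (n > 0L) {
    acc <- function(dh, idx1, part) {
      rs <- rowsum(part, idx1)
      dh[as.integer(rownames(rs)), ] <- dh[as.integer(rownames(rs)), ] + rs
      dh
    }
    dH <- acc(dH, src1, dX[, 1:d, drop = FALSE])
    dH <- acc(dH, tgt1, dX[, (d + 1L):(2L * d), drop = FALSE])
  }
  grads <- list(head = hb$grads, layers = vector("list", cfg$L))
  for (l in rev(seq_len(cfg$L))) {
    lb <- layer_backward(dH, dE, p$layers[[l]], cfg, cache$layers[[l]])
    grads$layers[[l]] <- lb$grads
    dH <- lb$dHin
    dE <- lb$dEin
  }
  grads$W_pe <- t(cache$pe) %*% dH
  nb <- embed_backward(dH, p$node_embed, cache$ne)
  eb <- embed_backward(dE, p$edge_embed, cache$ee)
  grads$node_embed <- nb$grads
  grads$edge_embed <- eb$grads
  grads
}

#' Score every edge of an assembly graph
#'
#' Runs the full scorer in evaluation mode (running BatchNorm statistics,
#' deterministic positional-encoding signs) and returns one probability per
#' edge.
#'
#' @param graph an `assembly_graph`.
#' @param features a `feature_set` from [extract_features()], aligned to the
#'   graph.
#' @param model a `gt_model`.
#' @param pe optional precomputed positional-encoding matrix
#'   (m x `lappe_k`); computed with [laplacian_pe()] when missing.
#' @return numeric vector of edge scores in `(0, 1)`, `edge_id` order.
#' @export
score_edges <- function(graph, features, model, pe = NULL) {
  if (nrow(features$node_raw) != n_nodes(graph) ||
      nrow(features$edge_raw) != n_edges(graph)) {
    stop("features are not aligned to the graph")
  }
  if (is.null(pe)) {
    pe <- laplacian_pe(graph, model$config$lappe_k,
                       normalized = model$config$normalized_laplacian)
  }
  fw <- gt_forward(model, features$node_raw, features$edge_raw, pe,
                   graph$edges$source + 1L, graph$edges$target + 1L,
                   training = FALSE)
  fw$scores
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the full `gt_model` (config and
#' parameters, including BatchNorm running statistics).
#'
#' @param model a `gt_model`
#' @param path checkpoint file path
#' @return `path` invisibly; `load_checkpoint` returns the `gt_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gt_model")) stop("not a gt_model checkpoint")
  model
}
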