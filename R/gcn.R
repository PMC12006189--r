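# Spectral graph-convolutional classifier on binarized connectivity graphs.
#
# Propagation rule per layer: H' = ReLU(D^{-1/2} (A + I) D^{-1/2} H W),
# where D is the degree matrix of A + I. Two graph-convolution layers
# (widths 16 and 32), each followed by a node-count-preserving
# closed-neighborhood max-pooling, then global mean pooling over the 19
# nodes, a 64-unit fully-connected layer with dropout, and 2 output units.

#' One classification sample for the graph classifier
#'
#' @param adjacency 19 x 19 symmetric binary matrix with zero diagonal.
#' @param features 19 x 4 node-feature matrix (time + frequency features).
#' @param label Class label 0/1 (may be NA at prediction time).
#' @param subject_id Optional provenance string.
#' @return Object of class `graph_sample`.
#' @export
graph_sample <- function(adjacency, features, label = NA_integer_,
                         subject_id = NA_character_) {
  adjacency <- as.matrix(adjacency)
  features <- as.matrix(features)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(!adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (nrow(features) != nrow(adjacency))
    stop("features must have one row per node")
  structure(list(adjacency = adjacency, features = features,
                 label = as.integer(label), subject_id = subject_id),
            class = "graph_sample")
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree
#' matrix of `A + I`. Every degree is at least 1, so the normalization is
#' always defined; an isolated node's row equals the identity row, and the
#' spectral radius never exceeds 1.
#'
#' @param A Symmetric binary adjacency matrix with zero diagonal.
#' @return Symmetric normalized matrix of the same size.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (any(A != t(A))) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  dinv * At * rep(dinv, each = nrow(At))
}

#' One graph-convolution layer
#'
#' `ReLU(A_norm %*% H %*% W)` with `A_norm` from [normalize_adjacency()].
#'
#' @param H Node-feature matrix (nodes x d_in).
#' @param A_norm Normalized adjacency (nodes x nodes).
#' @param W Weight matrix (d_in x d_out).
#' @return Non-negative node-feature matrix (nodes x d_out).
#' @export
gcn_layer <- function(H, A_norm, W) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (ncol(A_norm) != nrow(H)) stop("A_norm and H shapes disagree")
  if (ncol(H) != nrow(W)) stop("H and W shapes disagree")
  pmax(A_norm %*% H %*% W, 0)
}

# closed neighborhoods {i} U neighbors(i) as a list of index vectors
closed_neighborhoods <- function(A) {
  lapply(seq_len(nrow(A)), function(i) c(i, which(A[i, ] != 0)))
}

#' Closed-neighborhood max-pooling
#'
#' Node i's row becomes the elementwise maximum over node i and its
#' neighbors. Node count and feature width are preserved, so the pooling
#' sharpens local activations without changing the graph's size.
#'
#' @param H Node-feature matrix.
#' @param A Binary adjacency (or a precomputed neighborhood list).
#' @return Matrix of the same shape as `H`.
#' @export
neighborhood_pool <- function(H, A) {
  nb <- if (is.list(A)) A else closed_neighborhoods(as.matrix(A))
  out <- H
  for (i in seq_along(nb))
    if (length(nb[[i]]) > 1L)
      out[i, ] <- apply(H[nb[[i]], , drop = FALSE], 2L, max)
  out
}

# pooling with argmax bookkeeping for backpropagation
pool_with_argmax <- function(H, nb) {
  out <- H
  arg <- matrix(seq_len(nrow(H)), nrow(H), ncol(H))
  for (i in seq_along(nb)) {
    rows <- nb[[i]]
    if (length(rows) > 1L) {
      sub <- H[rows, , drop = FALSE]
      j <- max.col(t(sub), ties.method = "first")
      arg[i, ] <- rows[j]
      out[i, ] <- sub[cbind(j, seq_len(ncol(H)))]
    }
  }
  list(H = out, arg = arg)
}

#' Training configuration for the graph classifier
#'
#' Defaults: 100 epochs, batch size 64, Adam with learning rate 1e-3,
#' cross-entropy loss over two output units, 50% dropout before the output
#' layer, graph-convolution widths 16 and 32, fully-connected width 64.
#'
#' @param epochs,batch_size,lr,dropout,seed Optimizer settings.
#' @param hidden1,hidden2 Graph-convolution layer widths.
#' @param fc_size Fully-connected layer width.
#' @return List of class `gcn_config`.
#' @export
gcn_config <- function(epochs = 100, batch_size = 64, lr = 1e-3,
                       dropout = 0.5, hidden1 = 16, hidden2 = 32,
                       fc_size = 64, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 dropout = dropout, hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(hidden2), fc_size = as.integer(fc_size),
                 seed = as.integer(seed)),
            class = "gcn_config")
}

gcn_init_weights <- function(d_in, cfg) {
  fan <- function(r, c) {
    s <- sqrt(6 / (r + c))
    matrix(stats::runif(r * c, -s, s), r, c)
  }
  with_seed(cfg$seed, list(
    W0 = fan(d_in, cfg$hidden1),
    W1 = fan(cfg$hidden1, cfg$hidden2),
    Wfc = fan(cfg$fc_size, cfg$hidden2),
    bfc = numeric(cfg$fc_size),
    Wout = fan(2L, cfg$fc_size),
    bout = numeric(2L)
  ))
}

# forward pass for one sample; returns scores and, optionally, the cache
# needed for backpropagation. `mask` is the dropout mask on the FC layer
# (NULL at inference).
gcn_forward_cached <- function(An, nb, X, w, mask = NULL, keep_cache = FALSE) {
  M0 <- An %*% X
  Z1 <- M0 %*% w$W0
  H1 <- pmax(Z1, 0)
  p1 <- pool_with_argmax(H1, nb)
  M1 <- An %*% p1$H
  Z2 <- M1 %*% w$W1
  H2 <- pmax(Z2, 0)
  p2 <- pool_with_argmax(H2, nb)
  g <- colMeans(p2$H)
  a <- drop(w$Wfc %*% g) + w$bfc
  r <- pmax(a, 0)
  rd <- if (is.null(mask)) r else r * mask
  s <- drop(w$Wout %*% rd) + w$bout
  if (!keep_cache) return(list(scores = s))
  list(scores = s, M0 = M0, Z1 = Z1, p1 = p1, M1 = M1, Z2 = Z2, p2 = p2,
       g = g, a = a, rd = rd)
}

#' Forward pass of the graph classifier
#'
#' Deterministic at inference (dropout disabled).
#'
#' @param sample A [graph_sample()].
#' @param weights Trained weights (from [gcn_train()]) or
#'   `gcn_init_weights`.
#' @return Numeric vector of 2 class scores (pre-softmax).
#' @export
gcn_forward <- function(sample, weights) {
  stopifnot(inherits(sample, "graph_sample"))
  An <- normalize_adjacency(sample$adjacency)
  nb <- closed_neighborhoods(sample$adjacency)
  gcn_forward_cached(An, nb, sample$features, weights)$scores
}

# scatter pooled gradients back through the argmax bookkeeping
unpool_grad <- function(dP, arg) {
  dH <- matrix(0, nrow(dP), ncol(dP))
  for (j in seq_len(ncol(dP))) {
    s <- rowsum(dP[, j], arg[, j])
    dH[as.integer(rownames(s)), j] <- s
  }
  dH
}

#' Train the graph classifier
#'
#' Mini-batch Adam training of the two-layer graph-convolutional network
#' with softmax cross-entropy over the two output units. Per-epoch training
#' (and optional validation) loss and accuracy are recorded. Fully seeded:
#' the same data and seed reproduce identical weights.
#'
#' @param samples List of labeled [graph_sample()]s with both classes.
#' @param cfg A [gcn_config()].
#' @param validation Optional list of labeled [graph_sample()]s monitored
#'   each epoch.
#' @return Object of class `gcn_model` with `weights` and `history`.
#' @export
gcn_train <- function(samples, cfg = gcn_config(), validation = NULL) {
  labs <- vapply(samples, function(s) s$label, integer(1))
  if (any(is.na(labs))) stop("all training samples must be labeled")
  if (length(unique(labs)) < 2L)
    stop("training data must contain both classes")
  d_in <- ncol(samples[[1]]$features)
  w <- gcn_init_weights(d_in, cfg)
  pre <- lapply(samples, function(s)
    list(An = normalize_adjacency(s$adjacency),
         nb = closed_neighborhoods(s$adjacency), X = s$features,
         y = s$label))
  pnames <- names(w)
  mom <- lapply(w, function(p) p * 0)
  vel <- lapply(w, function(p) p * 0)
  tstep <- 0L
  n <- length(pre)
  hist_rows <- list()
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L; nb_batches <- 0L
      for (s0 in seq(1L, n, by = cfg$batch_size)) {
        bidx <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
        grads <- lapply(w, function(p) p * 0)
        bloss <- 0
        for (i in bidx) {
          ps <- pre[[i]]
          mask <- (stats::runif(cfg$fc_size) > cfg$dropout) / (1 - cfg$dropout)
          fw <- gcn_forward_cached(ps$An, ps$nb, ps$X, w, mask = mask,
                                   keep_cache = TRUE)
          sc <- fw$scores - max(fw$scores)
          p <- exp(sc) / sum(exp(sc))
          bloss <- bloss - log(max(p[ps$y + 1L], 1e-12))
          if ((which.max(p) - 1L) == ps$y) ep_correct <- ep_correct + 1L
          ds <- p
          ds[ps$y + 1L] <- ds[ps$y + 1L] - 1
          grads$Wout <- grads$Wout + ds %o% fw$rd
          grads$bout <- grads$bout + ds
          dr <- drop(t(w$Wout) %*% ds) * mask * (fw$a > 0)
          grads$Wfc <- grads$Wfc + dr %o% fw$g
          grads$bfc <- grads$bfc + dr
          dg <- drop(t(w$Wfc) %*% dr)
          dP2 <- matrix(dg, nrow(ps$X), length(dg), byrow = TRUE) / nrow(ps$X)
          dH2 <- unpool_grad(dP2, fw$p2$arg)
          dZ2 <- dH2 * (fw$Z2 > 0)
          grads$W1 <- grads$W1 + t(fw$M1) %*% dZ2
          dP1 <- ps$An %*% dZ2 %*% t(w$W1)
          dH1 <- unpool_grad(dP1, fw$p1$arg)
          dZ1 <- dH1 * (fw$Z1 > 0)
          grads$W0 <- grads$W0 + t(fw$M0) %*% dZ1
        }
        grads <- lapply(grads, function(gm) gm / length(bidx))
        gnorm <- sqrt(sum(vapply(grads, function(gm) sum(gm^2), numeric(1))))
        if (gnorm > 5) grads <- lapply(grads, function(gm) gm * 5 / gnorm)
        tstep <- tstep + 1L
        for (pn in pnames) {
          mom[[pn]] <- 0.9 * mom[[pn]] + 0.1 * grads[[pn]]
          vel[[pn]] <- 0.999 * vel[[pn]] + 0.001 * grads[[pn]]^2
          mhat <- mom[[pn]] / (1 - 0.9^tstep)
          vhat <- vel[[pn]] / (1 - 0.999^tstep)
          w[[pn]] <- w[[pn]] - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
        }
        ep_loss <- ep_loss + bloss / length(bidx)
        nb_batches <- nb_batches + 1L
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / nb_batches,
                        train_acc = ep_correct / n, val_loss = NA_real_,
                        val_acc = NA_real_)
      if (!is.null(validation)) {
        ev <- gcn_evaluate_loss(validation, w)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
      }
      hist_rows[[ep]] <- row
    }
  })
  structure(list(weights = w, cfg = cfg,
                 history = do.call(rbind, hist_rows)),
            class = "gcn_model")
}

gcn_evaluate_loss <- function(samples, w) {
  loss <- 0; correct <- 0L
  for (s in samples) {
    sc <- gcn_forward(s, w)
    sc <- sc - max(sc)
    p <- exp(sc) / sum(exp(sc))
    loss <- loss - log(max(p[s$label + 1L], 1e-12))
    if ((which.max(p) - 1L) == s$label) correct <- correct + 1L
  }
  list(loss = loss / length(samples), acc = correct / length(samples))
}

#' Predict classes for graph samples
#'
#' @param model A trained `gcn_model` (or a raw weight list).
#' @param samples List of [graph_sample()]s.
#' @return Data frame with the two class scores and the predicted label.
#' @export
gcn_predict <- function(model, samples) {
  w <- if (inherits(model, "gcn_model")) model$weights else model
  sc <- t(vapply(samples, function(s) gcn_forward(s, w), numeric(2)))
  data.frame(score0 = sc[, 1], score1 = sc[, 2],
             predicted = as.integer(sc[, 2] > sc[, 1]))
}
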