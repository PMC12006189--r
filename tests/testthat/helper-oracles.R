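# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles are deliberately naive transcriptions, kept
# separate from the implementation paths they check.

# naive PLI: double loop over channel pairs, wrapped phase differences
pli_oracle <- function(dat) {
  ph <- t(apply(dat, 1L, function(x) {
    n <- length(x)
    X <- stats::fft(x)
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else h[2:((n + 1) / 2)] <- 2
    Arg(stats::fft(X * h, inverse = TRUE) / n)
  }))
  K <- nrow(ph)
  out <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (k == l) next
    d <- ph[k, ] - ph[l, ]
    d <- (d + pi) %% (2 * pi) - pi
    out[k, l] <- abs(mean(sign(d)))
  }
  out
}

# scalar-loop fusion mapping
mapping_oracle <- function(z) {
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    out[i] <- if (z[i] <= 1) (exp(z[i]) - 1) / (2 * exp(1) - 2)
              else 1 - (exp(2 - z[i]) - 1) / (2 * exp(1) - 2)
  }
  out
}

# mean local clustering coefficient by direct triangle counting
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

# characteristic path length of the largest component via Floyd-Warshall
path_length_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  reach <- is.finite(D)
  comp_sizes <- rowSums(reach)
  members <- which(reach[which.max(comp_sizes), ])
  if (length(members) < 2) return(0)
  sub <- D[members, members]
  mean(sub[upper.tri(sub)])
}

# dense triple-loop graph-convolution layer
gcn_layer_oracle <- function(H, A_norm, W) {
  n <- nrow(H); din <- ncol(H); dout <- ncol(W)
  M <- matrix(0, n, din)
  for (i in seq_len(n)) for (j in seq_len(din))
    for (k in seq_len(n)) M[i, j] <- M[i, j] + A_norm[i, k] * H[k, j]
  O <- matrix(0, n, dout)
  for (i in seq_len(n)) for (j in seq_len(dout))
    for (k in seq_len(din)) O[i, j] <- O[i, j] + M[i, k] * W[k, j]
  pmax(O, 0)
}

# exact two-sided Mann-Whitney p by enumeration of all rank arrangements
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  pooled <- c(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  })
  pl <- mean(us <= u_obs + 1e-9)
  pg <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(pl, pg)))
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# toy labeled segments: class 1 = 10 Hz tones on all channels, class 0 =
# white noise (time-domain separable); classes at 10 vs 30 Hz for the
# frequency extractor are built with `tone_segment`
tone_segment <- function(freq, label, seed, noise = 0.2) {
  set.seed(seed)
  t0 <- (0:639) / 128
  ph <- stats::runif(19, -pi, pi)
  d <- t(sapply(ph, function(p) sin(2 * pi * freq * t0 + p))) +
    noise * matrix(stats::rnorm(19 * 640), 19, 640)
  eeg_segment(d, label = label, subject_id = paste0("s", seed))
}

noise_segment <- function(label, seed) {
  set.seed(seed)
  eeg_segment(matrix(stats::rnorm(19 * 640), 19, 640), label = label,
              subject_id = paste0("s", seed))
}

random_segment <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(19 * 640), 19, 640)
  rownames(m) <- canonical_montage()
  m
}
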