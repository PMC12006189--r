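# Graph-convolutional classifier: normalization, layers, pooling, forward
# pass, and training.

test_that("adjacency normalization has the closed-form special cases", {
  expect_identical(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(a2), matrix(0.5, 2, 2))
  set.seed(4)
  for (i in 1:10) {
    a <- random_adjacency(sample(5:19, 1))
    an <- normalize_adjacency(a)
    expect_equal(an, t(an))
    expect_lte(max(eigen(an, symmetric = TRUE,
                         only.values = TRUE)$values), 1 + 1e-9)
    # isolated nodes keep an identity row
    iso <- which(rowSums(a) == 0)
    for (i0 in iso) expect_equal(an[i0, ], diag(nrow(a))[i0, ])
  }
})

test_that("graph convolution matches the dense triple-loop oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:19, 1)
    a <- random_adjacency(n)
    an <- normalize_adjacency(a)
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 6), 4, 6)
    expect_equal(gcn_layer(H, an, W), gcn_layer_oracle(H, an, W),
                 tolerance = 1e-6)
  }
  # zero adjacency reduces to ReLU(H W); identity W keeps ReLU(H)
  H <- matrix(rnorm(12), 3, 4)
  expect_equal(gcn_layer(H, normalize_adjacency(matrix(0, 3, 3)), diag(4)),
               pmax(H, 0))
  expect_true(all(gcn_layer(-abs(H), diag(3), diag(4)) == 0))
})

test_that("neighborhood pooling uses closed neighborhoods", {
  H <- matrix(rnorm(12), 4, 3)
  expect_identical(neighborhood_pool(H, matrix(0, 4, 4)), H)
  cg <- matrix(1, 4, 4) - diag(4)
  pooled <- neighborhood_pool(H, cg)
  expect_equal(pooled, matrix(apply(H, 2, max), 4, 3, byrow = TRUE))
  expect_identical(neighborhood_pool(pooled, cg), pooled)  # idempotent
})

test_that("forward pass is permutation-equivariant and deterministic", {
  set.seed(6)
  a <- random_adjacency(19)
  X <- matrix(rnorm(76), 19, 4)
  w <- pcohnet:::gcn_init_weights(4, gcn_config(seed = 2))
  s1 <- gcn_forward(graph_sample(a, X), w)
  expect_identical(s1, gcn_forward(graph_sample(a, X), w))
  perm <- sample(19)
  s2 <- gcn_forward(graph_sample(a[perm, perm], X[perm, ]), w)
  expect_equal(s1, s2, tolerance = 1e-9)
  # zero features reduce to the bias pathway
  s0 <- gcn_forward(graph_sample(a, 0 * X), w)
  expect_equal(s0, drop(w$Wout %*% pmax(w$bfc, 0)) + w$bout)
})

test_that("training recovers a separable graph family and is seeded", {
  set.seed(9)
  frontal <- matrix(0, 19, 19)
  frontal[1, 2] <- frontal[2, 1] <- frontal[3, 4] <- frontal[4, 3] <- 1
  posterior <- matrix(0, 19, 19)
  posterior[18, 19] <- posterior[19, 18] <- posterior[13, 14] <-
    posterior[14, 13] <- 1
  noisy <- function(base) {
    a <- base
    i <- sample(5:12, 2)
    a[i[1], i[2]] <- a[i[2], i[1]] <- 1
    a
  }
  # node-identifying features shared across samples plus noise
  ident <- matrix(rnorm(76), 19, 4)
  mk <- function(base, lab) graph_sample(noisy(base),
                                         ident + matrix(rnorm(76, sd = 0.1),
                                                        19, 4), label = lab)
  train <- c(lapply(1:20, function(i) mk(frontal, 1L)),
             lapply(1:20, function(i) mk(posterior, 0L)))
  val <- c(lapply(1:10, function(i) mk(frontal, 1L)),
           lapply(1:10, function(i) mk(posterior, 0L)))
  cfg <- gcn_config(epochs = 60, lr = 1e-2, seed = 5)
  model <- gcn_train(train, cfg, validation = val)
  pred <- gcn_predict(model, val)
  labs <- vapply(val, function(s) s$label, integer(1))
  expect_gte(mean(pred$predicted == labs), 0.9)
  expect_identical(nrow(model$history), 60L)
  model2 <- gcn_train(train, cfg)
  expect_identical(model$weights, model2$weights)
  expect_error(gcn_train(train[1:20], cfg), "both classes")
})

test_that("label-shuffled graph training stays near chance", {
  set.seed(21)
  base1 <- matrix(0, 19, 19); base1[1, 2] <- base1[2, 1] <- 1
  base0 <- matrix(0, 19, 19); base0[18, 19] <- base0[19, 18] <- 1
  ident <- matrix(rnorm(76), 19, 4)
  mk <- function(base, lab) graph_sample(base, ident +
                                           matrix(rnorm(76, sd = 0.1), 19, 4),
                                         label = lab)
  labs <- sample(rep(0:1, each = 20))
  train <- lapply(1:40, function(i)
    mk(if (i <= 20) base1 else base0, labs[i]))
  val <- c(lapply(1:15, function(i) mk(base1, sample(0:1, 1))),
           lapply(1:15, function(i) mk(base0, sample(0:1, 1))))
  model <- gcn_train(train, gcn_config(epochs = 40, lr = 1e-2, seed = 8))
  pred <- gcn_predict(model, val)
  vl <- vapply(val, function(s) s$label, integer(1))
  expect_true(abs(mean(pred$predicted == vl) - 0.5) <=
                2.576 * sqrt(0.25 / 30))
})
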