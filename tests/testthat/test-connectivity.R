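# Phase extraction, PLI, Welch cross-spectra, coherence, the fusion
# mapping, and binarization.

test_that("instantaneous phase of a pure tone advances linearly", {
  t0 <- (0:639) / 128
  x <- rbind(sin(2 * pi * 10 * t0), cos(2 * pi * 10 * t0))
  ph <- instantaneous_phase(x)
  dph <- diff(ph[1, ])
  dph <- (dph + pi) %% (2 * pi) - pi
  interior <- 30:600
  expect_lt(max(abs(dph[interior] - 2 * pi * 10 / 128)), 1e-3)
  # cos leads sin by pi/2
  d <- (ph[2, interior] - ph[1, interior] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(d - pi / 2)), 0.02)
  expect_error(instantaneous_phase(rbind(x[1, ], 0 * t0)), "constant")
})

test_that("PLI matches the elementwise oracle and its analytic cases", {
  for (s in 1:5) {
    m <- random_segment(s)
    got <- pli_matrix(m)$values
    expect_lt(max(abs(got - pli_oracle(m))), 1e-12)
  }
  # identical channels: sign(0) = 0 everywhere
  m <- random_segment(7)
  m[2, ] <- m[1, ]
  expect_identical(pli_matrix(m)$values[1, 2], 0)
  # constant lag pi/4 between equal-frequency sinusoids
  t0 <- (0:639) / 128
  x <- rbind(sin(2 * pi * 8 * t0), sin(2 * pi * 8 * t0 - pi / 4))
  expect_equal(pli_matrix(x)$values[1, 2], 1, tolerance = 1e-6)
})

test_that("Welch cross-spectra behave on canonical inputs", {
  set.seed(42)
  flat <- replicate(50, {
    cs <- cross_spectra(matrix(rnorm(2 * 640), 2), fs = 128)
    Re(cs$cross[1, 1, ])
  })
  m <- rowMeans(flat)
  expect_lt(max(m) / min(m), 1.5)  # flat auto-spectrum across the grid
  # duplicated channels: Cauchy-Schwarz equality at every frequency
  x <- matrix(rnorm(640), 1)[c(1, 1), ]
  cs <- cross_spectra(x, fs = 128)
  expect_equal(Mod(cs$cross[1, 2, ])^2,
               Re(cs$cross[1, 1, ]) * Re(cs$cross[2, 2, ]),
               tolerance = 1e-9)
  # tone peaks at the nearest grid frequency
  t0 <- (0:639) / 128
  cs2 <- cross_spectra(rbind(sin(2 * pi * 10 * t0), rnorm(640)), fs = 128)
  expect_equal(cs2$freqs[which.max(Re(cs2$cross[1, 1, ]))], 10)
})

test_that("coherence follows the signal-plus-noise prediction", {
  set.seed(5)
  # per-frequency SNR r gives true coherence C = r/(1+r); averaging navg
  # Welch windows biases the estimate upward by about (1-C)^2/navg
  for (r in c(0.5, 2)) {
    vals <- replicate(30, {
      x <- rnorm(640)
      y <- x + rnorm(640) / sqrt(r)
      coh_matrix(rbind(x, y), fs = 128)$values[1, 2]
    })
    C <- r / (1 + r)
    expect_equal(mean(vals), C + (1 - C)^2 / 9, tolerance = 0.04)
  }
  # duplicated channels: coherence 1 off-diagonal
  x <- rnorm(640)
  expect_equal(coh_matrix(rbind(x, x), fs = 128)$values[1, 2], 1,
               tolerance = 1e-9)
})

test_that("fusion mapping has the stated endpoint, continuity and symmetry", {
  expect_identical(mapping_F(0), 0)
  expect_identical(mapping_F(2), 1)
  lhs <- (exp(1) - 1) / (2 * exp(1) - 2)
  expect_identical(lhs, 0.5)
  expect_lt(abs(mapping_F(1) - 0.5), 1e-15)
  expect_lt(abs(mapping_F(1 + 1e-12) - mapping_F(1)), 1e-11)
  z <- seq(0, 2, length.out = 2001)
  fz <- mapping_F(z)
  expect_true(all(diff(fz) > 0))
  expect_lt(max(abs(fz + mapping_F(2 - z) - 1)), 1e-12)
  expect_lt(max(abs(fz - mapping_oracle(z))), 1e-15)
  expect_error(mapping_F(-0.1), "\\[0, 2\\]")
  expect_error(mapping_F(2.1), "\\[0, 2\\]")
})

test_that("fused matrix equals the scalar-loop oracle and handles bounds", {
  set.seed(8)
  for (i in 1:5) {
    p <- matrix(runif(19 * 19, 0, 0.9), 19)
    p <- (p + t(p)) / 2; diag(p) <- 0
    c0 <- matrix(runif(19 * 19, 0, 0.9), 19)
    c0 <- (c0 + t(c0)) / 2; diag(c0) <- 0
    pli <- connectivity_matrix(p, "PLI")
    coh <- connectivity_matrix(c0, "COH")
    got <- pcoh_matrix(pli, coh)$values
    want <- matrix(mapping_oracle(pli$values + coh$values), 19)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_true(all(diag(got) == 0))
  }
  z <- connectivity_matrix(matrix(0, 19, 19), "PLI")
  z2 <- connectivity_matrix(matrix(0, 19, 19), "COH")
  expect_true(all(pcoh_matrix(z, z2)$values == 0))
  one <- matrix(1, 19, 19); diag(one) <- 0
  full <- pcoh_matrix(connectivity_matrix(one, "PLI"),
                      connectivity_matrix(one, "COH"))$values
  expect_equal(full[1, 2], 1)
  expect_error(pcoh_matrix(z2, z), "expects one PLI and one COH")
})

test_that("binarization respects the >= boundary", {
  v <- matrix(0, 19, 19)
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.49
  pc <- connectivity_matrix(v, "PCOH")
  b <- binarize(pc, 0.5)
  expect_identical(b$adjacency[1, 2], 1)
  expect_identical(b$adjacency[1, 3], 0)
  all1 <- binarize(connectivity_matrix(matrix(0.3, 19, 19) -
                                         diag(0.3, 19), "PCOH"), 0)
  expect_true(all(all1$adjacency[upper.tri(all1$adjacency)] == 1))
  keep1 <- binarize(pc, 1)
  expect_true(all(keep1$adjacency == 0))
  expect_error(binarize(pc, 1.2), "threshold")
})

test_that("connectivity matrices are symmetric, zero-diagonal and bounded", {
  for (s in 1:3) {
    m <- random_segment(100 + s)
    for (cm in list(pli_matrix(m), coh_matrix(m, fs = 128),
                    segment_pcoh(eeg_segment(m)))) {
      v <- cm$values
      expect_identical(v, t(v))
      expect_true(all(diag(v) == 0))
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})
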