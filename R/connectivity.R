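# Functional connectivity: phase lag index, magnitude-squared coherence,
# their nonlinear fusion (P-COH), and binarization.

#' Connectivity matrix container
#'
#' Symmetric 19 x 19 matrix with zero diagonal and entries in \[0, 1\].
#'
#' @param values 19 x 19 numeric matrix.
#' @param kind One of "PLI", "COH", "PCOH".
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("PLI", "COH", "PCOH")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-9)
    stop("connectivity matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop("connectivity values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, kind = kind),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix %s> %d x %d, mean off-diagonal %.3f\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

# Analytic signal via the frequency domain (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel
#'
#' Phase of the analytic signal (Hilbert transform) of each channel,
#' wrapped to (-pi, pi].
#'
#' @param segment An [eeg_segment()] (or any channels x samples matrix).
#' @return Matrix of phases, channels x samples.
#' @export
instantaneous_phase <- function(segment) {
  dat <- if (inherits(segment, "eeg_segment")) segment$data else as.matrix(segment)
  v <- apply(dat, 1L, stats::var)
  if (any(v == 0))
    stop("constant channel(s) ", paste(which(v == 0), collapse = ", "),
         ": instantaneous phase undefined")
  ph <- t(apply(dat, 1L, function(x) Arg(analytic_signal(x))))
  # Arg() returns (-pi, pi]; make the boundary convention explicit
  ph[ph <= -pi] <- pi
  dimnames(ph) <- dimnames(dat)
  ph
}

#' Phase lag index matrix
#'
#' For channels k and l, `PLI = |mean(sign(phi_k - phi_l))|` over the
#' segment's samples, with the phase difference wrapped to `[-pi, pi)` and
#' `sign(0) = 0`. Identical channels therefore give
#' 0, and a constant nonzero lag gives 1. Insensitive to zero-lag
#' (volume-conducted) synchrony.
#'
#' @param segment An [eeg_segment()] or channels x samples matrix.
#' @return A [connectivity_matrix()] of kind "PLI".
#' @export
pli_matrix <- function(segment) {
  ph <- instantaneous_phase(segment)
  K <- nrow(ph)
  s <- matrix(0, K, K)
  for (k in seq_len(K - 1L)) {
    d <- sweep(ph[(k + 1L):K, , drop = FALSE], 2L, ph[k, ])
    d <- (d + pi) %% (2 * pi) - pi  # wrap the difference to [-pi, pi)
    s[k, (k + 1L):K] <- abs(rowMeans(sign(d)))
  }
  s <- s + t(s)
  dimnames(s) <- list(rownames(ph), rownames(ph))
  connectivity_matrix(s, kind = "PLI")
}

#' Welch-averaged auto- and cross-spectra
#'
#' Hann-tapered Welch estimate on a shared frequency grid, restricted to
#' the analysis band. Averaging over windows is essential: a single
#' periodogram makes magnitude-squared coherence identically 1.
#'
#' @param segment An [eeg_segment()] or channels x samples matrix.
#' @param n_window Samples per Welch window (default 128).
#' @param overlap Fractional window overlap (default 0.5).
#' @param band Frequency band (Hz) retained on the grid.
#' @param fs Sampling rate; taken from the segment when available.
#' @return List with `freqs` (Hz), `cross` (K x K x F complex array,
#'   auto-spectra on the diagonal) and `n_avg` (number of windows).
#' @export
cross_spectra <- function(segment, n_window = 128, overlap = 0.5,
                          band = c(0.5, 60), fs = NULL) {
  dat <- if (inherits(segment, "eeg_segment")) segment$data else as.matrix(segment)
  if (is.null(fs)) fs <- if (inherits(segment, "eeg_segment")) segment$fs else 128
  n <- ncol(dat)
  K <- nrow(dat)
  if (n_window > n) stop("Welch window longer than the segment")
  step <- max(1L, as.integer(round(n_window * (1 - overlap))))
  starts <- seq(1L, n - n_window + 1L, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_window) / (n_window + 1))
  freqs_all <- (seq_len(n_window) - 1) * fs / n_window
  keep <- which(freqs_all >= band[1] & freqs_all <= band[2] &
                  freqs_all <= fs / 2)
  acc <- array(0i, dim = c(K, K, length(keep)))
  for (s0 in starts) {
    seg <- dat[, s0:(s0 + n_window - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(stats::mvfft(t(seg * rep(taper, each = K))))[, keep, drop = FALSE]
    for (j in seq_along(keep))
      acc[, , j] <- acc[, , j] + X[, j] %*% Conj(t(X[, j]))
  }
  acc <- acc / length(starts)
  list(freqs = freqs_all[keep], cross = acc, n_avg = length(starts))
}

#' Magnitude-squared coherence matrix
#'
#' For channels k and l, `COH_kl(f) = |S_kl(f)|^2 / (S_kk(f) S_ll(f))` is
#' averaged over all retained in-band frequencies; the diagonal is forced
#' to zero.
#'
#' @param segment An [eeg_segment()] or channels x samples matrix.
#' @param ... Passed to [cross_spectra()].
#' @return A [connectivity_matrix()] of kind "COH".
#' @export
coh_matrix <- function(segment, ...) {
  cs <- cross_spectra(segment, ...)
  K <- dim(cs$cross)[1]
  Fn <- dim(cs$cross)[3]
  acc <- matrix(0, K, K)
  for (j in seq_len(Fn)) {
    S <- cs$cross[, , j]
    auto <- Re(diag(S))
    if (any(auto <= 0))
      stop("zero auto-spectrum at ", cs$freqs[j],
           " Hz: coherence undefined")
    acc <- acc + Mod(S)^2 / (auto %o% auto)
  }
  vals <- acc / Fn
  vals <- pmin(vals, 1)
  diag(vals) <- 0
  labs <- if (inherits(segment, "eeg_segment")) rownames(segment$data)
          else rownames(segment)
  dimnames(vals) <- list(labs, labs)
  connectivity_matrix(vals, kind = "COH")
}

#' Piecewise-exponential fusion mapping
#'
#' Maps the sum PLI + COH from \[0, 2\] onto \[0, 1\]:
#' `F(z) = (exp(z) - 1) / (2e - 2)` for `z` in \[0, 1\] and
#' `F(z) = 1 - (exp(2 - z) - 1) / (2e - 2)` for `z` in (1, 2\].
#' Continuous, strictly increasing, with `F(0) = 0`, `F(1) = 1/2`,
#' `F(2) = 1`; it shrinks small fused values and amplifies large ones,
#' sharpening the contrast of the fused connectivity.
#'
#' @param z Numeric vector with values in \[0, 2\].
#' @return Mapped values in \[0, 1\].
#' @export
mapping_F <- function(z) {
  if (any(!is.finite(z)) || any(z < 0) || any(z > 2))
    stop("mapping_F is defined on [0, 2]")
  denom <- 2 * exp(1) - 2
  ifelse(z <= 1, (exp(z) - 1) / denom, 1 - (exp(2 - z) - 1) / denom)
}

#' Fused phase/amplitude connectivity matrix (P-COH)
#'
#' Elementwise `F(PLI + COH)` of two connectivity matrices from the same
#' segment. The diagonal stays zero automatically since `F(0) = 0`.
#'
#' @param pli A [connectivity_matrix()] of kind "PLI".
#' @param coh A [connectivity_matrix()] of kind "COH".
#' @return A [connectivity_matrix()] of kind "PCOH".
#' @export
pcoh_matrix <- function(pli, coh) {
  stopifnot(inherits(pli, "connectivity_matrix"),
            inherits(coh, "connectivity_matrix"))
  if (pli$kind != "PLI" || coh$kind != "COH")
    stop("pcoh_matrix expects one PLI and one COH matrix, got ",
         pli$kind, " and ", coh$kind)
  if (!all(dim(pli$values) == dim(coh$values)))
    stop("matrix dimensions disagree")
  connectivity_matrix(mapping_F(pli$values + coh$values), kind = "PCOH")
}

#' Binarize a fused connectivity matrix
#'
#' Entries greater than or equal to the threshold become 1, smaller
#' entries 0; the diagonal stays 0.
#'
#' @param pcoh A [connectivity_matrix()] of kind "PCOH".
#' @param threshold Cutoff in \[0, 1\].
#' @return List with `adjacency` (0/1 matrix) and `threshold_used`.
#' @export
binarize <- function(pcoh, threshold) {
  stopifnot(inherits(pcoh, "connectivity_matrix"))
  if (pcoh$kind != "PCOH") stop("binarize expects a PCOH matrix")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  adj <- (pcoh$values >= threshold) * 1
  diag(adj) <- 0
  list(adjacency = adj, threshold_used = threshold)
}

#' Fused connectivity of one segment
#'
#' Convenience wrapper: PLI, COH and their fusion in one call.
#'
#' @param segment An [eeg_segment()].
#' @param ... Passed to [cross_spectra()] via [coh_matrix()].
#' @return A [connectivity_matrix()] of kind "PCOH".
#' @export
segment_pcoh <- function(segment, ...) {
  pcoh_matrix(pli_matrix(segment), coh_matrix(segment, ...))
}
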