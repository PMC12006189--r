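# Per-channel time-domain (LSTM) and frequency-domain (CNN) feature
# extractors. Both are applied per channel with shared weights: every
# channel's 640-sample sequence (or 640-point magnitude spectrum) is one
# training example carrying its segment's label, and the 2-unit pre-softmax
# output activations become that channel's feature pair. Stacking the 19
# channels gives the 19 x 2 time and frequency feature matrices, which are
# concatenated into the 19 x 4 node-feature matrix of the graph classifier.

#' Training configuration for the feature extractors
#'
#' Defaults follow the standard recipe used throughout the package: 10
#' epochs, batch size 32, adaptive-moment (Adam) optimization of a
#' cross-entropy loss over two output units, 50% dropout, LSTM hidden size
#' 128 with a 64-unit fully-connected layer.
#'
#' @param epochs,batch_size,lr,dropout,seed Optimizer settings.
#' @param hidden LSTM hidden-state width.
#' @param fc_size Fully-connected layer width.
#' @return List of class `extractor_config`.
#' @export
extractor_config <- function(epochs = 10, batch_size = 32, lr = 1e-3,
                             dropout = 0.5, hidden = 128, fc_size = 64,
                             seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 dropout = dropout, hidden = as.integer(hidden),
                 fc_size = as.integer(fc_size), seed = as.integer(seed)),
            class = "extractor_config")
}

# per-channel standardization (zero mean, unit variance); constant
# channels map to zeros
standardize_channels <- function(dat) {
  mu <- rowMeans(dat)
  sdv <- apply(dat, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  (dat - mu) / sdv
}

#' One step of the LSTM recurrence (reference implementation)
#'
#' Gate updates of a standard LSTM cell with logistic gate activations and
#' tanh candidate/output nonlinearities:
#' forget `f = sigma(W_f [h, x] + b_f)`, input `i = sigma(W_i [h, x] + b_i)`,
#' candidate `g = tanh(W_C [h, x] + b_C)`, cell `C' = f * C + i * g`,
#' output `o = sigma(W_o [h, x] + b_o)`, hidden `h' = o * tanh(C')`.
#' This plain-R transcription defines the semantics the compiled trainer
#' must reproduce.
#'
#' @param state List with vectors `h` and `C` of equal length.
#' @param x_t Scalar input at this step.
#' @param w List with matrices `W_f`, `W_i`, `W_C`, `W_o` (rows = hidden
#'   size, cols = hidden size + 1) and bias vectors `b_f`, `b_i`, `b_C`,
#'   `b_o`.
#' @return Updated state list with `h` and `C`.
#' @export
lstm_step <- function(state, x_t, w) {
  h <- state$h
  C <- state$C
  n <- length(h)
  for (nm in c("W_f", "W_i", "W_C", "W_o"))
    if (!all(dim(w[[nm]]) == c(n, n + 1L)))
      stop(nm, " must be ", n, " x ", n + 1L)
  for (nm in c("b_f", "b_i", "b_C", "b_o"))
    if (length(w[[nm]]) != n) stop(nm, " must have length ", n)
  z <- c(h, x_t)
  sig <- function(x) 1 / (1 + exp(-x))
  f <- sig(drop(w$W_f %*% z) + w$b_f)
  i <- sig(drop(w$W_i %*% z) + w$b_i)
  g <- tanh(drop(w$W_C %*% z) + w$b_C)
  o <- sig(drop(w$W_o %*% z) + w$b_o)
  C_new <- f * C + i * g
  list(h = o * tanh(C_new), C = C_new)
}

segment_labels <- function(segments) {
  labs <- vapply(segments, function(s) s$label, integer(1))
  if (any(is.na(labs))) stop("all segments must carry a class label")
  labs
}

#' Train the time-domain (LSTM) feature extractor
#'
#' One shared model over all channels: each channel's standardized
#' 640-sample sequence is a training example labeled with its segment's
#' class. Architecture: LSTM(hidden) -> dropout -> FC(64, ReLU) -> dropout
#' -> 2 output units, trained with softmax cross-entropy and Adam.
#'
#' @param segments List of labeled [eeg_segment()]s with both classes
#'   present.
#' @param cfg An [extractor_config()].
#' @return Object of class `time_extractor` with the trained weights and
#'   per-epoch loss/accuracy history.
#' @export
train_time_extractor <- function(segments, cfg = extractor_config()) {
  labs <- segment_labels(segments)
  if (length(unique(labs)) < 2L)
    stop("training data must contain both classes")
  X <- do.call(cbind, lapply(segments, function(s)
    t(standardize_channels(s$data))))
  y <- rep(labs, each = nrow(segments[[1]]$data))
  fit <- cpp_lstm_train(X, y, cfg$hidden, cfg$fc_size, cfg$epochs,
                        cfg$batch_size, cfg$lr, cfg$dropout, cfg$seed)
  structure(c(fit, list(cfg = cfg)), class = "time_extractor")
}

#' Time-domain node features of one segment
#'
#' @param segment An [eeg_segment()].
#' @param model A trained `time_extractor`.
#' @return 19 x 2 matrix of pre-softmax output activations, rows in
#'   canonical channel order.
#' @export
time_features <- function(segment, model) {
  if (!inherits(model, "time_extractor")) stop("model must be a trained time_extractor")
  X <- t(standardize_channels(segment$data))
  out <- cpp_lstm_apply(X, model$W, model$b, model$Wfc, model$bfc,
                        model$Wout, model$bout, model$hidden)
  rownames(out) <- rownames(segment$data)
  out
}

#' Magnitude spectrum of every channel
#'
#' Full-length 640-point discrete Fourier transform magnitudes per channel
#' (both conjugate halves retained), the input representation of the
#' frequency-domain extractor.
#'
#' @param segment An [eeg_segment()] or channels x samples matrix.
#' @return Non-negative channels x 640 matrix.
#' @export
spectrum_matrix <- function(segment) {
  dat <- if (inherits(segment, "eeg_segment")) segment$data else as.matrix(segment)
  out <- Mod(t(stats::mvfft(t(dat))))
  dimnames(out) <- dimnames(dat)
  out
}

# per-channel max-normalization of spectra (scale stability for the CNN)
normalize_spectra <- function(spec) {
  mx <- apply(spec, 1L, max)
  mx[mx == 0] <- 1
  spec / mx
}

#' Train the frequency-domain (CNN) feature extractor
#'
#' One shared per-channel model on max-normalized 640-point magnitude
#' spectra: conv(16 filters, length-5 kernel, same padding, ReLU) ->
#' dropout -> maxpool(2) -> conv(32, length-5, ReLU) -> dropout ->
#' maxpool(2) -> flatten -> FC(64, ReLU) -> dropout -> 2 output units,
#' trained with softmax cross-entropy and Adam.
#'
#' @param segments List of labeled [eeg_segment()]s.
#' @param cfg An [extractor_config()] (`hidden` is ignored here).
#' @return Object of class `freq_extractor`.
#' @export
train_freq_extractor <- function(segments, cfg = extractor_config()) {
  labs <- segment_labels(segments)
  if (length(unique(labs)) < 2L)
    stop("training data must contain both classes")
  X <- do.call(cbind, lapply(segments, function(s)
    t(normalize_spectra(spectrum_matrix(s)))))
  y <- rep(labs, each = nrow(segments[[1]]$data))
  fit <- cpp_cnn_train(X, y, cfg$epochs, cfg$batch_size, cfg$lr,
                       cfg$dropout, cfg$seed)
  structure(c(fit, list(cfg = cfg)), class = "freq_extractor")
}

#' Frequency-domain node features of one segment
#'
#' @param segment An [eeg_segment()].
#' @param model A trained `freq_extractor`.
#' @return 19 x 2 matrix of pre-softmax output activations.
#' @export
freq_features <- function(segment, model) {
  if (!inherits(model, "freq_extractor")) stop("model must be a trained freq_extractor")
  X <- t(normalize_spectra(spectrum_matrix(segment)))
  out <- cpp_cnn_apply(X, model$W1, model$b1, model$W2, model$b2,
                       model$Wfc, model$bfc, model$Wout, model$bout)
  rownames(out) <- rownames(segment$data)
  out
}

#' Concatenate time and frequency features into the node-feature matrix
#'
#' @param t_feat 19 x 2 time-domain feature matrix.
#' @param f_feat 19 x 2 frequency-domain feature matrix.
#' @return 19 x 4 matrix; columns 1-2 are the time features, 3-4 the
#'   frequency features.
#' @export
concat_features <- function(t_feat, f_feat) {
  if (!all(dim(t_feat) == c(19L, 2L)) || !all(dim(f_feat) == c(19L, 2L)))
    stop("both feature matrices must be 19 x 2")
  cbind(t_feat, f_feat)
}

#' Save or load a trained extractor checkpoint
#'
#' Checkpoints carry a format-version header so stale files are rejected
#' on load.
#'
#' @param model A trained `time_extractor` or `freq_extractor`.
#' @param path Checkpoint file path.
#' @return `load_extractor` returns the model; `save_extractor` the path,
#'   invisibly.
#' @export
save_extractor <- function(model, path) {
  if (!inherits(model, c("time_extractor", "freq_extractor")))
    stop("model must be a trained extractor")
  saveRDS(list(format = "pcohnet-extractor", version = 1L,
               class = class(model)[1], model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pcohnet-extractor"))
    stop("not an extractor checkpoint: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported checkpoint version ", obj$version)
  structure(obj$model, class = obj$class)
}
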