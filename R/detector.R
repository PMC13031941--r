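#' Detector configuration
#'
#' Architecture and training schedule for the binary pulse-presence
#' classifier: a convolutional feature extractor, global average pooling,
#' a classification head of two fully connected layers (512 and 256 units,
#' rectified-linear activations) with dropout rates 0.5 and 0.2, and a
#' two-unit softmax output. Dense and convolutional weights are initialized
#' Glorot-uniform with zero biases; training minimizes categorical
#' cross-entropy with an adaptive-moment (Adam) optimizer under a staircase
#' exponential learning-rate decay (initial 0.001, factor 0.75 every 90
#' steps).
#'
#' @param backbone `"small_conv"`: a compact stack of strided 3x3
#'   convolution + ReLU blocks sized to train on one CPU in minutes.
#' @param conv_filters integer vector of filters per convolution block.
#' @param head_widths widths of the two fully connected layers.
#' @param dropout_rates dropout rates after each head layer, in \[0, 1).
#' @param n_classes number of softmax outputs (2: absence, presence).
#' @param lr_initial,lr_decay,lr_steps staircase learning-rate schedule:
#'   rate at step k is `lr_initial * lr_decay^floor(k / lr_steps)`.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed pinning initialization, shuffling and dropout.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(backbone = "small_conv",
                            conv_filters = c(16L, 32L, 64L),
                            head_widths = c(512L, 256L),
                            dropout_rates = c(0.5, 0.2),
                            n_classes = 2L,
                            lr_initial = 0.001, lr_decay = 0.75,
                            lr_steps = 90L,
                            batch_size = 32L, epochs = 20L, seed = 1L) {
  stopifnot(all(dropout_rates >= 0), all(dropout_rates < 1),
            length(head_widths) == length(dropout_rates))
  if (!identical(backbone, "small_conv"))
    stop("unknown backbone: ", backbone)
  structure(list(backbone = backbone, conv_filters = as.integer(conv_filters),
                 head_widths = as.integer(head_widths),
                 dropout_rates = dropout_rates, n_classes = as.integer(n_classes),
                 lr_initial = lr_initial, lr_decay = lr_decay,
                 lr_steps = as.integer(lr_steps),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "detector_config")
}

#' Staircase learning-rate schedule
#'
#' @param step 0-based optimizer step.
#' @param initial initial learning rate.
#' @param decay multiplicative decay factor.
#' @param every steps between decays.
#' @return learning rate `initial * decay^floor(step / every)`.
#' @export
lr_schedule <- function(step, initial = 0.001, decay = 0.75, every = 90) {
  initial * decay^floor(step / every)
}

#' Build an untrained detector
#'
#' Assembles feature extractor -> global average pool -> 512 -> dropout 0.5
#' -> 256 -> dropout 0.2 -> softmax(2) with Glorot-uniform weights (seeded
#' by the config) and zero biases.
#'
#' @param config a [detector_config()].
#' @param input_shape tensor shape (time, frequency, channels) fed to the
#'   network.
#' @return an object of class `detector`.
#' @export
build_detector <- function(config = detector_config(),
                           input_shape = c(97L, 90L, 3L)) {
  stopifnot(inherits(config, "detector_config"))
  with_seed(config$seed, {
    layers <- list()
    shape <- as.integer(input_shape)
    for (f in config$conv_filters) {
      l <- nn_conv(shape, f, kernel = 3L, stride = 2L)
      layers <- c(layers, list(l), list(nn_relu()))
      shape <- l$shape_out
    }
    layers <- c(layers, list(nn_gap(shape)))
    n_in <- shape[3]
    for (k in seq_along(config$head_widths)) {
      layers <- c(layers, list(nn_dense(n_in, config$head_widths[k])),
                  list(nn_relu()),
                  list(nn_dropout(config$dropout_rates[k])))
      n_in <- config$head_widths[k]
    }
    layers <- c(layers, list(nn_dense(n_in, config$n_classes)))
    structure(list(layers = layers, config = config,
                   input_shape = as.integer(input_shape),
                   history = NULL, trained = FALSE),
              class = "detector")
  })
}

#' Number of trainable parameters
#'
#' @param detector a [build_detector()] object.
#' @return total count of weights and biases.
#' @export
count_params <- function(detector) nn_count_params(detector$layers)

as_input_matrix <- function(x, input_shape) {
  d <- prod(input_shape)
  if (is.matrix(x)) {
    if (nrow(x) != d) stop("input rows do not match the detector input shape")
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    if (!all(dim(x) == input_shape)) stop("input shape mismatch")
    return(matrix(as.vector(x), d, 1))
  }
  stop("frames must be a (prod(shape) x n) matrix or a single tensor")
}

#' Train the detector
#'
#' Minimizes categorical cross-entropy over shuffled minibatches with Adam
#' and the staircase learning-rate schedule; the config seed pins shuffling
#' and dropout so a rerun reproduces the training history exactly.
#'
#' @param detector a [build_detector()] object.
#' @param x frames: matrix with one flattened input tensor per column (as
#'   from [frontend_frames()]).
#' @param labels binary vector (1 = pulse present) of length `ncol(x)`.
#' @param quiet suppress per-epoch progress.
#' @return the detector with trained weights, `trained = TRUE`, and
#'   `history` (tibble: epoch, loss, accuracy, lr at epoch end).
#' @export
train_detector <- function(detector, x, labels, quiet = TRUE) {
  stopifnot(inherits(detector, "detector"))
  cfg <- detector$config
  x <- as_input_matrix(x, detector$input_shape)
  labels <- as.integer(labels)
  if (length(labels) != ncol(x)) stop("labels must match frame count")
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  n <- ncol(x)
  Y_full <- rbind(1 - labels, labels)  # one-hot: row 1 absent, row 2 present
  with_seed(cfg$seed + 1L, {
    layers <- detector$layers
    state <- nn_adam_init(layers)
    step <- 0L
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- acc <- numeric(0)
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- x[, bi, drop = FALSE]
        Yb <- Y_full[, bi, drop = FALSE]
        fw <- nn_forward(layers, Xb, training = TRUE)
        P <- nn_softmax(fw$out)
        losses <- c(losses, -mean(log(pmax(colSums(P * Yb), 1e-12))))
        acc <- c(acc, mean((P[2, ] >= 0.5) == (Yb[2, ] == 1)))
        dZ <- (P - Yb) / ncol(Xb)
        grads <- nn_backward(layers, fw$caches, dZ)
        lr <- lr_schedule(step, cfg$lr_initial, cfg$lr_decay, cfg$lr_steps)
        upd <- nn_adam_step(layers, grads, state, lr, step + 1L)
        layers <- upd$layers; state <- upd$state
        step <- step + 1L
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                   accuracy = mean(acc),
                                   lr = lr_schedule(step - 1L, cfg$lr_initial,
                                                    cfg$lr_decay, cfg$lr_steps))
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep,
                        mean(losses), mean(acc)))
    }
    detector$layers <- layers
    detector$history <- do.call(rbind, hist)
    detector$trained <- TRUE
    detector
  })
}

#' Predict pulse-presence probabilities
#'
#' Frames are classified independently of chronological order; inference is
#' deterministic (dropout disabled).
#'
#' @param detector a (trained) detector.
#' @param x frames as in [train_detector()].
#' @return numeric vector of pulse-presence probabilities in \[0, 1\]; the
#'   full softmax matrix (rows: absent, present) is attached as attribute
#'   `"probs"`.
#' @export
predict_detector <- function(detector, x) {
  x <- as_input_matrix(x, detector$input_shape)
  P <- nn_softmax(nn_forward(detector$layers, x, training = FALSE)$out)
  out <- P[2, ]
  attr(out, "probs") <- P
  out
}

#' Convert probabilities to binary detections
#'
#' A frame counts as a detection when its probability is greater than or
#' equal to the threshold (ties count positive).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param threshold decision threshold in \[0, 1\].
#' @return integer vector of 0/1 detections.
#' @export
classify_detections <- function(probabilities, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must be in [0, 1]")
  as.integer(probabilities >= threshold)
}
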