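#' Network architecture configuration
#'
#' Describes the five-branch CNN--LSTM classifier. Each input channel feeds
#' its own stack of valid (un-padded, stride-1) convolutions with ReLU
#' activation, each followed by max pooling (size 2, stride 2, flooring odd
#' lengths) and dropout. The branch outputs are concatenated along the
#' feature axis, passed through a single tanh LSTM layer that returns every
#' time step, flattened, and classified by a ReLU layer and a 2-unit
#' softmax. The defaults are the production structure: filters and kernel
#' sizes 70/50/30/10, dropout 50/50/25/25\%, LSTM hidden size 50, so a
#' 1792-sample segment yields 89 time steps and a 4450-long flattened
#' vector.
#'
#' The time-step chain is derived at configuration time and checked against
#' `expected_time_steps`; a geometry that does not produce the expected
#' length is refused with the derived value in the message. Shallower
#' ablation variants (1--3 conv layers, or no LSTM) can be configured by
#' shortening the vectors / setting `use_lstm = FALSE` and passing
#' `expected_time_steps = NULL`.
#'
#' @param n_branches number of weight-independent channel branches (5).
#' @param conv_filters,conv_kernel_sizes,dropout_rates equal-length vectors
#'   (1--4 entries) describing the conv stack.
#' @param pool_size max-pool kernel and stride (2).
#' @param lstm_hidden LSTM hidden units (50).
#' @param use_lstm set `FALSE` for the CNN-only ablation.
#' @param fc1_units hidden units of the fully connected head (50).
#' @param output_units softmax outputs (2: truthful, deceptive).
#' @param input_len samples per channel segment (1792).
#' @param expected_time_steps required post-conv sequence length (89), or
#'   `NULL` to accept whatever the geometry yields.
#' @return An `"arch_config"` with derived fields `time_steps`,
#'   `merged_features` and `flatten_len`.
#' @export
arch_config <- function(n_branches = 5L,
                        conv_filters = c(70L, 50L, 30L, 10L),
                        conv_kernel_sizes = c(70L, 50L, 30L, 10L),
                        pool_size = 2L,
                        dropout_rates = c(0.50, 0.50, 0.25, 0.25),
                        lstm_hidden = 50L, use_lstm = TRUE,
                        fc1_units = 50L, output_units = 2L,
                        input_len = 1792L, expected_time_steps = 89L) {
  nl <- length(conv_filters)
  if (nl < 1L || nl > 4L)
    stop("between 1 and 4 convolutional layers are supported", call. = FALSE)
  if (length(conv_kernel_sizes) != nl || length(dropout_rates) != nl)
    stop("conv_filters, conv_kernel_sizes and dropout_rates must have equal length",
         call. = FALSE)
  if (pool_size != 2L)
    stop("pool_size must be 2", call. = FALSE)
  if (any(conv_filters < 1L) || any(conv_kernel_sizes < 1L))
    stop("filters and kernel sizes must be positive", call. = FALSE)
  if (any(dropout_rates < 0) || any(dropout_rates >= 1))
    stop("dropout_rates must lie in [0, 1)", call. = FALSE)
  stopifnot(n_branches >= 1L, lstm_hidden >= 1L, fc1_units >= 1L,
            output_units == 2L, input_len >= 1L)

  chain <- conv_pool_chain(input_len, conv_kernel_sizes, pool_size)
  ts <- chain[length(chain)]
  if (!is.null(expected_time_steps) && ts != expected_time_steps)
    stop(sprintf(
      "configuration error: conv/pool arithmetic yields %d time steps (chain %s), expected %d",
      ts, paste(chain, collapse = " -> "), expected_time_steps),
      call. = FALSE)
  merged <- n_branches * conv_filters[nl]
  structure(list(
    n_branches = as.integer(n_branches),
    conv_filters = as.integer(conv_filters),
    conv_kernel_sizes = as.integer(conv_kernel_sizes),
    pool_size = 2L,
    dropout_rates = as.numeric(dropout_rates),
    lstm_hidden = as.integer(lstm_hidden),
    use_lstm = isTRUE(use_lstm),
    fc1_units = as.integer(fc1_units),
    output_units = 2L,
    input_len = as.integer(input_len),
    time_steps = as.integer(ts),
    merged_features = as.integer(merged),
    flatten_len = as.integer(ts * if (isTRUE(use_lstm)) lstm_hidden else merged)),
    class = "arch_config")
}

# sequence lengths after each conv+pool stage, starting at the input
conv_pool_chain <- function(input_len, kernels, pool_size = 2L) {
  L <- as.integer(input_len)
  out <- L
  for (k in kernels) {
    L <- L - as.integer(k) + 1L
    if (L <= 0L)
      stop("configuration error: segment exhausted by kernel size ", k,
           call. = FALSE)
    L <- L %/% pool_size
    out <- c(out, L)
  }
  out
}

#' Per-stage sequence lengths of an architecture
#'
#' @param arch an [arch_config()].
#' @return integer vector: input length followed by the length after each
#'   conv+pool stage (default architecture: 1792, 861, 406, 188, 89).
#' @export
css_shape_chain <- function(arch = arch_config()) {
  stopifnot(inherits(arch, "arch_config"))
  conv_pool_chain(arch$input_len, arch$conv_kernel_sizes, arch$pool_size)
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config> %d branches x %d conv layers (filters %s, kernels %s)%s\n",
              x$n_branches, length(x$conv_filters),
              paste(x$conv_filters, collapse = "/"),
              paste(x$conv_kernel_sizes, collapse = "/"),
              if (x$use_lstm) sprintf(", LSTM(%d)", x$lstm_hidden) else ""))
  cat(sprintf("  shape: %s time steps -> %d x %d -> flatten %d -> FC(%d) -> softmax(2)\n",
              paste(css_shape_chain(x), collapse = " -> "),
              x$time_steps,
              if (x$use_lstm) x$lstm_hidden else x$merged_features,
              x$flatten_len, x$fc1_units))
  invisible(x)
}

#' Training configuration
#'
#' Adam on the mean softmax cross-entropy, learning rate 0.0015 and batch
#' size 64 by default. A validation fraction is carved from the training
#' data for early stopping on validation loss (patience in epochs); set
#' `validation_fraction = 0` to train for exactly `max_epochs`.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   tolerated before stopping; ignored when there is no validation split.
#' @param validation_fraction fraction of the training data held out for
#'   early stopping (default 0.1).
#' @param seed default seed for [css_fit()].
#' @return A `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.0015, batch_size = 64L,
                         max_epochs = 100L, early_stopping_patience = 10L,
                         validation_fraction = 0.1, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be positive", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  if (early_stopping_patience < 0L)
    stop("early_stopping_patience must be nonnegative", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) classifier
#'
#' Instantiates the network with randomly initialized weights (He-scaled
#' normal for the ReLU convolutions and first FC layer, Glorot-uniform for
#' the LSTM and softmax layer, forget-gate bias 1). Building fails loudly
#' if the conv/pool arithmetic of `arch` does not produce its declared
#' time-step count.
#'
#' @param arch an [arch_config()].
#' @param seed integer seed for the weight initialization.
#' @return A `"css_model"` (untrained: `$training` is `NULL`).
#' @export
css_build <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  flat <- nn_flatten_len(unclass(arch))
  if (flat != arch$flatten_len)
    stop("configuration error: derived flatten length ", flat,
         " does not match declared ", arch$flatten_len, call. = FALSE)
  weights <- with_seed(seed, nn_init(unclass(arch)))
  structure(list(arch = arch, weights = weights, control = NULL,
                 training = NULL,
                 classes = c("truthful", "deceptive"),
                 call = sys.call()),
            class = "css_model")
}

segments_to_cube <- function(segments) {
  stopifnot(inherits(segments, "css_segments"))
  aperm(segments$x, c(2L, 1L, 3L))  # input_len x channels x n
}

labels_to_int <- function(label) {
  if (any(!label %in% c("truthful", "deceptive")))
    stop("labels must be 'truthful' or 'deceptive' for training",
         call. = FALSE)
  as.integer(label == "deceptive")  # class index 1 = deceptive
}

#' Fit the question-set deception classifier
#'
#' Trains the five-branch CNN--LSTM network end to end on labeled
#' question-set segments using Adam and the mean softmax cross-entropy
#' cost. Dropout, weight initialization, the validation split and the
#' epoch shuffles are all driven by `seed`, so identical data and seed
#' give identical parameters.
#'
#' @param segments a `"css_segments"` container with labels in
#'   `{"truthful", "deceptive"}`; both classes must be present.
#' @param arch an [arch_config()]; its `input_len` must match the segments.
#' @param control a [train_config()].
#' @param seed integer seed (defaults to `control$seed`).
#' @return A fitted `"css_model"` with the training log in `$training`
#'   (per-epoch training loss and, when a validation split is used,
#'   validation loss and the restored best epoch).
#' @seealso [predict.css_model()], [predict_proba()], [cross_validate()]
#' @export
css_fit <- function(segments, arch = arch_config(), control = train_config(),
                    seed = control$seed) {
  stopifnot(inherits(segments, "css_segments"),
            inherits(arch, "arch_config"),
            inherits(control, "train_config"))
  if (dim(segments$x)[1] != arch$n_branches ||
      dim(segments$x)[2] != arch$input_len)
    stop(sprintf("segment shape %d x %d does not match architecture %d x %d",
                 dim(segments$x)[1], dim(segments$x)[2],
                 arch$n_branches, arch$input_len), call. = FALSE)
  y <- labels_to_int(segments$label)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; both truthful and deceptive segments are required",
         call. = FALSE)
  n <- length(y)
  X <- segments_to_cube(segments)

  res <- with_seed(seed, {
    weights <- nn_init(unclass(arch))
    n_val <- floor(control$validation_fraction * n)
    val_idx <- if (n_val >= 2L) sort(sample.int(n, n_val)) else integer()
    cfg <- list(learning_rate = control$learning_rate,
                batch_size = control$batch_size,
                max_epochs = control$max_epochs,
                patience = control$early_stopping_patience,
                val_idx = as.integer(val_idx))
    out <- nn_train(weights, unclass(arch), X, y, cfg)
    out$val_idx <- val_idx
    out
  })

  structure(list(arch = arch, weights = res$weights, control = control,
                 training = list(train_loss = res$train_loss,
                                 val_loss = res$val_loss,
                                 epochs_run = res$epochs_run,
                                 best_epoch = res$best_epoch,
                                 n_train = n - length(res$val_idx),
                                 n_val = length(res$val_idx),
                                 seed = as.integer(seed)),
                 classes = c("truthful", "deceptive"),
                 call = sys.call()),
            class = "css_model")
}

#' Predict deception probabilities for question sets
#'
#' Inference is deterministic: dropout is disabled, so the same segment
#' always yields the same probability. The reported scalar is always the
#' softmax mass of the deceptive class.
#'
#' @param object a `"css_model"`.
#' @param newdata a `"css_segments"` container or a single
#'   `"question_set_segment"`.
#' @param type `"prob"` for deceptive-class probabilities, `"class"` for
#'   hard labels (probability > 0.5 means deceptive), `"matrix"` for the
#'   full two-column softmax output.
#' @param ... unused.
#' @return numeric vector, factor, or n x 2 matrix according to `type`.
#' @export
predict.css_model <- function(object, newdata,
                              type = c("prob", "class", "matrix"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "question_set_segment"))
    newdata <- as_css_segments(list(newdata))
  stopifnot(inherits(newdata, "css_segments"))
  X <- segments_to_cube(newdata)
  pm <- nn_predict(object$weights, unclass(object$arch), X)
  colnames(pm) <- object$classes
  switch(type,
         prob = as.numeric(pm[, "deceptive"]),
         class = factor(ifelse(pm[, "deceptive"] > 0.5, "deceptive",
                               "truthful"),
                        levels = object$classes),
         matrix = pm)
}

#' @rdname predict.css_model
#' @param model a fitted or built `"css_model"`.
#' @param segment segments to score.
#' @export
predict_proba <- function(model, segment) {
  predict(model, segment, type = "prob")
}

#' @export
print.css_model <- function(x, ...) {
  cat("<css_model> 5-channel CNN",
      if (x$arch$use_lstm) "-> LSTM" else "(no LSTM)",
      "-> FC deception classifier\n")
  print(x$arch)
  if (is.null(x$training)) {
    cat("  untrained (random initialization)\n")
  } else {
    tl <- x$training$train_loss
    cat(sprintf("  trained %d epochs on %d segments (cross-entropy %.4f -> %.4f)\n",
                x$training$epochs_run, x$training$n_train,
                tl[1], tl[length(tl)]))
    if (length(x$training$val_loss))
      cat(sprintf("  early stopping on %d validation segments; best epoch %d\n",
                  x$training$n_val, x$training$best_epoch))
  }
  invisible(x)
}

#' @export
summary.css_model <- function(object, ...) {
  w <- object$weights
  npar <- function(l) sum(vapply(l, function(e)
    if (is.list(e)) npar(e) else length(e), numeric(1)))
  per_branch <- vapply(w$conv, npar, numeric(1))
  out <- list(arch = object$arch,
              n_parameters = npar(w),
              parameters_per_branch = per_branch,
              training = object$training)
  class(out) <- "summary.css_model"
  out
}

#' @export
print.summary.css_model <- function(x, ...) {
  print(x$arch)
  cat(sprintf("  %d trainable parameters (%s per conv branch)\n",
              x$n_parameters,
              paste(unique(x$parameters_per_branch), collapse = "/")))
  if (!is.null(x$training))
    cat(sprintf("  final training cross-entropy %.4f after %d epochs\n",
                x$training$train_loss[length(x$training$train_loss)],
                x$training$epochs_run))
  invisible(x)
}

#' @export
coef.css_model <- function(object, ...) object$weights

#' @export
plot.css_model <- function(x, ...) {
  if (is.null(x$training)) stop("model is untrained; nothing to plot")
  tl <- x$training$train_loss
  vl <- x$training$val_loss
  plot(seq_along(tl), tl, type = "b", pch = 16, xlab = "epoch",
       ylab = "cross-entropy",
       ylim = range(c(tl, vl)), main = "training history", ...)
  if (length(vl)) {
    lines(seq_along(vl), vl, type = "b", pch = 1, lty = 2)
    legend("topright", c("training", "validation"), pch = c(16, 1),
           lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
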