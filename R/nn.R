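#' Deep model specifications
#'
#' Constructors for the five deep regression architectures. Each records
#' the published layer dimensions and the default learning rate; the
#' architectures themselves are compiled, so the structural fields are
#' validated rather than free:
#'
#' * `cnn_spec()`: two 1-D convolutions (1 -> 128 -> 256 channels, kernel
#'   3, ReLU), flatten, fully connected layer (width `fc_hidden`), dropout
#'   0.3, scalar head; learning rate 0.0005.
#' * `lstm_spec()`: linear lift of the B-band spectrum to 1024 dimensions,
#'   consumed as a single-step one-way LSTM with hidden size 1024.
#' * `cnn_lstm_spec()`: three convolutions (128, 256, 512 channels, kernel
#'   3), then a one-way LSTM over the 512-wide token sequence with hidden
#'   size 256.
#' * `transformer_spec()`: per-band linear lift to `d_model` = 256,
#'   sinusoidal positional encoding, 6 encoder layers (4-head attention
#'   with d_k = d_q = d_v = 64, feed-forward hidden 1024, post-norm
#'   residuals), flattened into a fully connected scalar head.
#' * `cnn_transformer_spec()`: the same encoder stack fed by the two-conv
#'   front end (kernel 3, same-padding so the token count equals the band
#'   count); learning rate 0.0008.
#'
#' @param conv_channels,kernel_size,dropout_p,fc_hidden CNN structure.
#' @param input_dim,hidden_dim LSTM dimensions.
#' @param lstm_input,lstm_hidden CNN-LSTM recurrence dimensions.
#' @param d_model,n_layers,n_heads,d_k,ff_hidden Transformer encoder
#'   dimensions (`n_heads * d_k` must equal `d_model`).
#' @param lr default learning rate used when [train_config()] leaves `lr`
#'   unset.
#' @return An object of class `nn_spec` (subclassed by architecture).
#' @name nn_specs
NULL

nn_arch_id <- c(cnn = 1L, lstm = 2L, cnn_lstm = 3L, transformer = 4L,
                cnn_transformer = 5L)

new_nn_spec <- function(arch, fields, lr) {
  structure(c(fields, list(arch = arch, lr = lr)),
            class = c(paste0(arch, "_spec"), "nn_spec"))
}

#' @rdname nn_specs
#' @export
cnn_spec <- function(conv_channels = c(128L, 256L), kernel_size = 3L,
                     dropout_p = 0.3, fc_hidden = 64L, lr = 5e-4) {
  if (!identical(as.integer(conv_channels), c(128L, 256L)) ||
      kernel_size != 3L || fc_hidden != 64L)
    stop("cnn_spec: this build compiles the published structure ",
         "(channels 128/256, kernel 3, fc 64)")
  if (dropout_p < 0 || dropout_p >= 1)
    stop("cnn_spec: `dropout_p` must lie in [0, 1)")
  new_nn_spec("cnn", list(conv_channels = c(128L, 256L), kernel_size = 3L,
                          dropout_p = dropout_p, fc_hidden = 64L), lr)
}

#' @rdname nn_specs
#' @export
lstm_spec <- function(input_dim = 1024L, hidden_dim = 1024L, lr = 8e-4) {
  if (input_dim != 1024L || hidden_dim != 1024L)
    stop("lstm_spec: this build compiles the published structure ",
         "(1024 input, 1024 hidden)")
  new_nn_spec("lstm", list(input_dim = 1024L, hidden_dim = 1024L), lr)
}

#' @rdname nn_specs
#' @export
cnn_lstm_spec <- function(conv_channels = c(128L, 256L, 512L),
                          lstm_input = 512L, lstm_hidden = 256L,
                          lr = 8e-4) {
  if (!identical(as.integer(conv_channels), c(128L, 256L, 512L)) ||
      lstm_input != 512L || lstm_hidden != 256L)
    stop("cnn_lstm_spec: this build compiles the published structure")
  if (conv_channels[length(conv_channels)] != lstm_input)
    stop("cnn_lstm_spec: last conv channels must equal `lstm_input`")
  new_nn_spec("cnn_lstm",
              list(conv_channels = c(128L, 256L, 512L),
                   lstm_input = 512L, lstm_hidden = 256L), lr)
}

#' @rdname nn_specs
#' @export
transformer_spec <- function(d_model = 256L, n_layers = 6L, n_heads = 4L,
                             d_k = 64L, ff_hidden = 1024L, lr = 8e-4) {
  if (n_heads * d_k != d_model)
    stop("transformer_spec: `n_heads * d_k` must equal `d_model`")
  if (d_model != 256L || n_layers != 6L || n_heads != 4L ||
      ff_hidden != 1024L)
    stop("transformer_spec: this build compiles the published structure ",
         "(d_model 256, 6 layers, 4 heads, feed-forward 1024)")
  new_nn_spec("transformer",
              list(d_model = 256L, n_layers = 6L, n_heads = 4L,
                   d_k = 64L, ff_hidden = 1024L), lr)
}

#' @rdname nn_specs
#' @export
cnn_transformer_spec <- function(conv_channels = c(128L, 256L),
                                 d_model = 256L, n_layers = 6L,
                                 n_heads = 4L, d_k = 64L,
                                 ff_hidden = 1024L, lr = 8e-4) {
  if (n_heads * d_k != d_model)
    stop("cnn_transformer_spec: `n_heads * d_k` must equal `d_model`")
  if (!identical(as.integer(conv_channels), c(128L, 256L)) ||
      d_model != 256L || n_layers != 6L || n_heads != 4L ||
      ff_hidden != 1024L)
    stop("cnn_transformer_spec: this build compiles the published ",
         "structure")
  new_nn_spec("cnn_transformer",
              list(conv_channels = c(128L, 256L), d_model = 256L,
                   n_layers = 6L, n_heads = 4L, d_k = 64L,
                   ff_hidden = 1024L), lr)
}

#' Training configuration for the deep models
#'
#' Mean-squared-error loss optimised with AdamW on mini-batches of 10
#' spectra; the state with the lowest validation RMSE is kept, and
#' training stops after `patience` epochs without improvement.
#'
#' @param lr learning rate; `NULL` uses the architecture default
#'   (0.0008, or 0.0005 for the CNN).
#' @param batch_size mini-batch size (default 10).
#' @param max_epochs epoch budget (default 500).
#' @param patience early-stopping patience on validation RMSE
#'   (default 50).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param max_grad_norm global gradient-norm clipping threshold
#'   (default 1); `0` disables clipping.
#' @param warmup_epochs linear learning-rate warmup span in epochs
#'   (default 5); `0` disables warmup.
#' @param scale_inputs standardise spectra before the network using
#'   calibration statistics: bands are centred by their calibration means
#'   and divided by one global standard deviation (preserving the relative
#'   variance structure across bands). Stored in the model and applied
#'   transparently at prediction time. Default `TRUE`.
#' @param seed integer seed for weight initialisation order, batch
#'   shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = NULL, batch_size = 10L, max_epochs = 500L,
                         patience = 50L, weight_decay = 0.01,
                         max_grad_norm = 1, warmup_epochs = 5L,
                         scale_inputs = TRUE, seed = 1L) {
  if (!is.null(lr) && lr <= 0) stop("train_config: `lr` must be positive")
  if (batch_size < 1) stop("train_config: `batch_size` must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 max_grad_norm = max_grad_norm,
                 warmup_epochs = as.integer(warmup_epochs),
                 scale_inputs = isTRUE(scale_inputs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained deep model
#'
#' Instantiates the compiled architecture for a given input length and
#' initialises its weights (uniform fan-in scaling, deterministic for a
#' fixed seed).
#'
#' @param spec an `nn_spec` from one of the [nn_specs] constructors.
#' @param seq_len number of input bands (default 209, the band count after
#'   edge trimming).
#' @param seed initialisation seed.
#' @return Object of class `nn_model` (untrained).
#' @export
build_model <- function(spec, seq_len = 209L, seed = 1L) {
  if (!inherits(spec, "nn_spec"))
    stop("build_model: `spec` must be an nn_spec")
  arch <- nn_arch_id[[spec$arch]]
  weights <- cpp_nn_init(arch, as.integer(seq_len), as.integer(seed))
  structure(list(spec = spec, arch = arch, seq_len = as.integer(seq_len),
                 weights = weights, trained = FALSE,
                 y_center = 0, y_scale = 1,
                 x_center = NULL, x_scale = 1, history = NULL,
                 best_epoch = NA_integer_),
            class = "nn_model")
}

#' Train a deep model
#'
#' Optimises the model on calibration spectra with AdamW and MSE loss.
#' Targets are z-scored with the calibration mean/sd before optimisation
#' and predictions are transformed back, so the loss scale is comparable
#' between targets measured in different units. The returned model
#' carries the epoch history and the weights of the best validation
#' epoch.
#'
#' @param model an `nn_model` from [build_model()].
#' @param X_cal,y_cal calibration spectra (matrix or [spectra_matrix],
#'   rows = samples) and targets.
#' @param X_val,y_val validation data used for early stopping.
#' @param cfg a [train_config()].
#' @return The trained `nn_model`.
#' @export
train_model <- function(model, X_cal, y_cal, X_val, y_val,
                        cfg = train_config()) {
  if (!inherits(model, "nn_model"))
    stop("train_model: `model` must be an nn_model")
  Xc <- spectra_values(X_cal); Xv <- spectra_values(X_val)
  if (ncol(Xc) != model$seq_len || ncol(Xv) != model$seq_len)
    stop("train_model: input width does not match model seq_len (",
         model$seq_len, ")")
  if (nrow(Xc) != length(y_cal) || nrow(Xv) != length(y_val))
    stop("train_model: target lengths do not match spectra")
  y_center <- mean(y_cal)
  y_scale <- sd(y_cal)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  if (cfg$scale_inputs) {
    model$x_center <- colMeans(Xc)
    ctr <- sweep(Xc, 2, model$x_center)
    model$x_scale <- sd(ctr)
    if (!is.finite(model$x_scale) || model$x_scale == 0)
      model$x_scale <- 1
    Xc <- ctr / model$x_scale
    Xv <- sweep(Xv, 2, model$x_center) / model$x_scale
  } else {
    model$x_center <- NULL
    model$x_scale <- 1
  }
  lr <- if (is.null(cfg$lr)) model$spec$lr else cfg$lr
  res <- cpp_nn_train(model$arch, model$weights, Xc,
                      (y_cal - y_center) / y_scale, Xv,
                      (y_val - y_center) / y_scale,
                      lr, cfg$batch_size, cfg$max_epochs, cfg$patience,
                      cfg$seed, cfg$weight_decay, cfg$max_grad_norm,
                      cfg$warmup_epochs)
  model$weights <- res$weights
  model$history <- data.frame(epoch = seq_along(res$train_mse),
                              train_mse = res$train_mse,
                              val_rmse = res$val_rmse)
  model$best_epoch <- res$best_epoch
  model$y_center <- y_center
  model$y_scale <- y_scale
  model$trained <- TRUE
  model
}

#' Predict from a deep model
#'
#' Evaluation-mode forward pass (dropout inert): repeated calls on the
#' same input return identical values.
#'
#' @param object an `nn_model`.
#' @param newdata matrix or [spectra_matrix] whose width matches the
#'   model's `seq_len`.
#' @param ... unused.
#' @return Numeric vector, one finite value per row.
#' @export
predict.nn_model <- function(object, newdata, ...) {
  Xv <- spectra_values(newdata)
  if (ncol(Xv) != object$seq_len)
    stop("predict.nn_model: input width ", ncol(Xv),
         " does not match model seq_len ", object$seq_len)
  if (!is.null(object$x_center))
    Xv <- sweep(Xv, 2, object$x_center) / object$x_scale
  object$y_center +
    object$y_scale * as.numeric(cpp_nn_predict(object$arch,
                                               object$weights, Xv))
}

# apply the model's stored input standardisation (identity if untrained
# or trained with scale_inputs = FALSE)
nn_input_scale <- function(model, X) {
  if (!is.null(model$x_center))
    X <- sweep(X, 2, model$x_center) / model$x_scale
  X
}

#' Number of trainable parameters
#'
#' @param model an `nn_model`.
#' @return Integer count over all weight matrices and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, 0L))
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model:%s> seq_len %d, %s parameters, %s\n",
              x$spec$arch, x$seq_len,
              format(n_parameters(x), big.mark = ","),
              if (x$trained)
                sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained"))
  invisible(x)
}
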