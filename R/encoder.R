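#' Inverse-frequency class weights
#'
#' Computes the per-class loss multipliers used during supervised
#' fine-tuning to counter class imbalance: `W_cj = S / (C * S_cj)`, where
#' `S` is the total number of training samples, `C` the number of classes
#' and `S_cj` the number of samples in class `c_j`. By construction every
#' class contributes the same total loss mass `S / C`, so
#' `sum_j W_cj * S_cj = S` exactly.
#'
#' @param counts positive per-class sample counts (named or unnamed).
#' @return an object of class `class_weight_table`: list with `weights`
#'   (numeric, aligned with `counts`), `S`, `C` and `counts`.
#' @export
#' @examples
#' compute_class_weights(c(neg = 100, pos = 20))$weights
compute_class_weights <- function(counts) {
  if (length(counts) < 2)
    stop("need at least two classes", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all class counts must be positive", call. = FALSE)
  S <- sum(counts)
  C <- length(counts)
  w <- S / (C * counts)
  structure(list(weights = w, S = S, C = C, counts = counts),
            class = "class_weight_table")
}

#' @export
print.class_weight_table <- function(x, ...) {
  cat(sprintf("<class_weight_table> S=%g, C=%d; weights: %s\n", x$S, x$C,
              paste(signif(x$weights, 6), collapse = ", ")))
  invisible(x)
}

#' Specification of the feature-compression encoder
#'
#' Architecture and training hyper-parameters of the two-step autoencoder
#' compressor. The default funnel `3072 -> 1024 -> 512 -> 256` takes the
#' three-view concatenated descriptor down to a 256-value code (a 12-fold
#' reduction); the decoder mirrors the encoder widths during unsupervised
#' pre-training. Hidden layers are rectified-linear (the decoder output is
#' linear, the fine-tuning head sigmoid); dropout 0.2 is applied after every
#' non-final layer during training only.
#'
#' @param layer_widths integer vector from input width down to the
#'   bottleneck, strictly decreasing (default `c(3072, 1024, 512, 256)`).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.2).
#' @param epochs training epochs per phase (default 10).
#' @param batch_size mini-batch size (default 128).
#' @param learning_rate Adam step size (default 1e-3, the optimizer's
#'   conventional default).
#' @param activation hidden activation, `"relu"` (default) or `"linear"`
#'   (used e.g. to compare a linear encoder against PCA).
#' @param validation_fraction fraction of the training set held out for the
#'   per-epoch validation loss (default 0.1).
#' @param seed integer seed driving initialization, shuffling, dropout and
#'   the validation split.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(layer_widths = c(3072L, 1024L, 512L, 256L),
                         dropout_rate = 0.2, epochs = 10L, batch_size = 128L,
                         learning_rate = 1e-3, activation = c("relu", "linear"),
                         validation_fraction = 0.1, seed = 1L) {
  layer_widths <- as.integer(layer_widths)
  if (length(layer_widths) < 2L || any(diff(layer_widths) >= 0))
    stop("layer_widths must be strictly decreasing to the bottleneck",
         call. = FALSE)
  if (any(layer_widths < 1L))
    stop("layer_widths must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (epochs < 1 || batch_size < 1)
    stop("epochs and batch_size must be positive", call. = FALSE)
  activation <- match.arg(activation)
  structure(list(layer_widths = layer_widths, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, activation = activation,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf(
    "<encoder_spec> %s; dropout %.2g, %d epochs, batch %d, lr %.2g, %s\n",
    paste(x$layer_widths, collapse = " -> "), x$dropout_rate, x$epochs,
    x$batch_size, x$learning_rate, x$activation))
  invisible(x)
}

.encoder_acts <- function(spec, n_layers) rep(spec$activation, n_layers)

#' Step 1: unsupervised autoencoder pre-training
#'
#' Constructs the symmetric autoencoder (mirrored decoder widths, dropout
#' after every non-final layer) and trains it for `spec$epochs` epochs with
#' outputs set equal to inputs, mean-squared-error loss and the Adam
#' optimizer. The weights of the final epoch are retained — no early
#' stopping. Per-epoch training and validation losses are recorded.
#'
#' @param store a [feature_store()] whose width equals
#'   `spec$layer_widths[1]`.
#' @param spec an [encoder_spec()].
#' @return an object of class `encoder_model` with `phase = "pretrained"`.
#' @export
pretrain_autoencoder <- function(store, spec = encoder_spec()) {
  stopifnot(inherits(store, "feature_store"), inherits(spec, "encoder_spec"))
  X <- store$features
  w <- spec$layer_widths
  if (ncol(X) != w[1L])
    stop(sprintf("store width %d does not match encoder input %d",
                 ncol(X), w[1L]), call. = FALSE)
  n_enc <- length(w) - 1L
  widths_full <- c(w, rev(w)[-1L])
  layers <- .with_seed(spec$seed, .mlp_init(widths_full))
  acts <- c(.encoder_acts(spec, length(widths_full) - 2L), "linear")
  fit <- .mlp_train(X, X, layers, acts, loss = "mse",
                    epochs = spec$epochs, batch_size = spec$batch_size,
                    dropout = spec$dropout_rate, lr = spec$learning_rate,
                    val_fraction = spec$validation_fraction,
                    seed = .substream_seed(spec$seed, 1L),
                    phase_name = "pretrain")
  structure(list(spec = spec,
                 encoder = fit$layers[seq_len(n_enc)],
                 decoder = fit$layers[(n_enc + 1L):length(fit$layers)],
                 head = NULL, phase = "pretrained", history = fit$history),
            class = "encoder_model")
}

#' Step 2: supervised fine-tuning with class weights
#'
#' Discards the decoder, appends a one-unit sigmoid head after the
#' bottleneck (with dropout between bottleneck and head during training) and
#' minimizes class-weighted binary cross-entropy with Adam for
#' `spec$epochs` epochs at `spec$batch_size`. Class weights default to the
#' inverse-frequency rule of [compute_class_weights()], which equalizes the
#' total loss mass of the two classes.
#'
#' @param model a pretrained `encoder_model`.
#' @param store a labelled [feature_store()] (binary 0/1 labels, no NA).
#' @param class_weights optional [compute_class_weights()] table, indexed
#'   `(negative, positive)`; computed from the store labels when `NULL`.
#' @return the model with `phase = "finetuned"`, history extended.
#' @export
finetune_with_labels <- function(model, store, class_weights = NULL) {
  stopifnot(inherits(model, "encoder_model"),
            inherits(store, "feature_store"))
  if (model$phase != "pretrained")
    stop("finetune_with_labels expects a pretrained model", call. = FALSE)
  y <- store$labels
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("fine-tuning requires binary 0/1 labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (is.null(class_weights))
    class_weights <- compute_class_weights(c(sum(y == 0L), sum(y == 1L)))
  if (length(class_weights$weights) != 2L)
    stop("class_weights must cover exactly the two classes", call. = FALSE)
  X <- store$features
  spec <- model$spec
  bottleneck <- spec$layer_widths[length(spec$layer_widths)]
  head_layer <- .with_seed(.substream_seed(spec$seed, 2L),
                           .mlp_init(c(bottleneck, 1L)))
  layers <- c(model$encoder, head_layer)
  acts <- c(.encoder_acts(spec, length(model$encoder)), "sigmoid")
  sample_w <- class_weights$weights[y + 1L]
  fit <- .mlp_train(X, matrix(as.numeric(y), ncol = 1L), layers, acts,
                    loss = "wbce", epochs = spec$epochs,
                    batch_size = spec$batch_size,
                    dropout = spec$dropout_rate, lr = spec$learning_rate,
                    sample_w = sample_w,
                    val_fraction = spec$validation_fraction,
                    seed = .substream_seed(spec$seed, 3L),
                    phase_name = "finetune")
  model$encoder <- fit$layers[seq_len(length(model$encoder))]
  model$head <- fit$layers[[length(fit$layers)]]
  model$decoder <- NULL
  model$phase <- "finetuned"
  model$class_weights <- class_weights
  model$history <- rbind(model$history, fit$history)
  model
}

#' Remove the classification head, keeping the bare encoder
#'
#' After fine-tuning, the one-unit head is removed; what remains is the
#' deterministic compression map used to tag archives for search. Encoding
#' is a pure function of the input (dropout is inactive at inference).
#'
#' @param model a finetuned `encoder_model`.
#' @return the model with `phase = "encoder_only"`.
#' @export
strip_head <- function(model) {
  stopifnot(inherits(model, "encoder_model"))
  if (model$phase != "finetuned")
    stop("strip_head expects a finetuned model", call. = FALSE)
  model$head <- NULL
  model$phase <- "encoder_only"
  model
}

#' Encode feature vectors to bottleneck codes
#'
#' Deterministic forward pass through the encoder layers (activation
#' included at the bottleneck, matching what the decoder and head saw during
#' training). Accepts a matrix or a single vector.
#'
#' @param model an `encoder_model` (any phase).
#' @param x numeric matrix (rows = items) or vector of the encoder's input
#'   width.
#' @return matrix of codes, `nrow(x)` x bottleneck width.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "encoder_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  w <- model$spec$layer_widths
  if (ncol(x) != w[1L])
    stop(sprintf("input width %d does not match encoder input %d",
                 ncol(x), w[1L]), call. = FALSE)
  acts <- .encoder_acts(model$spec, length(model$encoder))
  if (nrow(x) == 0L) return(matrix(numeric(), 0L, w[length(w)]))
  fwd <- .mlp_forward(x, model$encoder, acts, training = FALSE)
  fwd$a[[length(model$encoder) + 1L]]
}

#' Encode a whole feature store
#'
#' @param model an `encoder_model`, typically after [strip_head()].
#' @param store a [feature_store()] of matching width.
#' @return a [feature_store()] of codes (`config = "code"`), ids and labels
#'   preserved in row order.
#' @export
encode_store <- function(model, store) {
  stopifnot(inherits(store, "feature_store"))
  codes <- encode(model, store$features)
  feature_store(codes, store$ids, store$labels, config = "code",
                backbone = sprintf("encoder[%s]",
                                   paste(model$spec$layer_widths,
                                         collapse = "-")),
                descriptor_length = ncol(codes))
}

#' Reconstruct inputs through the full autoencoder
#'
#' Available in the pretrained phase only; used to monitor reconstruction
#' quality and for the PCA comparison.
#'
#' @param model a pretrained `encoder_model`.
#' @param x input matrix.
#' @return reconstructed matrix of the same shape.
#' @export
reconstruct <- function(model, x) {
  stopifnot(inherits(model, "encoder_model"))
  if (is.null(model$decoder))
    stop("model has no decoder (phase: ", model$phase, ")", call. = FALSE)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  layers <- c(model$encoder, model$decoder)
  acts <- c(.encoder_acts(model$spec, length(layers) - 1L), "linear")
  fwd <- .mlp_forward(x, layers, acts, training = FALSE)
  fwd$a[[length(layers) + 1L]]
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %s, phase=%s, %d history epochs\n",
              paste(x$spec$layer_widths, collapse = " -> "), x$phase,
              nrow(x$history)))
  invisible(x)
}

#' PCA baseline compression
#'
#' Mean-centred orthogonal projection onto the top `dim` principal axes,
#' the optimal linear compressor at a given width, used as the reference the
#' autoencoder is compared against. The reconstruction mean squared error of
#' the projection equals the mean of the discarded eigenvalues' mass.
#'
#' @param store a [feature_store()].
#' @param dim number of components, at most `min(n - 1, feature dim)`.
#' @return list with `codes` (a [feature_store()] of scores), `rotation`,
#'   `center` and `eigenvalues` (variances along all computed axes).
#' @export
pca_compress <- function(store, dim) {
  stopifnot(inherits(store, "feature_store"))
  n <- nrow(store$features)
  p <- ncol(store$features)
  if (dim > min(n - 1L, p))
    stop(sprintf("dim must be <= min(n - 1, p) = %d", min(n - 1L, p)),
         call. = FALSE)
  pc <- stats::prcomp(store$features, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(dim), drop = FALSE]
  dimnames(scores) <- NULL
  list(codes = feature_store(scores, store$ids, store$labels,
                             config = "code",
                             backbone = sprintf("pca-%d", dim),
                             descriptor_length = as.integer(dim)),
       rotation = pc$rotation[, seq_len(dim), drop = FALSE],
       center = pc$center,
       eigenvalues = pc$sdev^2)
}
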