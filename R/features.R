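#' Define a feature-extraction backbone
#'
#' A backbone is the frozen descriptor network of the pipeline, treated
#' purely as a contract: a deterministic map from a 224 x 224 x 3 image
#' array to a fixed-length real vector (the activation of the last pooling
#' layer of a convolutional network, in the canonical case of a
#' DenseNet-121-style extractor with 1024 outputs). Any input normalization
#' the network expects is owned by the backbone's `apply` function.
#'
#' @param name backbone name recorded in store metadata.
#' @param descriptor_length output vector length.
#' @param apply function taking a `side x side x 3` numeric array and
#'   returning a numeric vector of `descriptor_length`.
#' @param input_side expected view side length (default 224).
#' @return an object of class `backbone`.
#' @seealso [stub_backbone()] for the deterministic arithmetic backbone used
#'   in tests and examples.
#' @export
backbone <- function(name, descriptor_length, apply, input_side = 224L) {
  stopifnot(is.function(apply))
  descriptor_length <- as.integer(descriptor_length)
  if (descriptor_length < 1L)
    stop("descriptor_length must be positive", call. = FALSE)
  structure(list(name = as.character(name),
                 descriptor_length = descriptor_length,
                 apply = apply, input_side = as.integer(input_side)),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s: %d x %d x 3 -> %d\n", x$name, x$input_side,
              x$input_side, x$descriptor_length))
  invisible(x)
}

#' Deterministic stub backbone (block means + fixed random projection)
#'
#' A pure-arithmetic stand-in for a pretrained convolutional extractor:
#' per-channel mean pooling over non-overlapping `block x block` pixel
#' blocks (7 x 7 blocks per channel at the default geometry), followed by a
#' fixed projection to `descriptor_length` dimensions through a matrix drawn
#' once from `proj_seed`. It needs no learned weights, is exactly
#' reproducible across platforms, and preserves the coarse spatial contrasts
#' (such as a darkened pleural rim) that the retrieval pipeline exploits.
#'
#' @param descriptor_length output length (default 1024).
#' @param block pooling block side in pixels (default 32).
#' @param input_side expected view side (default 224; must be a multiple of
#'   `block`).
#' @param proj_seed seed of the fixed projection matrix. Part of the
#'   backbone identity: two stubs with the same seed are the same function.
#' @return a [backbone()].
#' @export
#' @examples
#' b <- stub_backbone()
#' v <- extract_view_descriptor(matrix(runif(224^2), 224, 224), b)
#' length(v)
stub_backbone <- function(descriptor_length = 1024L, block = 32L,
                          input_side = 224L, proj_seed = 20210510L) {
  if (input_side %% block != 0)
    stop("input_side must be a multiple of block", call. = FALSE)
  nb <- (input_side %/% block)^2L * 3L
  proj <- .with_seed(proj_seed,
                     matrix(rnorm(descriptor_length * nb) / sqrt(nb),
                            nb, descriptor_length))
  backbone(
    name = sprintf("stub-b%d-d%d", block, descriptor_length),
    descriptor_length = descriptor_length,
    input_side = input_side,
    apply = function(arr) {
      pooled <- vapply(1:3, function(ch)
        as.vector(.block_means(arr[, , ch], block)),
        numeric(nb %/% 3L))
      as.vector(as.vector(pooled) %*% proj)
    })
}

# Mean over non-overlapping b x b blocks; returns (s/b) x (s/b) matrix.
.block_means <- function(m, b) {
  s <- nrow(m)
  nb <- s %/% b
  # sum rows within blocks, then columns
  rs <- rowsum(m, rep(seq_len(nb), each = b))
  cs <- t(rowsum(t(rs), rep(seq_len(nb), each = b)))
  cs / (b * b)
}

#' Extract a descriptor from a single view
#'
#' Replicates the grayscale view to three identical channels (frozen
#' extractors expect colour input) and applies the backbone.
#'
#' @param view `side x side` numeric matrix in `[0, 1]`.
#' @param backbone a [backbone()].
#' @return numeric vector of length `backbone$descriptor_length`.
#' @export
extract_view_descriptor <- function(view, backbone) {
  stopifnot(inherits(backbone, "backbone"))
  s <- backbone$input_side
  if (!is.matrix(view) || nrow(view) != s || ncol(view) != s)
    stop(sprintf("view must be a %d x %d matrix", s, s), call. = FALSE)
  arr <- array(view, dim = c(s, s, 3L))
  out <- backbone$apply(arr)
  if (length(out) != backbone$descriptor_length || !all(is.finite(out)))
    stop("backbone returned an invalid descriptor", call. = FALSE)
  as.numeric(out)
}

#' Build a configuration-1/2/3 descriptor from a view set
#'
#' Configuration 1 describes the whole image with a single vector.
#' Configuration 2 concatenates the left-half and flipped-right-half
#' descriptors, letting each chest side be matched separately with the
#' flip acting as coarse registration. Configuration 3 concatenates both
#' halves and the whole image. Segment order is fixed as
#' `[left, right_flipped]` (config 2) and `[left, right_flipped, whole]`
#' (config 3).
#'
#' @param views a [make_views()] result.
#' @param config 1, 2 or 3.
#' @param backbone a [backbone()].
#' @return numeric vector of length `config * descriptor_length`.
#' @export
build_feature <- function(views, config, backbone) {
  stopifnot(inherits(views, "view_set"))
  if (!config %in% 1:3) stop("config must be 1, 2 or 3", call. = FALSE)
  if (config == 1)
    return(extract_view_descriptor(views$whole, backbone))
  left <- extract_view_descriptor(views$left, backbone)
  right <- extract_view_descriptor(views$right_flipped, backbone)
  if (config == 2) return(c(left, right))
  c(left, right, extract_view_descriptor(views$whole, backbone))
}

#' Tag an image collection with descriptors
#'
#' Phase 1 of the pipeline: every archived image is converted to a
#' descriptor under one configuration, producing the searchable
#' [feature_store()]. Input order is preserved.
#'
#' @param images a `phantom_set`, or a list of intensity matrices.
#' @param config 1, 2 or 3.
#' @param backbone a [backbone()].
#' @param ids,labels item ids and 0/1 labels; taken from the phantom
#'   manifest when `images` is a `phantom_set`.
#' @param skip_errors if `TRUE`, images failing preprocessing are dropped
#'   with a warning naming their ids; if `FALSE` (default) the first
#'   failure aborts, naming the id.
#' @return a [feature_store()].
#' @export
#' @examples
#' ph <- generate_phantoms(phantom_spec(6, image_side = 64, seed = 1))
#' b <- stub_backbone(descriptor_length = 32, block = 16, input_side = 64)
#' st <- tag_archive(ph, config = 2, backbone = b, side = 64)
#' dim(st)
tag_archive <- function(images, config, backbone, ids = NULL, labels = NULL,
                        skip_errors = FALSE, side = backbone$input_side) {
  if (inherits(images, "phantom_set")) {
    if (is.null(ids)) ids <- images$manifest$id
    if (is.null(labels)) labels <- images$manifest$label
    images <- images$images
  }
  if (!is.list(images) || length(images) == 0)
    stop("images must be a non-empty list", call. = FALSE)
  n <- length(images)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  dim_out <- as.integer(config) * backbone$descriptor_length
  feats <- matrix(NA_real_, n, dim_out)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    v <- tryCatch(
      build_feature(make_views(images[[i]], side = side), config, backbone),
      error = function(e) e)
    if (inherits(v, "error")) {
      if (!skip_errors)
        stop(sprintf("feature extraction failed for '%s': %s", ids[i],
                     conditionMessage(v)), call. = FALSE)
      ok[i] <- FALSE
    } else feats[i, ] <- v
  }
  if (!all(ok))
    warning("skipped images: ", paste(ids[!ok], collapse = ", "))
  feature_store(feats[ok, , drop = FALSE], ids[ok], labels[ok],
                config = as.integer(config), backbone = backbone$name,
                descriptor_length = backbone$descriptor_length)
}
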