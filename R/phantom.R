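#' Specification of a synthetic thorax phantom collection
#'
#' Parameters of the phantom generator. Negative phantoms are exactly
#' mirror-symmetric about the vertical midline (up to additive pixel noise):
#' two bright elliptical lung fields, a central mediastinal band and
#' rib-like sinusoidal texture, all built from symmetric functions of the
#' distance to the midline. Positive phantoms additionally carry a darkened
#' pleural crescent along the lateral edge of one randomly chosen lung,
#' emulating the thin lucent rim of a collapsed lung. The construction makes
#' the left/flipped-right symmetry assumption of the two-view descriptor
#' configurations literally true for negatives and broken for positives.
#'
#' @param n_images number of phantoms (>= 2).
#' @param image_side image side length in pixels (default 224).
#' @param positive_fraction fraction of images carrying a lesion, in (0, 1);
#'   default 0.06, the pneumothorax prevalence of the large public
#'   chest-radiograph corpora this generator stands in for.
#' @param lesion_contrast relative darkening of the crescent, in (0, 1];
#'   default 0.35 — a clearly visible but not saturating defect.
#' @param lesion_width_frac crescent width as a fraction of the image side,
#'   in (0, 0.5]; default 0.12.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (default 0.01, i.e. ~1% of the dynamic range).
#' @param seed integer master seed; identical spec + seed reproduce the
#'   collection exactly.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_images, image_side = 224L, positive_fraction = 0.06,
                         lesion_contrast = 0.35, lesion_width_frac = 0.12,
                         noise_sd = 0.01, seed = 1L) {
  .assert_scalar_number(n_images, "n_images")
  if (n_images < 2) stop("n_images must be >= 2", call. = FALSE)
  .assert_scalar_number(positive_fraction, "positive_fraction")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)", call. = FALSE)
  .assert_scalar_number(lesion_contrast, "lesion_contrast")
  if (lesion_contrast <= 0 || lesion_contrast > 1)
    stop("lesion_contrast must be in (0, 1]", call. = FALSE)
  .assert_scalar_number(lesion_width_frac, "lesion_width_frac")
  if (lesion_width_frac <= 0 || lesion_width_frac > 0.5)
    stop("lesion_width_frac must be in (0, 0.5]", call. = FALSE)
  .assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (image_side < 8) stop("image_side must be >= 8", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_side = as.integer(image_side),
                 positive_fraction = positive_fraction,
                 lesion_contrast = lesion_contrast,
                 lesion_width_frac = lesion_width_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic thorax phantom collection
#'
#' Draws `n_images` phantoms according to a [phantom_spec()]. Exactly
#' `round(n_images * positive_fraction)` images are positive; which images,
#' which side carries the lesion, symmetric per-image anatomy jitter and the
#' pixel noise are all driven by per-image substreams derived from the
#' master seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_set`: list with `images` (list of
#'   intensity matrices in `[0, 1]`), and `manifest` (data.frame with
#'   columns `id`, `label` (0/1), `side` ("left"/"right"/"none"), `seed`).
#' @export
#' @examples
#' ph <- generate_phantoms(phantom_spec(10, image_side = 64, seed = 7))
#' table(ph$manifest$label)
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_images
  n_pos <- as.integer(round(n * spec$positive_fraction))
  pos_idx <- .with_seed(spec$seed, sample.int(n, n_pos))
  labels <- integer(n)
  labels[pos_idx] <- 1L
  images <- vector("list", n)
  sides <- rep("none", n)
  for (i in seq_len(n)) {
    sub <- .substream_seed(spec$seed, i)
    res <- .with_seed(sub, .draw_phantom(spec, positive = labels[i] == 1L))
    images[[i]] <- res$image
    sides[i] <- res$side
  }
  manifest <- data.frame(id = sprintf("phantom_%04d", seq_len(n)),
                         label = labels, side = sides,
                         seed = spec$seed, stringsAsFactors = FALSE)
  structure(list(images = images, manifest = manifest, spec = spec),
            class = "phantom_set")
}

# One phantom. All base-pattern terms depend on the column only through the
# absolute distance to the vertical midline, so negatives are exactly
# mirror-symmetric before noise.
.draw_phantom <- function(spec, positive) {
  s <- spec$image_side
  y <- matrix(seq_len(s) / s, s, s)              # rows: 0..1 top-bottom
  u <- matrix(abs(seq_len(s) - (s + 1) / 2) / s, s, s, byrow = TRUE)

  # symmetric anatomy jitter (same draw used for both sides)
  lung_off <- 0.22 + runif(1, -0.015, 0.015)     # midline -> lung centre
  lung_a <- 0.13 + runif(1, -0.01, 0.01)         # semi-axis, horizontal
  lung_b <- 0.30 + runif(1, -0.02, 0.02)         # semi-axis, vertical
  cy <- 0.52 + runif(1, -0.02, 0.02)
  rib_freq <- 2 * pi / (0.09 + runif(1, -0.01, 0.01))
  rib_phase <- runif(1, 0, 2 * pi)

  r_ell <- sqrt(((u - lung_off) / lung_a)^2 + ((y - cy) / lung_b)^2)
  lung <- r_ell <= 1
  img <- matrix(0.15, s, s)
  img <- img + 0.30 * exp(-(u / 0.06)^2)         # mediastinal band
  img[lung] <- 0.72 + 0.06 * sin(rib_freq * y[lung] + rib_phase)

  side <- "none"
  if (positive) {
    side <- if (runif(1) < 0.5) "left" else "right"
    # crescent: outer rim of the chosen lung, width lesion_width_frac * side
    depth <- spec$lesion_width_frac * s / (lung_a * s)   # in ellipse radius
    cols <- matrix(seq_len(s), s, s, byrow = TRUE)
    on_side <- if (side == "left") cols <= (s + 1) / 2 else cols >= (s + 1) / 2
    rim <- lung & on_side & (u > lung_off) & (r_ell >= 1 - depth)
    img[rim] <- img[rim] * (1 - spec$lesion_contrast)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(s * s, 0, spec$noise_sd), s, s)
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, side = side)
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d images (%d positive), %d x %d px, seed %d\n",
              length(x$images), sum(x$manifest$label), x$spec$image_side,
              x$spec$image_side, x$spec$seed))
  invisible(x)
}

#' Specification of a synthetic labelled feature-cluster collection
#'
#' Describes a two-class Gaussian feature set emulating concatenated deep
#' features whose discriminative signal lives in a low-dimensional subspace:
#' both classes are unit-variance isotropic Gaussians in `dim` dimensions,
#' and the class-mean difference is non-zero only on the first
#' `informative_dim` coordinates, with Euclidean norm `separation`. The
#' Bayes-optimal AUC of any linear score is `pnorm(separation / 2)`.
#'
#' @param n_samples number of vectors.
#' @param dim feature dimension (default 3072, the length of the three-view
#'   concatenated descriptor).
#' @param informative_dim size of the informative subspace (default 256, the
#'   autoencoder bottleneck width).
#' @param separation Euclidean distance between the class means (>= 0).
#' @param positive_fraction fraction of positive labels in (0, 1), default
#'   0.06.
#' @param seed integer seed; identical spec reproduces identical samples.
#' @return an object of class `feature_sim_spec`.
#' @export
feature_sim_spec <- function(n_samples, dim = 3072L, informative_dim = 256L,
                             separation = 6, positive_fraction = 0.06,
                             seed = 1L) {
  .assert_scalar_number(n_samples, "n_samples")
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (informative_dim > dim)
    stop("informative_dim must be <= dim", call. = FALSE)
  if (informative_dim < 1 || dim < 1)
    stop("dim and informative_dim must be positive", call. = FALSE)
  .assert_scalar_number(separation, "separation")
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), dim = as.integer(dim),
                 informative_dim = as.integer(informative_dim),
                 separation = separation,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)),
            class = "feature_sim_spec")
}

#' Generate labelled Gaussian feature clusters
#'
#' Samples the two-class Gaussian structure described by a
#' [feature_sim_spec()]. Negatives are centred at the origin; positives at a
#' mean vector that is constant on the informative coordinates and zero
#' elsewhere, scaled so its norm equals `separation`. Exactly
#' `round(n_samples * positive_fraction)` samples are positive.
#'
#' @param spec a [feature_sim_spec()].
#' @return a [feature_store()] with `config = "sim"`.
#' @export
#' @examples
#' fs <- generate_feature_clusters(
#'   feature_sim_spec(100, dim = 16, informative_dim = 4, separation = 4))
#' dim(fs$features)
generate_feature_clusters <- function(spec) {
  stopifnot(inherits(spec, "feature_sim_spec"))
  n <- spec$n_samples
  d <- spec$dim
  n_pos <- as.integer(round(n * spec$positive_fraction))
  .with_seed(spec$seed, {
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L
    x <- matrix(rnorm(n * d), n, d)
    if (n_pos > 0 && spec$separation > 0) {
      shift <- spec$separation / sqrt(spec$informative_dim)
      x[labels == 1L, seq_len(spec$informative_dim)] <-
        x[labels == 1L, seq_len(spec$informative_dim)] + shift
    }
    feature_store(x, ids = sprintf("sim_%05d", seq_len(n)), labels = labels,
                  config = "sim", backbone = "gaussian-sim")
  })
}
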