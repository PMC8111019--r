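#' Receiver operating characteristic curve
#'
#' Computes sensitivity and specificity under the `>=` decision rule at
#' thresholds placed at the midpoints between consecutive unique scores,
#' with `+Inf`/`-Inf` sentinels, in descending order. The AUC is obtained by
#' trapezoidal integration over (1 - specificity, sensitivity), which equals
#' the Mann-Whitney rank concordance with ties credited 1/2. The Youden
#' operating point (the threshold maximizing J = sensitivity + specificity
#' - 1, ties broken toward the smallest threshold, i.e. higher sensitivity)
#' is selected on the curve.
#'
#' @param scores numeric prediction scores (e.g. vote likelihoods).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return an object of class `roc_curve`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `youden_threshold`, `youden_j`.
#' @export
#' @examples
#' roc_curve(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))$auc
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 and scores non-missing", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  us <- sort(unique(scores), decreasing = TRUE)
  mids <- if (length(us) > 1L) (us[-1L] + us[-length(us)]) / 2 else numeric()
  thr <- c(Inf, mids, -Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n_neg,
                 numeric(1))
  x <- 1 - spec
  auc <- sum(diff(x) * (sens[-1L] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # thresholds descending: last = smallest
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_threshold = thr[best],
                 youden_j = j[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f, Youden J %.4f at threshold %.4g\n",
              x$auc, x$youden_j, x$youden_threshold))
  invisible(x)
}

#' Youden operating threshold of a ROC curve
#'
#' @param curve a [roc_curve()].
#' @return the threshold maximizing sensitivity + specificity - 1; ties are
#'   broken toward the smallest threshold.
#' @export
youden <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  curve$youden_threshold
}

#' Two-by-two confusion counts
#'
#' @param labels binary 0/1 truth.
#' @param predictions binary 0/1 predictions of equal length.
#' @return 2 x 2 integer matrix, rows = truth (positive, negative), columns
#'   = predicted (positive, negative); entries sum to the input length.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length", call. = FALSE)
  if (!all(c(labels, predictions) %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  m <- matrix(c(sum(labels == 1L & predictions == 1L),
                sum(labels == 0L & predictions == 1L),
                sum(labels == 1L & predictions == 0L),
                sum(labels == 0L & predictions == 0L)), 2L, 2L)
  dimnames(m) <- list(truth = c("positive", "negative"),
                      predicted = c("positive", "negative"))
  m
}

#' Assign items to cross-validation folds
#'
#' Seeded random partition into `n_folds` near-equal groups (sizes differing
#' by at most one). When `labels` are supplied the partition is stratified:
#' items are shuffled within each class and dealt cyclically, so every fold
#' receives a near-equal share of each class — important at low prevalence,
#' where an unstratified split can leave folds without a single positive.
#'
#' @param ids distinct item ids (length >= `n_folds`).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @param labels optional per-id class labels for stratification.
#' @return an object of class `fold_assignment`: integer fold index in
#'   `1..n_folds` named by id, with `seed` and `n_folds` attributes.
#' @export
make_folds <- function(ids, n_folds = 10L, seed = 1L, labels = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("ids must be distinct", call. = FALSE)
  n <- length(ids)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n < n_folds) stop("fewer ids than folds", call. = FALSE)
  order_ids <- .with_seed(seed, {
    if (is.null(labels)) sample.int(n)
    else {
      if (length(labels) != n)
        stop("labels must match ids", call. = FALSE)
      unlist(lapply(split(seq_len(n), labels),
                    function(ix) ix[sample.int(length(ix))]),
             use.names = FALSE)
    }
  })
  fold <- integer(n)
  fold[order_ids] <- rep_len(seq_len(n_folds), n)
  names(fold) <- ids
  structure(fold, seed = as.integer(seed), n_folds = as.integer(n_folds),
            class = "fold_assignment")
}

#' Cross-validated image-search classification
#'
#' Runs the full retrieval-classification protocol under stratified k-fold
#' cross-validation. In each fold the held-out group is the query set and
#' the remaining items form the searchable archive. Modes:
#' \describe{
#'   \item{`"raw"`}{search directly on the stored descriptors.}
#'   \item{`"autothorax"`}{per fold, pretrain the autoencoder on the
#'     archive, fine-tune it with inverse-frequency class weights on the
#'     archive labels, strip the head, encode archive and queries, then
#'     search on the codes.}
#'   \item{`"pca"`}{per fold, fit PCA on the archive and search on the
#'     projected codes (the linear baseline).}
#' }
#' For every query the class likelihood is the positive fraction m/k among
#' its k nearest archived neighbours. Per fold, a ROC curve is built from
#' the likelihoods, the Youden threshold selected on it, and sensitivity /
#' specificity reported at that operating point alongside the fold AUC.
#'
#' @param store a labelled [feature_store()] (binary, no NA).
#' @param mode `"raw"`, `"autothorax"` or `"pca"`.
#' @param k vector of neighbour counts to evaluate (each clipped at the
#'   archive size).
#' @param n_folds number of folds (default 10).
#' @param seed master seed for fold assignment and per-fold encoder
#'   training.
#' @param spec optional [encoder_spec()] for `"autothorax"`; defaults to
#'   the standard funnel ending at 256 with the input width taken from the
#'   store. Its seed is re-derived per fold.
#' @param pca_dim number of components for `"pca"` (default 256).
#' @return an object of class `eval_report`: list with `per_fold`
#'   (data.frame: fold, k, auc, sensitivity, specificity, threshold),
#'   `summary` (per-k means and standard deviations), `confusion` (per-k
#'   2 x 2 counts summed over folds), and the run metadata.
#' @export
run_cv <- function(store, mode = c("raw", "autothorax", "pca"), k = 11L,
                   n_folds = 10L, seed = 1L, spec = NULL, pca_dim = 256L) {
  mode <- match.arg(mode)
  stopifnot(inherits(store, "feature_store"))
  y <- store$labels
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("run_cv requires binary 0/1 labels", call. = FALSE)
  k <- sort(unique(as.integer(k)))
  if (any(k < 1L)) stop("k must be >= 1", call. = FALSE)
  folds <- make_folds(store$ids, n_folds, seed, labels = y)
  per_fold <- vector("list", n_folds)
  conf <- lapply(k, function(kk)
    matrix(0L, 2L, 2L, dimnames = list(truth = c("positive", "negative"),
                                       predicted = c("positive", "negative"))))
  names(conf) <- as.character(k)
  for (f in seq_len(n_folds)) {
    val_idx <- which(folds == f)
    arch_idx <- which(folds != f)
    y_arch <- y[arch_idx]
    if (length(unique(y_arch)) < 2L)
      stop(sprintf("fold %d archive is missing a class", f), call. = FALSE)
    if (length(unique(y[val_idx])) < 2L)
      stop(sprintf("fold %d validation set is missing a class", f),
           call. = FALSE)
    arch <- store[arch_idx]
    val <- store[val_idx]
    if (mode == "autothorax") {
      sp <- if (is.null(spec))
        encoder_spec(layer_widths = .default_funnel(ncol(store$features)))
      else spec
      sp$seed <- .substream_seed(seed, 1000L + f)
      model <- pretrain_autoencoder(arch, sp)
      model <- finetune_with_labels(model, arch)
      model <- strip_head(model)
      arch <- encode_store(model, arch)
      val <- encode_store(model, val)
    } else if (mode == "pca") {
      fit <- pca_compress(arch, pca_dim)
      arch <- fit$codes
      proj <- sweep(val$features, 2L, fit$center) %*% fit$rotation
      dimnames(proj) <- NULL
      val <- feature_store(proj, val$ids, val$labels, config = "code",
                           backbone = sprintf("pca-%d", pca_dim))
    }
    index <- build_index(arch)
    d2 <- .distance_matrix(val$features, index)
    ord <- t(apply(d2, 1L, order))
    rows <- lapply(k, function(kk) {
      k_eff <- min(kk, index$n)
      m <- vapply(seq_len(nrow(ord)), function(i)
        sum(index$labels[ord[i, seq_len(k_eff)]] == 1L), integer(1))
      lik <- m / k_eff
      roc <- roc_curve(lik, val$labels)
      thr <- min(max(roc$youden_threshold, 0), 1)
      pred <- as.integer(lik >= thr)
      cm <- confusion_counts(val$labels, pred)
      conf[[as.character(kk)]] <<- conf[[as.character(kk)]] + cm
      data.frame(fold = f, k = kk, auc = roc$auc,
                 sensitivity = cm[1, 1] / sum(cm[1, ]),
                 specificity = cm[2, 2] / sum(cm[2, ]),
                 threshold = thr)
    })
    per_fold[[f]] <- do.call(rbind, rows)
  }
  per_fold <- do.call(rbind, per_fold)
  agg <- lapply(split(per_fold, per_fold$k), function(d)
    data.frame(k = d$k[1], mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = stats::sd(d$sensitivity),
               mean_specificity = mean(d$specificity),
               sd_specificity = stats::sd(d$specificity)))
  structure(list(per_fold = per_fold,
                 summary = do.call(rbind, c(agg, make.row.names = FALSE)),
                 confusion = conf, mode = mode, k = k,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 n = nrow(store$features)),
            class = "eval_report")
}

# Default encoder funnel for a given input width: halve (at least) down to
# a 256 bottleneck, mirroring the canonical 3072 -> 1024 -> 512 -> 256.
.default_funnel <- function(input_dim) {
  if (input_dim == 3072L) return(c(3072L, 1024L, 512L, 256L))
  widths <- input_dim
  while (widths[length(widths)] > 512L)
    widths <- c(widths, widths[length(widths)] %/% 2L)
  unique(c(widths, 256L))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mode=%s, %d folds, n=%d, seed=%d\n", x$mode,
              x$n_folds, x$n, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares two matched per-fold metric vectors. Zero differences are
#' dropped; absolute differences are ranked with mid-ranks on ties; the
#' statistic is the sum of ranks of positive differences. The two-sided
#' p-value is exact (by sign-flip enumeration over the rank distribution)
#' for up to 25 non-zero differences, and uses the tie-corrected normal
#' approximation above that.
#'
#' @param a,b numeric vectors of equal length >= 5 (e.g. per-fold AUCs of
#'   two methods).
#' @return list with `statistic` (V), `p_value`, `n_nonzero` and `method`.
#' @export
#' @examples
#' wilcoxon_paired(c(.92, .91, .93, .92, .92, .91),
#'                 c(.88, .89, .88, .87, .90, .88))
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of V via DP over doubled ranks (integers even
    # with mid-ranks); each rank joins the positive set with prob 1/2
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))  # counts[s + 1] = #assignments, sum s
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (sign-flip enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = v, p_value = p, n_nonzero = n, method = method)
}
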