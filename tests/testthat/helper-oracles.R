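# Independent oracles used across the suite. Each is a brute-force or
# closed-form computation that shares no code with the implementation it
# checks.

# Exhaustive nearest-neighbour scan: plain per-row loop, stable tie order.
oracle_knn <- function(archive, query, k) {
  d <- numeric(nrow(archive))
  for (i in seq_len(nrow(archive)))
    d[i] <- sqrt(sum((archive[i, ] - query)^2))
  ord <- seq_along(d)[order(d, seq_along(d), method = "radix")]
  ord <- ord[seq_len(min(k, length(d)))]
  list(idx = ord, dist = d[ord])
}

# Mann-Whitney concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden sweep over candidate thresholds under the >= rule;
# ties broken toward the smallest threshold.
oracle_youden <- function(scores, labels) {
  us <- sort(unique(scores), decreasing = TRUE)
  cand <- c(Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, -Inf)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j || (j == best_j && t < best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    vs[mask + 1] <- sum(r[signs])
  }
  p <- min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
  list(statistic = v, p_value = p)
}

# Closed-form centre-aligned bilinear interpolation of `img` at a single
# output pixel (i, j) of an out_h x out_w grid.
oracle_bilinear_at <- function(img, i, j, out_h, out_w) {
  coord <- function(idx, n_in, n_out) {
    s <- (idx - 0.5) * n_in / n_out + 0.5
    min(max(s, 1), n_in)
  }
  y <- coord(i, nrow(img), out_h)
  x <- coord(j, ncol(img), out_w)
  y0 <- min(floor(y), nrow(img) - 1)
  x0 <- min(floor(x), ncol(img) - 1)
  fy <- y - y0
  fx <- x - x0
  (1 - fy) * (1 - fx) * img[y0, x0] + (1 - fy) * fx * img[y0, x0 + 1] +
    fy * (1 - fx) * img[y0 + 1, x0] + fy * fx * img[y0 + 1, x0 + 1]
}

# Per-channel block means of a square image, naive double loop.
oracle_block_means <- function(img, block) {
  nb <- nrow(img) %/% block
  out <- matrix(0, nb, nb)
  for (bi in seq_len(nb))
    for (bj in seq_len(nb))
      out[bi, bj] <- mean(img[((bi - 1) * block + 1):(bi * block),
                              ((bj - 1) * block + 1):(bj * block)])
  out
}

# Small labelled store fixture.
make_tiny_store <- function(n = 30, d = 8, seed = 1, sep = 4,
                            positive_fraction = 0.3) {
  generate_feature_clusters(feature_sim_spec(
    n, dim = d, informative_dim = max(1, d %/% 4), separation = sep,
    positive_fraction = positive_fraction, seed = seed))
}
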