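# Brute-force oracles, deliberately written as explicit loops and naive
# enumerations, independent of the package's implementation paths.

oracle_moments <- function(v) {
  n <- length(v)
  mu <- 0
  for (x in v) mu <- mu + x / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    d <- x - mu
    m2 <- m2 + d^2 / n
    m3 <- m3 + d^3 / n
    m4 <- m4 + d^4 / n
  }
  sig <- sqrt(m2)
  list(mean = mu, sd = sig,
       skewness = m3 / sig^3, kurtosis = m4 / sig^4)
}

oracle_entropy_bits <- function(v, width = 1) {
  bins <- floor(v / width)
  h <- 0
  for (b in unique(bins)) {
    p <- sum(bins == b) / length(v)
    h <- h - p * log2(p)
  }
  h
}

oracle_percentile <- function(v, prob) {
  # linear interpolation between closest order statistics (type 7)
  s <- sort(v)
  h <- (length(s) - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1 else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    stat <- stat + (tab[i, j] - E[i, j])^2 / E[i, j]
  }
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

oracle_confusion <- function(x, malignant, threshold) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(x)) {
    pos <- x[i] >= threshold
    if (malignant[i] && pos) tp <- tp + 1
    if (malignant[i] && !pos) fn <- fn + 1
    if (!malignant[i] && !pos) tn <- tn + 1
    if (!malignant[i] && pos) fp <- fp + 1
  }
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

oracle_stump <- function(x, y) {
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p <- mean(yy)
    2 * p * (1 - p)
  }
  u <- sort(unique(x))
  parent <- gini(y)
  best_dec <- -Inf
  best_t <- NA
  for (k in seq_len(length(u) - 1)) {
    t <- (u[k] + u[k + 1]) / 2
    right <- x >= t
    dec <- parent - mean(right) * gini(y[right]) -
      mean(!right) * gini(y[!right])
    if (dec > best_dec + 1e-12) {
      best_dec <- dec
      best_t <- t
    }
  }
  list(threshold = best_t, impurity_decrease = best_dec, parent = parent)
}

# Mean of a lower-truncated normal by numerical integration (no closed
# form shared with the implementation).
oracle_tnorm_mean <- function(mu, sigma, lower) {
  z <- integrate(function(x) dnorm(x, mu, sigma), lower, Inf,
                 rel.tol = 1e-12)$value
  integrate(function(x) x * dnorm(x, mu, sigma), lower, Inf,
            rel.tol = 1e-12)$value / z
}

make_disk <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  matrix((g$row - c0)^2 + (g$col - c0)^2 <= r^2, n, n)
}

make_square <- function(a, pad = 10) {
  n <- a + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + a), (pad + 1):(pad + a)] <- TRUE
  m
}

make_ellipse <- function(a, b, pad = 10) {
  n <- 2 * (max(a, b) + pad) + 1
  c0 <- max(a, b) + pad + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  matrix(((g$row - c0) / b)^2 + ((g$col - c0) / a)^2 <= 1, n, n)
}

random_feature_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    node_id = sprintf("n%03d", seq_len(n)),
    label = c("benign", "malignant",
              sample(c("benign", "malignant"), n - 2, replace = TRUE,
                     prob = c(0.55, 0.45))),
    score = round(rnorm(n), 1)  # rounding forces ties
  )
}
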