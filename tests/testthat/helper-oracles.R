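# Independent oracle implementations used to cross-check the package.
# Each is written straight from the underlying definition, not by
# calling the code path it checks.

# keyed multiplicative-congruential stream, reimplemented
oracle_lcg <- function(key, n) {
  M <- 2147483647; A <- 48271
  x <- (key %% (M - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (A * x) %% M
    out[i] <- 2 * x / M - 1
  }
  out
}

# mock embedding row reimplemented from its documented construction
oracle_mock_row <- function(dim, seed, period, jitter, letter, pos) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  li <- match(letter, alpha)
  M <- 2147483647
  key_base <- ((seed + 1) * 1000003 + li * 101) %% M
  key_pos <- ((seed + 1) * 1000003 + li * 101 +
              (1 + (pos - 1) %% period) * 7919) %% M
  base <- numeric(dim)
  own <- (seq_len(dim) - 1L) %% 20L == (li - 1L)
  base[own] <- 0.75 + 0.25 * oracle_lcg(key_base, sum(own))
  base + jitter * oracle_lcg(key_pos, dim)
}

# Mann-Whitney pairwise AUC estimator, ties counted one half
oracle_mw_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# exact Shapley values for a 2-feature model by enumerating both
# orderings, marginal contributions averaged over the background
oracle_shapley_2feat <- function(f, x, background) {
  nb <- nrow(background)
  f_bg <- mean(f(background))
  with1 <- background; with1[, 1] <- x[1]
  with2 <- background; with2[, 2] <- x[2]
  f_1 <- mean(f(with1)); f_2 <- mean(f(with2))
  f_12 <- f(matrix(x, 1))
  phi1 <- 0.5 * ((f_1 - f_bg) + (f_12 - f_2))
  phi2 <- 0.5 * ((f_2 - f_bg) + (f_12 - f_1))
  c(phi1, phi2)
}

# Chou-style pseudo amino-acid composition, independent loop-based
# reimplementation with the same three property scales
oracle_paac <- function(sequence, lam, w) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  h1 <- c(0.62, 0.29, -0.9, -0.74, 1.19, 0.48, -0.4, 1.38, -1.5, 1.06,
          0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26)
  h2 <- c(-0.5, -1, 3, 3, -2.5, 0, -0.5, -1.8, 3, -1.8,
          -1.3, 0.2, 0, 0.2, 3, 0.3, -0.4, -1.5, -3.4, -2.3)
  h3 <- c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
          75, 58, 42, 72, 101, 31, 45, 43, 130, 107)
  std <- function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  scales <- list(std(h1), std(h2), std(h3))
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    acc <- 0
    for (i in seq_len(L - j)) {
      a <- match(ch[i], alpha); b <- match(ch[i + j], alpha)
      acc <- acc + mean(vapply(scales, function(s) (s[b] - s[a])^2,
                               numeric(1)))
    }
    theta[j] <- acc / (L - j)
  }
  f <- vapply(alpha, function(a) sum(ch == a), numeric(1)) / L
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# one midpoint-free random labeled matrix for sampling tests
random_labeled <- function(n_min, n_maj, dim, seed) {
  set.seed(seed)
  X <- matrix(rnorm((n_min + n_maj) * dim), n_min + n_maj, dim)
  labeled_matrix(X, c(rep(1L, n_min), rep(0L, n_maj)))
}
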