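# Shared fixtures, built in code.

# Gaussian blobs in d dimensions: centers is a k x d matrix, n_per cells per
# blob, unit noise SD. Returns list(x, labels).
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per * d, mean = rep(centers[j, ], each = n_per), sd = sd),
           nrow = n_per)
  }))
  rownames(x) <- sprintf("cell_%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("dim_%02d", seq_len(d))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Two blobs separated by `sep` along the first of d dimensions.
make_pair <- function(n_per, sep, d = 10, seed = 1) {
  centers <- matrix(0, 2, d)
  centers[2, 1] <- sep
  make_blobs(n_per, centers, seed = seed)
}

# Small dense count matrix with named dims.
tiny_counts <- function(values, cells = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cells %||% sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%d", seq_len(ncol(m)))
  Matrix::Matrix(m, sparse = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All set partitions of n items as label vectors (Bell-number many).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (j in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, j)
  }
  out
}

# Brute-force ARI by enumerating all item pairs.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- 1
  for (i in rev(seq_len(m))) {
    run_min <- min(run_min, p[o[i]] * m / i)
    adj[o[i]] <- run_min
  }
  adj
}

# Direct-summation upper-tail hypergeometric oracle.
hyper_bruteforce <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
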