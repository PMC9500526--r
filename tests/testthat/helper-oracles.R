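# Independent brute-force oracles, coded from the definitions with naive
# loops. They deliberately share no code with the package internals.

MISSING_CHARS <- c("N", "-")

# Diversity statistics by exhaustive per-site / per-pair recount.
# Complete deletion for K/H/S; Pi by pairwise deletion (or complete).
oracle_div <- function(mat, pi_complete = FALSE) {
  mat <- toupper(mat)
  n <- nrow(mat)
  complete_cols <- c()
  for (j in seq_len(ncol(mat))) {
    if (!any(mat[, j] %in% MISSING_CHARS)) complete_cols <- c(complete_cols, j)
  }
  R <- mat[, complete_cols, drop = FALSE]
  haps <- character(0)
  for (i in seq_len(n)) haps <- c(haps, paste(R[i, ], collapse = ""))
  K <- length(unique(haps))
  H <- 0
  if (K > 1) {
    fr <- as.numeric(table(haps)) / n
    H <- (n / (n - 1)) * (1 - sum(fr * fr))
  }
  S <- 0
  for (j in seq_len(ncol(R))) if (length(unique(R[, j])) > 1) S <- S + 1
  tot <- 0; npair <- 0
  src <- if (pi_complete) R else mat
  for (i in 1:(n - 1)) for (k in (i + 1):n) {
    npair <- npair + 1
    for (j in seq_len(ncol(src))) {
      a <- src[i, j]; b <- src[k, j]
      if (!(a %in% MISSING_CHARS) && !(b %in% MISSING_CHARS) && a != b)
        tot <- tot + 1
    }
  }
  list(K = K, H = H, S = S, Pi = tot / npair)
}

# Independent transcription of the Tajima 1989 constants.
oracle_tajima <- function(S, Pi, n) {
  if (S == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (Pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Pairwise raw-difference count by exhaustive recount (pairwise deletion).
oracle_diff_matrix <- function(mat) {
  mat <- toupper(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (k in (i + 1):n) {
    cnt <- 0
    for (j in seq_len(ncol(mat))) {
      a <- mat[i, j]; b <- mat[k, j]
      if (!(a %in% MISSING_CHARS) && !(b %in% MISSING_CHARS) && a != b)
        cnt <- cnt + 1
    }
    d[i, k] <- d[k, i] <- cnt
  }
  d
}

# Scalar K2P distance for one pair of gap-free sequences.
oracle_k2p_pair <- function(s1, s2) {
  purines <- c("A", "G")
  m <- 0; ts <- 0; tv <- 0
  for (j in seq_along(s1)) {
    a <- s1[j]; b <- s2[j]
    if (a %in% MISSING_CHARS || b %in% MISSING_CHARS) next
    m <- m + 1
    if (a != b) {
      if ((a %in% purines) == (b %in% purines)) ts <- ts + 1 else tv <- tv + 1
    }
  }
  P <- ts / m; Q <- tv / m
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# One-level AMOVA decomposition straight from the sums of squares, with a
# different accumulation style from the package (explicit double loops).
oracle_amova <- function(d, g) {
  g <- as.character(g)
  N <- length(g)
  labs <- unique(g)
  P <- length(labs)
  tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) tot <- tot + d[i, j]
  ssd_t <- tot / N
  ssd_w <- 0
  for (lab in labs) {
    idx <- which(g == lab)
    acc <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d[idx[a], idx[b]]
    ssd_w <- ssd_w + acc / length(idx)
  }
  ssd_a <- ssd_t - ssd_w
  s2w <- ssd_w / (N - P)
  sum_sq <- 0
  for (lab in labs) sum_sq <- sum_sq + sum(g == lab)^2
  nprime <- (N - sum_sq / N) / (P - 1)
  s2a <- (ssd_a / (P - 1) - s2w) / nprime
  list(sigma2_among = s2a, sigma2_within = s2w,
       phi = if (s2a + s2w > 0) s2a / (s2a + s2w) else 0,
       ssd_total = ssd_t, ssd_within = ssd_w, ssd_among = ssd_a)
}

# Classical scaling by explicit double-centering and eigendecomposition.
oracle_mds <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  kk <- min(k, length(pos))
  e$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(kk)]]), kk)
}

# PCA scores via eigendecomposition of the covariance of centered rows.
oracle_pca_scores <- function(X, k) {
  Xc <- sweep(X, 2, colMeans(X))
  e <- eigen(stats::cov(Xc), symmetric = TRUE)
  (Xc %*% e$vectors)[, seq_len(k), drop = FALSE]
}

# Random test alignment with optional missing data.
random_alignment <- function(n, L, p_missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (p_missing > 0) {
    hit <- which(runif(n * L) < p_missing)
    m[hit] <- sample(c("N", "-"), length(hit), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n))
  m
}
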