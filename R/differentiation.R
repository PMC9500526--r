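# Distance matrices, one-level distance AMOVA / PhiST, pairwise PhiST, MDS.

#' Pairwise difference matrix
#'
#' Entry (i, j) is the number of sites at which sequences i and j carry
#' different non-missing bases, under pairwise deletion: each pair is
#' compared over the sites complete in that pair.
#'
#' @param aln An `mt_alignment` (or character/integer matrix).
#' @param allow_null Permit pairs with zero jointly complete sites? If
#'   `FALSE` (default) such a pair is an error; if `TRUE` its distance is
#'   `NA` with a warning.
#' @return Symmetric numeric matrix (zero diagonal) with a `metric`
#'   attribute `"raw_differences"`.
#' @export
difference_matrix <- function(aln, allow_null = FALSE) {
  M <- as_base_int(aln)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 sequences")
  miss <- M >= 5L
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  null_pairs <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      if (!any(ok)) {
        if (!allow_null)
          stop("pair (", rownames(M)[i], ", ", rownames(M)[j],
               ") has no jointly complete site")
        d[i, j] <- d[j, i] <- NA_real_
        null_pairs <- null_pairs + 1L
        next
      }
      d[i, j] <- d[j, i] <- sum(M[i, ok] != M[j, ok])
    }
  }
  if (null_pairs > 0L)
    warning(null_pairs, " pair(s) with no jointly complete site set to NA")
  attr(d, "metric") <- "raw_differences"
  d
}

#' Kimura two-parameter distance matrix
#'
#' For each pair, over jointly complete sites, computes the transition
#' proportion P (A<->G, C<->T) and transversion proportion Q, then
#' \eqn{d = -\tfrac{1}{2}\ln\big((1-2P-Q)\sqrt{1-2Q}\big)}.
#' Saturated pairs (log argument <= 0) get `NA` with a warning.
#'
#' @param aln An `mt_alignment` (or character/integer matrix).
#' @return Symmetric numeric matrix with `metric` attribute `"K2P"`.
#' @export
k2p_matrix <- function(aln) {
  M <- as_base_int(aln)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 sequences")
  miss <- M >= 5L
  purine <- M == 1L | M == 3L            # A or G
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  saturated <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      m <- sum(ok)
      if (m == 0L) stop("pair (", rownames(M)[i], ", ", rownames(M)[j],
                        ") has no jointly complete site")
      diff <- ok & (M[i, ] != M[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))   # same base class
      tv <- sum(diff) - ts
      P <- ts / m
      Q <- tv / m
      arg <- if (1 - 2 * Q <= 0) -1 else (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
      if (arg <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        saturated <- saturated + 1L
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(arg)
      }
    }
  }
  if (saturated > 0L)
    warning(saturated, " saturated pair(s) set to NA (K2P log argument <= 0)")
  attr(d, "metric") <- "K2P"
  d
}

# One-level AMOVA variance decomposition from a distance matrix and an
# integer/character group assignment vector. Distances are interpreted as
# squared (the convention for molecular pairwise-difference AMOVA).
amova_components <- function(d, g) {
  g <- as.factor(g)
  N <- length(g)
  sizes <- as.integer(table(g))
  P <- nlevels(g)
  lt <- lower.tri(d)
  ssd_total <- sum(d[lt]) / N
  ssd_within <- 0
  for (k in levels(g)) {
    idx <- which(g == k)
    sub <- d[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1L
  df_within <- N - P
  s2w <- ssd_within / df_within
  n_prime <- (N - sum(sizes^2) / N) / (P - 1L)
  s2a <- (ssd_among / df_among - s2w) / n_prime
  phi <- if ((s2a + s2w) > 0) s2a / (s2a + s2w) else 0
  list(sigma2_among = s2a, sigma2_within = s2w, phi_st = phi,
       ssd_total = ssd_total, ssd_within = ssd_within, ssd_among = ssd_among,
       df_among = df_among, df_within = df_within, n_prime = n_prime)
}

# Resolve a partition (named list of ids) against a distance matrix,
# returning the row indices and the assignment factor.
resolve_partition <- function(d, partition, min_size = 2L) {
  if (is.null(rownames(d))) stop("distance matrix must have rownames")
  if (length(partition) < 2L) stop("need at least 2 groups")
  sizes <- vapply(partition, length, integer(1))
  if (any(sizes < min_size))
    stop("every group needs at least ", min_size, " members (",
         paste(names(partition)[sizes < min_size], collapse = ", "), ")")
  ids <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(ids)) stop("an id appears in two groups")
  idx <- match(ids, rownames(d))
  if (anyNA(idx))
    stop("ids not in distance matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  g <- factor(rep(names(partition), sizes), levels = names(partition))
  list(idx = idx, g = g)
}

#' One-level AMOVA with permutation test
#'
#' Distance-based analysis of molecular variance across groups. With total
#' sample size N, P groups of sizes n_k, and pairwise distances d (raw
#' difference counts, used directly as squared distances):
#' SSD_total = (1/N) sum_{i<j} d_ij;
#' SSD_within = sum_k (1/n_k) sum_{i<j in k} d_ij;
#' SSD_among = SSD_total - SSD_within; sigma2_within = SSD_within/(N-P);
#' n' = (N - sum n_k^2 / N)/(P-1);
#' sigma2_among = (SSD_among/(P-1) - sigma2_within)/n';
#' PhiST = sigma2_among / (sigma2_among + sigma2_within).
#'
#' Significance is assessed by permuting individual group labels; the
#' p-value is the +1-smoothed proportion of permuted PhiST values greater
#' than or equal to the observed one, with standard error
#' sqrt(p(1-p)/n_perm).
#'
#' @param d Symmetric distance matrix with sample ids as rownames (see
#'   [difference_matrix()]).
#' @param partition Named list of id vectors; at least 2 groups, each with
#'   at least 2 members.
#' @param n_perm Number of label permutations (default 10000; a warning is
#'   issued below 100; 0 skips the test).
#' @param seed Optional RNG seed for the permutations.
#' @return Object of class `amova_result`: variance components, `phi_st`,
#'   `p_value`, `p_se`, `n_perm`, degrees of freedom and SSD terms.
#' @export
amova <- function(d, partition, n_perm = 10000L, seed = NULL) {
  rp <- resolve_partition(d, partition)
  dsub <- d[rp$idx, rp$idx, drop = FALSE]
  if (anyNA(dsub)) stop("distance matrix contains NA entries")
  obs <- amova_components(dsub, rp$g)
  p_value <- NA_real_
  p_se <- NA_real_
  if (n_perm > 0L) {
    if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value")
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(rp$g)
      if (amova_components(dsub, gp)$phi_st >= obs$phi_st) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_perm + 1)
    p_se <- sqrt(p_value * (1 - p_value) / n_perm)
  }
  structure(c(obs, list(p_value = p_value, p_se = p_se,
                        n_perm = as.integer(n_perm))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level)\n")
  cat(sprintf("  among groups : df=%d  sigma2=%.5f\n", x$df_among,
              x$sigma2_among))
  cat(sprintf("  within groups: df=%d  sigma2=%.5f\n", x$df_within,
              x$sigma2_within))
  cat(sprintf("  PhiST = %.5f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf("   p = %.5f +- %.5f (%d permutations)", x$p_value, x$p_se,
                x$n_perm))
  cat("\n")
  invisible(x)
}

#' Pairwise PhiST matrix
#'
#' Runs the two-group AMOVA decomposition for every pair of groups.
#' Negative estimates (sampling noise around zero differentiation) are
#' retained.
#'
#' @inheritParams amova
#' @return Symmetric numeric matrix of pairwise PhiST (zero diagonal).
#' @export
pairwise_fst <- function(d, partition) {
  rp <- resolve_partition(d, partition)  # validates sizes / ids
  gn <- names(partition)
  P <- length(gn)
  out <- matrix(0, P, P, dimnames = list(gn, gn))
  for (a in 1:(P - 1)) {
    for (b in (a + 1):P) {
      ids <- c(partition[[a]], partition[[b]])
      idx <- match(ids, rownames(d))
      g <- factor(rep(gn[c(a, b)], c(length(partition[[a]]),
                                     length(partition[[b]]))))
      phi <- amova_components(d[idx, idx, drop = FALSE], g)$phi_st
      out[a, b] <- out[b, a] <- phi
    }
  }
  out
}

#' Classical multidimensional scaling of a PhiST matrix
#'
#' Classical (Torgerson) MDS via double-centering of the squared
#' dissimilarity matrix and eigendecomposition, as implemented by
#' `stats::cmdscale`. Negative entries (retained negative PhiST estimates)
#' are clamped to 0 first, since MDS needs a dissimilarity.
#'
#' @param fst Symmetric matrix with zero diagonal (e.g. [pairwise_fst()]).
#' @param k Number of dimensions requested (default 2). If fewer positive
#'   eigenvalues are available, fewer columns are returned with a warning.
#' @return List with `points` (groups x <= k coordinates) and `eig`
#'   (all eigenvalues of the doubly centered matrix).
#' @export
classical_mds <- function(fst, k = 2L) {
  if (!isSymmetric(unname(fst), tol = 1e-8))
    stop("input must be a symmetric dissimilarity matrix")
  if (any(fst < 0)) {
    message("clamping ", sum(fst < 0 & upper.tri(fst)),
            " negative entr(ies) to 0 for MDS")
    fst[fst < 0] <- 0
  }
  k <- min(k, nrow(fst) - 1L)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(fst), k = k, eig = TRUE))
  pts <- fit$points
  npos <- sum(fit$eig > max(fit$eig) * 1e-8)
  if (npos < k) {
    warning("only ", npos, " positive-eigenvalue dimension(s) available")
    pts <- pts[, seq_len(min(ncol(pts), npos)), drop = FALSE]
  }
  list(points = pts, eig = fit$eig)
}
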