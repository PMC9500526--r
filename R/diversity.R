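# Within-group diversity statistics: K, H, S, Pi, Tajima's D.

# Map an alignment / character matrix / integer matrix to integer codes
# 1..6 per MT_BASES. N (5) and gap (6) are missing for all statistics.
as_base_int <- function(x) {
  if (inherits(x, "mt_alignment")) x <- x$seqs
  if (is.character(x)) {
    x <- normalize_bases(x)
    m <- match(x, MT_BASES)
    dim(m) <- dim(x)
    dimnames(m) <- dimnames(x)
    return(m)
  }
  if (is.numeric(x)) return(x)
  stop("cannot interpret input as sequences")
}

# Mean pairwise differences from an integer matrix with no missing data,
# via per-site allele counts: sum_site (n^2 - sum_b n_b^2) / (n (n-1)).
pi_from_counts <- function(V) {
  n <- nrow(V)
  if (ncol(V) == 0L) return(0)
  cnt <- matrix(0L, ncol(V), 4L)
  for (b in 1:4) cnt[, b] <- colSums(V == b)
  sum(n^2 - rowSums(cnt^2)) / (n * (n - 1))
}

# Diversity statistics for an integer matrix with no missing data (used on
# the segregating-site submatrix of simulated datasets; invariant columns
# contribute nothing to K, H, S or Pi).
div_stats_int <- function(V) {
  n <- nrow(V)
  if (n < 2L) stop("need at least 2 sequences")
  if (ncol(V) == 0L)
    return(list(n = n, K = 1L, H = 0, S = 0L, Pi = 0))
  key <- do.call(paste, c(as.data.frame(V), sep = ","))
  p <- as.numeric(table(key)) / n
  K <- length(p)
  H <- if (K == 1L) 0 else (n / (n - 1)) * (1 - sum(p^2))
  neq <- V != matrix(V[1L, ], n, ncol(V), byrow = TRUE)
  S <- sum(colSums(neq) > 0L)
  list(n = n, K = K, H = H, S = S, Pi = pi_from_counts(V))
}

#' Within-group diversity statistics
#'
#' Computes, for one group of aligned sequences: the number of distinct
#' haplotypes K, haplotype (gene) diversity
#' \eqn{H = \frac{n}{n-1}(1 - \sum_i p_i^2)}, the number of segregating
#' sites S, and the mean number of pairwise differences Pi (reported as a
#' count of differing sites, not per site).
#'
#' Missing data (`N` and `-`) are handled by complete deletion for K, H and
#' S: sites containing any missing value are removed first. Pi uses, by
#' default, pairwise deletion (each pair is compared over the sites complete
#' in that pair); set `pi_policy = "complete"` to compute Pi on the
#' complete-deletion matrix instead.
#'
#' @param x An `mt_alignment`, a character matrix (samples x sites), or an
#'   integer base-code matrix.
#' @param pi_policy Missing-data policy for Pi: `"pairwise"` (default) or
#'   `"complete"`.
#' @return List with `n`, `K`, `H`, `S`, `Pi` and `sites_retained` (sites
#'   surviving complete deletion).
#' @export
within_group_stats <- function(x, pi_policy = c("pairwise", "complete")) {
  pi_policy <- match.arg(pi_policy)
  M <- as_base_int(x)
  n <- nrow(M)
  if (is.null(n) || n < 2L) stop("need at least 2 sequences")
  miss <- M >= 5L
  keep <- colSums(miss) == 0L
  R <- M[, keep, drop = FALSE]
  if (ncol(R) == 0L) {
    warning("no sites retained under complete deletion; ",
            "statistics returned at their floors")
    return(list(n = n, K = 1L, H = 0, S = 0L, Pi = 0, sites_retained = 0L))
  }
  base <- div_stats_int(R)
  Pi <- if (pi_policy == "complete") {
    base$Pi
  } else {
    tot <- 0
    np <- 0L
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !miss[i, ] & !miss[j, ]
        tot <- tot + sum(M[i, ok] != M[j, ok])
        np <- np + 1L
      }
    }
    tot / np
  }
  list(n = n, K = base$K, H = base$H, S = base$S, Pi = Pi,
       sites_retained = ncol(R))
}

#' Tajima's D
#'
#' Standardized difference between the mean pairwise differences Pi and the
#' Watterson estimate S/a1, using the constants of the classical
#' neutrality-test formulation:
#' a1 = sum_{i=1}^{n-1} 1/i, a2 = sum 1/i^2, b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2),
#' D = (Pi - S/a1) / sqrt(e1 S + e2 S (S-1)).
#'
#' @param S Number of segregating sites.
#' @param Pi Mean pairwise differences.
#' @param n Sample size (must be >= 4; the variance terms are unstable below).
#' @return D, or `NA` when `S == 0` (the statistic is undefined).
#' @export
tajimas_d <- function(S, Pi, n) {
  if (n < 4L) stop("Tajima's D requires n >= 4")
  if (S < 0) stop("S must be non-negative")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Diversity statistics for every group of a grouped alignment
#'
#' One row per group with n, K, H, S, Pi and Tajima's D. D is `NA` for
#' monomorphic groups (S = 0) and for groups with n < 4, where it is
#' undefined.
#'
#' @param ga A `grouped_alignment`.
#' @param pi_policy Passed to [within_group_stats()].
#' @return Data frame with columns `group`, `n`, `K`, `H`, `S`, `Pi`, `D`.
#' @export
diversity_by_group <- function(ga, pi_policy = c("pairwise", "complete")) {
  stopifnot(inherits(ga, "grouped_alignment"))
  pi_policy <- match.arg(pi_policy)
  rows <- lapply(names(ga$partition), function(g) {
    st <- within_group_stats(group_matrix(ga, g), pi_policy = pi_policy)
    D <- if (st$n >= 4L && st$S > 0L) tajimas_d(st$S, st$Pi, st$n) else NA_real_
    data.frame(group = g, n = st$n, K = st$K, H = st$H, S = st$S,
               Pi = st$Pi, D = D, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
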