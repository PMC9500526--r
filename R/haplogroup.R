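# Macro-haplogroup collapsing, per-group frequency tables, frequency PCA.

#' Default macro-haplogroup scheme
#'
#' Ordered list of macro-haplogroup labels used for collapsing fine
#' haplogroup calls. Matching is longest-prefix against this list, so
#' `"HV0a"` collapses to `HV` (not `H`), `"H1e8"` to `H`, `"V25"` to `V`,
#' `"L3b1a5"` to `L3`. L sub-lineages not listed here fall back to `"L"`.
#'
#' @return Character vector of macro labels.
#' @export
default_macro_scheme <- function() {
  c("L0", "L1", "L2", "L3", "L4", "L5", "HV", "H", "V", "J", "T",
    "U", "K", "I", "W", "X", "N", "R", "M")
}

#' Collapse haplogroup labels to macro-haplogroups
#'
#' Strips suffix annotations introduced by extra defining mutations
#' (`"+151"`, `"+16,311"`, `"+72at"`, ...) and returns the longest scheme
#' prefix of the remainder. Labels with no matching prefix raise an error
#' (silent pooling into an "other" class would bias downstream frequency
#' analyses), except that unlisted `L` sub-lineages collapse to `"L"`.
#'
#' @param label Character vector of haplogroup labels (e.g. `"T2b3+151"`).
#' @param scheme Macro scheme, default [default_macro_scheme()].
#' @return Character vector of macro labels.
#' @export
collapse_to_macro <- function(label, scheme = default_macro_scheme()) {
  if (anyDuplicated(scheme)) stop("scheme labels must be unique")
  stem <- sub("\\+.*$", "", trimws(label))
  if (any(is.na(stem) | !nzchar(stem)))
    stop("empty or missing haplogroup label")
  vapply(stem, function(s) {
    hit <- scheme[startsWith(s, scheme)]
    if (length(hit)) return(hit[which.max(nchar(hit))])
    if (startsWith(s, "L")) return("L")
    stop("haplogroup label '", s, "' matches no macro-haplogroup in scheme")
  }, character(1), USE.NAMES = FALSE)
}

#' Per-group macro-haplogroup frequency table
#'
#' Counts macro-haplogroups per group and derives relative frequencies
#' (count / group size). Macro columns follow the scheme order; all-zero
#' macros are dropped.
#'
#' @param table A `sample_table` (every sample must carry a haplogroup label).
#' @param scheme Macro scheme, default [default_macro_scheme()].
#' @param group_field Grouping column name, default `"group"`.
#' @return Object of class `haplo_freq`: list with integer `counts`
#'   (groups x macros), numeric `freq` (rows sum to 1), `n` (group sizes)
#'   and `scheme`.
#' @export
frequency_table <- function(table, scheme = default_macro_scheme(),
                            group_field = "group") {
  if (!group_field %in% names(table))
    stop("grouping column '", group_field, "' not present")
  g <- as.character(table[[group_field]])
  if (any(is.na(g) | !nzchar(g))) stop("every sample needs a group label")
  if (any(is.na(table$haplogroup)))
    stop("every sample needs a haplogroup label")
  macro <- collapse_to_macro(table$haplogroup, scheme)
  lev <- intersect(c(scheme, "L"), unique(macro))
  counts <- table(factor(g, levels = unique(g)), factor(macro, levels = lev))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  n <- rowSums(counts)
  freq <- counts / n
  structure(list(counts = counts, freq = freq, n = n, scheme = scheme),
            class = "haplo_freq")
}

#' @export
print.haplo_freq <- function(x, digits = 3, ...) {
  cat("haplo_freq:", nrow(x$counts), "groups x", ncol(x$counts),
      "macro-haplogroups\n")
  print(round(x$freq, digits))
  invisible(x)
}

#' Principal component analysis of haplogroup frequencies
#'
#' Decomposes the column-centered (optionally unit-variance scaled) relative
#' frequency matrix by singular values, returning biplot-ready group scores
#' and haplogroup loadings. Constant (zero-variance) haplogroup columns are
#' dropped with a warning before the decomposition.
#'
#' @param freq A `haplo_freq` object.
#' @param scale_unit_variance Scale columns to unit variance before the
#'   decomposition? Default `FALSE` (centering only).
#' @return Object of class `haplo_pca`: list with `scores`
#'   (groups x components), `loadings` (haplogroups x components),
#'   `explained_variance_ratio`, and `dropped` (names of constant columns).
#' @export
pca_frequencies <- function(freq, scale_unit_variance = FALSE) {
  stopifnot(inherits(freq, "haplo_freq"))
  X <- freq$freq
  if (nrow(X) < 2L) stop("PCA needs at least 2 groups")
  v <- apply(X, 2L, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    warning("dropping constant haplogroup column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2L)
    stop("PCA needs at least 2 haplogroup columns with nonzero variance")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale_unit_variance)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation,
                 explained_variance_ratio = evr, dropped = dropped,
                 center = pr$center,
                 scale = if (scale_unit_variance) pr$scale else NULL),
            class = "haplo_pca")
}

#' @export
print.haplo_pca <- function(x, ...) {
  cat("haplo_pca:", nrow(x$scores), "groups,", ncol(x$scores), "components\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}
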