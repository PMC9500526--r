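# ABC model choice: summary vectors, reference tables, LDA augmentation,
# random-forest classification with OOB confusion and error-regression
# posterior probability.

#' Names and order of the summary-statistic vector
#'
#' Per group (A then B, in partition order): haplotype count K, haplotype
#' diversity H, segregating sites S, Tajima's D, mean pairwise differences
#' Pi; then the pairwise PhiST between the two groups. 11 values total.
#'
#' @return Character vector of length 11.
#' @export
summary_stat_names <- function() {
  c("K_A", "H_A", "S_A", "D_A", "Pi_A",
    "K_B", "H_B", "S_B", "D_B", "Pi_B", "FST")
}

# Pairwise difference matrix from an integer matrix with no missing data,
# via per-base match-count crossproducts (fast path for simulated data).
pair_diff_int <- function(V) {
  n <- nrow(V)
  if (ncol(V) == 0L) return(matrix(0, n, n))
  eq <- matrix(0, n, n)
  for (b in 1:4) {
    Ib <- V == b
    eq <- eq + tcrossprod(Ib)
  }
  d <- ncol(V) - eq
  diag(d) <- 0
  d
}

# D with the reference-table imputation rule: 0 (flagged upstream) when the
# group is monomorphic or too small for the variance constants.
impute_d <- function(S, Pi, n) {
  if (S > 0L && n >= 4L) tajimas_d(S, Pi, n) else 0
}

#' Summary-statistic vector of a two-group dataset
#'
#' Computes the 11 summary statistics of [summary_stat_names()] for a
#' dataset with exactly two groups. Tajima's D is imputed as 0 (and flagged
#' in the `"imputed"` attribute) for monomorphic groups, where it is
#' undefined — random-forest features cannot be missing. PhiST is the
#' two-group AMOVA point estimate on raw pairwise difference counts.
#'
#' @param x A `grouped_alignment` with two groups, or a compact `sim_seqs`.
#' @return Named numeric vector of length 11 with attribute `"imputed"`
#'   (logical, which D entries were imputed).
#' @export
summary_vector <- function(x) UseMethod("summary_vector")

#' @export
summary_vector.sim_seqs <- function(x) {
  gl <- unique(x$group)
  if (length(gl) != 2L) stop("exactly 2 groups required")
  iA <- x$group == gl[1]
  sA <- div_stats_int(x$tip[iA, , drop = FALSE])
  sB <- div_stats_int(x$tip[!iA, , drop = FALSE])
  d <- pair_diff_int(x$tip)
  fst <- amova_components(d, factor(ifelse(iA, "A", "B")))$phi_st
  assemble_summary(sA, sB, fst)
}

#' @export
summary_vector.grouped_alignment <- function(x) {
  if (length(x$partition) != 2L) stop("exactly 2 groups required")
  gn <- names(x$partition)
  sA <- within_group_stats(group_matrix(x, gn[1]))
  sB <- within_group_stats(group_matrix(x, gn[2]))
  ids <- unlist(x$partition, use.names = FALSE)
  d <- difference_matrix(subset_alignment(x$alignment, ids))
  g <- factor(rep(gn, group_sizes(x)), levels = gn)
  fst <- amova_components(d, g)$phi_st
  assemble_summary(sA, sB, fst)
}

assemble_summary <- function(sA, sB, fst) {
  dA <- impute_d(sA$S, sA$Pi, sA$n)
  dB <- impute_d(sB$S, sB$Pi, sB$n)
  out <- c(sA$K, sA$H, sA$S, dA, sA$Pi,
           sB$K, sB$H, sB$S, dB, sB$Pi, fst)
  names(out) <- summary_stat_names()
  attr(out, "imputed") <- c(D_A = sA$S == 0L || sA$n < 4L,
                            D_B = sB$S == 0L || sB$n < 4L)
  out
}

#' Build a simulated reference table for ABC model choice
#'
#' Simulates `n_sims_per_model` datasets under each of the two topologies
#' (labels balanced), with parameters drawn from the priors, and summarizes
#' each with [summary_vector()]. A simulation that fails is retried on a
#' fresh draw (at most 10 times) with a message. Reproducible under `seed`.
#'
#' @param priors `prior_set` used for the continuity model (and, by default,
#'   for the discontinuity model too).
#' @param sampling A `sampling_config`.
#' @param n_sims_per_model Simulations per model (the study scale is 50,000;
#'   a warning is issued below 100).
#' @param seed Optional RNG seed.
#' @param priors_discontinuity Optional separate `prior_set` for the
#'   discontinuity model.
#' @param L,gen_time Locus length and generation time.
#' @return Object of class `reference_table` (a data frame): column `model`,
#'   the 11 statistic columns, and the drawn parameters as `param_*` columns.
#' @export
build_reference_table <- function(priors, sampling, n_sims_per_model,
                                  seed = NULL, priors_discontinuity = priors,
                                  L = 16569L, gen_time = 25) {
  if (n_sims_per_model < 100L)
    warning("fewer than 100 simulations per model gives a weak classifier")
  if (!is.null(seed)) set.seed(seed)
  topos <- c("continuity", "discontinuity")
  nrows <- 2L * n_sims_per_model
  stats_mat <- matrix(NA_real_, nrows, 11L,
                      dimnames = list(NULL, summary_stat_names()))
  par_list <- vector("list", nrows)
  model <- rep(topos, each = n_sims_per_model)
  row <- 0L
  for (topo in topos) {
    pri <- if (topo == "continuity") priors else priors_discontinuity
    for (s in seq_len(n_sims_per_model)) {
      row <- row + 1L
      for (attempt in 1:10) {
        res <- tryCatch({
          sim <- simulate_dataset(topo, pri, sampling, L = L,
                                  gen_time = gen_time, compact = TRUE)
          sv <- summary_vector(sim$data)
          if (!all(is.finite(sv))) stop("non-finite summary statistic")
          list(sv = sv, params = sim$params)
        }, error = function(e) e)
        if (!inherits(res, "error")) break
        message("simulation retry (", topo, " #", s, ", attempt ", attempt,
                "): ", conditionMessage(res))
        if (attempt == 10L)
          stop("simulation failed 10 times for model ", topo)
      }
      stats_mat[row, ] <- res$sv
      par_list[[row]] <- res$params
    }
  }
  params <- do.call(rbind, par_list)
  names(params) <- paste0("param_", names(params))
  out <- cbind(data.frame(model = model, stringsAsFactors = FALSE),
               as.data.frame(stats_mat), params)
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Append the linear discriminant axis as an extra summary statistic
#'
#' Fits the Fisher linear discriminant between the two model labels on the
#' reference table only (never on the observation), and projects both the
#' table rows and the observed vector onto the axis; the projection is
#' appended as feature `LDA1`. With two models there is exactly M - 1 = 1
#' axis. A singular within-class scatter matrix is ridge-regularized
#' (relative ridge 1e-8) with a warning. The direction is normalized to
#' unit length with a fixed sign convention, so the projection does not
#' depend on row order.
#'
#' @param table A `reference_table`.
#' @param observed Named numeric vector of the 11 observed statistics.
#' @return List with `table` (one extra `LDA1` column), `observed` (one
#'   extra `LDA1` entry) and `direction` (the unit discriminant vector).
#' @export
augment_with_lda <- function(table, observed) {
  sn <- summary_stat_names()
  if (!all(sn %in% names(table))) stop("table lacks summary-statistic columns")
  if (!all(sn %in% names(observed))) stop("observed lacks summary statistics")
  X <- as.matrix(table[sn])
  y <- factor(table$model)
  if (nlevels(y) != 2L) stop("exactly 2 model labels required")
  lev <- levels(y)
  mu1 <- colMeans(X[y == lev[1], , drop = FALSE])
  mu2 <- colMeans(X[y == lev[2], , drop = FALSE])
  Sw <- crossprod(scale(X[y == lev[1], , drop = FALSE], center = mu1,
                        scale = FALSE)) +
        crossprod(scale(X[y == lev[2], , drop = FALSE], center = mu2,
                        scale = FALSE))
  dmu <- mu2 - mu1
  w <- tryCatch(solve(Sw, dmu), error = function(e) {
    warning("within-class scatter is singular; applying ridge 1e-8")
    solve(Sw + diag(1e-8 * mean(diag(Sw)) + 1e-12, ncol(Sw)), dmu)
  })
  w <- w / sqrt(sum(w^2))
  nz <- which(abs(w) > 1e-12)[1]            # fixed sign convention
  if (length(nz) && w[nz] < 0) w <- -w
  table$LDA1 <- drop(X %*% w)
  obs <- c(observed[sn], LDA1 = sum(observed[sn] * w))
  list(table = table, observed = obs, direction = w)
}

# Map per-tree ranger predictions (class codes) to class labels.
tree_votes <- function(rf, obs_df, num_threads) {
  pa <- stats::predict(rf, data = obs_df, predict.all = TRUE,
                       num.threads = num_threads)$predictions
  codes <- as.vector(pa)
  lab <- rf$forest$levels[rf$forest$class.values][codes]
  table(factor(lab, levels = rf$forest$levels))
}

#' Random-forest model choice with OOB error and posterior probability
#'
#' Trains a classification forest on the (LDA-augmented) reference table,
#' derives the confusion matrix and per-model classification errors from
#' the out-of-bag predictions, counts the trees voting for each model at
#' the observed point, and estimates the posterior probability of the
#' selected model as 1 minus the predicted misclassification probability at
#' the observed point — a regression forest fitted to the OOB
#' misclassification indicator as a function of the features (the ABC-RF
#' procedure).
#'
#' @param table Reference table (with `LDA1` from [augment_with_lda()]).
#' @param observed Named numeric vector of observed features (with `LDA1`).
#' @param n_trees Trees per forest (default 500; at least 100 advised).
#' @param seed Optional RNG seed (the regression forest uses `seed + 1`).
#' @param num_threads Threads for ranger (default 1, fully deterministic).
#' @return Object of class `model_choice`: `votes` (counts summing to
#'   `n_trees`), `selected`, `oob_confusion` (rows = true model),
#'   `classification_error` per model, `prior_error_rate` (overall OOB
#'   error), `posterior_probability`, `n_trees`, and the LDA coordinates of
#'   simulations and observation when present.
#' @export
train_and_select <- function(table, observed, n_trees = 500L, seed = NULL,
                             num_threads = 1L) {
  if (n_trees < 100L) warning("fewer than 100 trees gives unstable votes")
  feat <- intersect(c(summary_stat_names(), "LDA1"), names(table))
  if (!all(feat %in% names(observed)))
    stop("observed vector lacks feature(s): ",
         paste(setdiff(feat, names(observed)), collapse = ", "))
  y <- factor(table$model)
  df <- data.frame(model = y, table[feat], check.names = FALSE)
  rf <- ranger::ranger(model ~ ., data = df, num.trees = n_trees,
                       seed = seed, num.threads = num_threads)
  oob <- rf$predictions
  usable <- !is.na(oob)
  conf <- table(true = y[usable], predicted = oob[usable])
  cls_err <- 1 - diag(conf) / rowSums(conf)
  obs_df <- as.data.frame(as.list(observed[feat]))
  names(obs_df) <- feat
  votes <- tree_votes(rf, obs_df, num_threads)
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    warning("vote tie; selecting lexicographically first model")
    top <- top[order(names(votes)[top])][1]
  }
  selected <- names(votes)[top]
  mis <- as.numeric(oob[usable] != y[usable])
  reg_df <- data.frame(mis = mis, table[feat][usable, , drop = FALSE],
                       check.names = FALSE)
  reg_seed <- if (is.null(seed)) NULL else (seed %% 2147483646L) + 1L
  reg <- ranger::ranger(mis ~ ., data = reg_df, num.trees = n_trees,
                        seed = reg_seed, num.threads = num_threads)
  phat <- stats::predict(reg, data = obs_df,
                         num.threads = num_threads)$predictions
  posterior <- min(max(1 - phat, 0), 1)
  structure(list(votes = votes, selected = selected, oob_confusion = conf,
                 classification_error = cls_err,
                 prior_error_rate = rf$prediction.error,
                 posterior_probability = posterior, n_trees = n_trees,
                 lda_table = if ("LDA1" %in% names(table)) table$LDA1,
                 lda_observed = if ("LDA1" %in% names(observed))
                   unname(observed["LDA1"]),
                 rf = rf, error_forest = reg, features = feat),
            class = "model_choice")
}

#' One-call ABC-RF model choice
#'
#' Convenience wrapper: [augment_with_lda()] then [train_and_select()].
#'
#' @inheritParams augment_with_lda
#' @inheritParams train_and_select
#' @return A `model_choice` object.
#' @export
model_choice <- function(table, observed, n_trees = 500L, seed = NULL,
                         num_threads = 1L) {
  aug <- augment_with_lda(table, observed)
  train_and_select(aug$table, aug$observed, n_trees = n_trees, seed = seed,
                   num_threads = num_threads)
}

#' @export
print.model_choice <- function(x, ...) {
  cat("ABC-RF model choice (", x$n_trees, " trees)\n", sep = "")
  for (m in names(x$votes)) {
    sel <- if (m == x$selected) " <- selected" else ""
    cat(sprintf("  %-15s classification error %.3f   votes %d%s\n",
                m, x$classification_error[[m]], x$votes[[m]], sel))
  }
  cat(sprintf("  posterior probability of %s: %.3f\n", x$selected,
              x$posterior_probability))
  invisible(x)
}
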