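# Shared, lazily built ABC fixture at the study's scaled-down analysis size
# (5,000 simulations per model, default priors, 500-tree forest) plus 200
# held-out pseudo-observations per model drawn from the same prior
# predictive. Built once per test run and reused by the calibration and
# model-recovery tests.

abc_cache <- new.env(parent = emptyenv())

abc_feature_frame <- function(stats_mat, direction) {
  f <- cbind(stats_mat, LDA1 = as.vector(stats_mat %*% direction))
  as.data.frame(f)
}

get_calibration_fixture <- function() {
  if (!is.null(abc_cache$fix)) return(abc_cache$fix)
  pri <- prior_set()
  sc <- sampling_config()
  # extreme prior draws can trip the per-branch saturation advisory
  ref <- suppressWarnings(build_reference_table(pri, sc, 5000L,
                                                seed = 20260901))

  lab <- rep(c("continuity", "discontinuity"), each = 200L)
  svs <- matrix(NA_real_, length(lab), 11L,
                dimnames = list(NULL, summary_stat_names()))
  set.seed(314159)
  for (i in seq_along(lab)) {
    repeat {
      sim <- suppressWarnings(
        simulate_dataset(lab[i], pri, sc, compact = TRUE))
      sv <- try(summary_vector(sim$data), silent = TRUE)
      if (!inherits(sv, "try-error") && all(is.finite(sv))) break
    }
    svs[i, ] <- sv
  }

  aug <- augment_with_lda(ref, svs[1, ])
  mc <- train_and_select(aug$table, aug$observed, n_trees = 500L, seed = 99L)
  feats <- abc_feature_frame(svs, aug$direction)
  pred <- stats::predict(mc$rf, data = feats, num.threads = 1L)$predictions
  phat <- stats::predict(mc$error_forest, data = feats,
                         num.threads = 1L)$predictions
  votes_all <- stats::predict(mc$rf, data = feats, predict.all = TRUE,
                              num.threads = 1L)$predictions
  lev <- mc$rf$forest$levels[mc$rf$forest$class.values]
  vote_share_sel <- apply(votes_all, 1L, function(z) {
    tab <- table(factor(lev[z], levels = mc$rf$forest$levels))
    max(tab) / sum(tab)
  })
  abc_cache$fix <- list(
    ref = ref, mc = mc, direction = aug$direction,
    held_label = lab, held_pred = as.character(pred),
    held_posterior = 1 - phat, held_vote_share = vote_share_sel)
  abc_cache$fix
}
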