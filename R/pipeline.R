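# End-to-end orchestration: frequencies -> PCA -> diversity -> AMOVA/PhiST
# -> MDS -> ABC model choice, with deterministic seed fan-out and a run
# manifest.

# Deterministic per-stage seed derived from the master seed and stage name.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 131 + h) %% 2147483587)
}

#' Read a prior file
#'
#' YAML file with one entry per parameter (`N_anc`, `N_sic`, `T_div`, `mu`),
#' each a mapping with `dist` (`uniform` or `loguniform`), `min` and `max`.
#' Parameters not listed keep the [prior_set()] defaults, so a supplementary
#' prior specification can be substituted wholesale or partially.
#'
#' @param path Path to a YAML prior file.
#' @return A `prior_set`.
#' @export
read_prior_yaml <- function(path) {
  if (!file.exists(path)) stop("prior file not found: ", path)
  spec <- yaml::read_yaml(path)
  defaults <- prior_set()
  bad <- setdiff(names(spec), names(defaults))
  if (length(bad)) stop("unknown prior parameter(s): ", paste(bad, collapse = ", "))
  pri <- defaults
  for (nm in names(spec)) {
    e <- spec[[nm]]
    if (is.null(e$dist) || is.null(e$min) || is.null(e$max))
      stop("prior '", nm, "' needs dist, min and max")
    pri[[nm]] <- switch(e$dist,
                        uniform = prior_uniform(e$min, e$max),
                        loguniform = prior_loguniform(e$min, e$max),
                        stop("unknown prior dist: ", e$dist))
  }
  do.call(prior_set, pri)
}

default_run_config <- function() {
  list(metadata = NULL,            # NULL -> packaged study-like table
       alignment = NULL,           # optional FASTA of real sequences
       group_field = "group",
       pca_scale = FALSE,
       n_perm = 1000L,
       synthetic = list(regime = "high", n_A = 8L, n_B = 17L,
                        L = 16569L, mu = 2.5e-8),
       abc = list(enabled = TRUE, n_sims = 500L, n_trees = 500L,
                  prior_file = NULL),
       out_dir = "results/pipeline",
       seed = 1L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  for (p in c(cfg$metadata, cfg$alignment, cfg$abc$prior_file))
    if (!is.null(p) && !file.exists(p)) stop("configured file not found: ", p)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage from one configuration: macro-haplogroup
#' frequency tables and PCA from the metadata; a grouped alignment (a real
#' FASTA when configured, otherwise a synthetic structured dataset);
#' per-group diversity statistics; AMOVA with permutation test, pairwise
#' PhiST and classical MDS; and, when enabled, ABC-RF model choice against
#' a freshly simulated reference table. All stochastic stages draw their
#' seeds deterministically from the master seed, and a JSON manifest
#' records versions, seeds, the configuration hash and completed stages.
#' A stage failure aborts with the failing stage named; outputs of earlier
#' stages and a manifest marking the failure are retained.
#'
#' @param config A (possibly partial) configuration list, or the path to a
#'   YAML file holding one. Unset entries use documented defaults; see the
#'   package vignette.
#' @return Invisibly, a list with the stage results and artifact paths.
#' @export
run_full_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(default_run_config(), config))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  done <- character(0)

  manifest_path <- file.path(out, "manifest.json")
  # hash identifies the analytical configuration, not where it is written
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  stages <- c("frequencies", "dataset", "differentiation", "abc")
  seeds <- vapply(stages, stage_seed, integer(1), master = cfg$seed)
  write_manifest <- function(failed = NULL) {
    jsonlite::write_json(
      list(package = "mitostruct",
           version = as.character(utils::packageVersion("mitostruct")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           master_seed = cfg$seed, stage_seeds = as.list(seeds),
           config_hash = cfg_hash, stages_completed = done,
           failed_stage = failed),
      manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      write_manifest(failed = name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    done <<- c(done, name)
    res
  }

  results$frequencies <- run_stage("frequencies", {
    meta <- if (is.null(cfg$metadata)) make_study_metadata()
            else read_metadata(cfg$metadata)
    ft <- frequency_table(meta, group_field = cfg$group_field)
    utils::write.csv(ft$counts, file.path(out, "haplogroup_counts.csv"))
    utils::write.csv(round(ft$freq, 6), file.path(out, "haplogroup_freq.csv"))
    pca <- tryCatch(pca_frequencies(ft, cfg$pca_scale),
                    warning = function(w)
                      suppressWarnings(pca_frequencies(ft, cfg$pca_scale)))
    utils::write.csv(round(pca$scores, 6), file.path(out, "pca_scores.csv"))
    utils::write.csv(round(pca$loadings, 6),
                     file.path(out, "pca_loadings.csv"))
    utils::write.csv(
      data.frame(component = seq_along(pca$explained_variance_ratio),
                 explained_variance_ratio = pca$explained_variance_ratio),
      file.path(out, "pca_explained_variance.csv"), row.names = FALSE)
    list(freq = ft, pca = pca, metadata = meta)
  })

  results$dataset <- run_stage("dataset", {
    if (!is.null(cfg$alignment)) {
      aln <- read_fasta_alignment(cfg$alignment)
      build_grouped(aln, results$frequencies$metadata, cfg$group_field)
    } else {
      sc <- cfg$synthetic
      make_structured_alignment(
        synthetic_config(n_A = sc$n_A, n_B = sc$n_B, L = sc$L,
                         regime = sc$regime, mu = sc$mu,
                         seed = seeds[["dataset"]]))
    }
  })

  results$differentiation <- run_stage("differentiation", {
    ga <- results$dataset
    div <- diversity_by_group(ga)
    utils::write.csv(div, file.path(out, "diversity_by_group.csv"),
                     row.names = FALSE)
    d <- difference_matrix(ga$alignment)
    am <- amova(d, ga$partition, n_perm = cfg$n_perm,
                seed = seeds[["differentiation"]])
    utils::write.csv(
      data.frame(source = c("among groups", "within groups"),
                 df = c(am$df_among, am$df_within),
                 SSD = c(am$ssd_among, am$ssd_within),
                 sigma2 = c(am$sigma2_among, am$sigma2_within),
                 phi_st = c(am$phi_st, NA),
                 p_value = c(am$p_value, NA), p_se = c(am$p_se, NA)),
      file.path(out, "amova.csv"), row.names = FALSE)
    fst <- pairwise_fst(d, ga$partition)
    utils::write.csv(fst, file.path(out, "pairwise_fst.csv"))
    mds <- classical_mds(fst, k = min(2L, length(ga$partition) - 1L))
    utils::write.csv(mds$points, file.path(out, "mds_coordinates.csv"))
    list(diversity = div, amova = am, fst = fst, mds = mds)
  })

  if (isTRUE(cfg$abc$enabled)) {
    results$abc <- run_stage("abc", {
      pri <- if (is.null(cfg$abc$prior_file)) prior_set()
             else read_prior_yaml(cfg$abc$prior_file)
      ga <- results$dataset
      if (length(ga$partition) != 2L)
        stop("ABC model choice needs exactly 2 groups, got ",
             length(ga$partition))
      grp_age <- vapply(names(ga$partition), function(g)
        mean(ga$ages[ga$partition[[g]]], na.rm = TRUE), numeric(1))
      if (anyNA(grp_age) || !is.finite(diff(grp_age)) || diff(grp_age) == 0)
        stop("ABC model choice needs distinct per-group sampling ages")
      # group A is the older sample; reorder the observed partition to match
      ord <- order(grp_age, decreasing = TRUE)
      ga$partition <- ga$partition[ord]
      results$dataset <- ga
      sizes <- group_sizes(ga)
      ref <- build_reference_table(pri, sampling_config(
               n_A = sizes[1], n_B = sizes[2],
               t_A = grp_age[ord][1], t_B = grp_age[ord][2],
               label_A = names(sizes)[1], label_B = names(sizes)[2]),
               n_sims_per_model = cfg$abc$n_sims,
               seed = seeds[["abc"]], L = ga$alignment$L)
      utils::write.csv(ref, file.path(out, "reference_table.csv"),
                       row.names = FALSE)
      obs <- summary_vector(ga)
      mc <- model_choice(ref, obs, n_trees = cfg$abc$n_trees,
                         seed = seeds[["abc"]])
      jsonlite::write_json(
        list(selected = mc$selected,
             votes = as.list(mc$votes),
             classification_error = as.list(mc$classification_error),
             prior_error_rate = mc$prior_error_rate,
             posterior_probability = mc$posterior_probability,
             n_trees = mc$n_trees,
             observed_statistics = as.list(obs)),
        file.path(out, "model_choice.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
      mc
    })
  }

  write_manifest()
  results$manifest <- manifest_path
  invisible(results)
}
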