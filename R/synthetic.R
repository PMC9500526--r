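# Synthetic-data generators: structured two-deme alignments at controlled
# divergence rungs, the packaged study-like metadata table, and
# pseudo-observed datasets at known parameter values.

#' Configuration for a synthetic structured alignment
#'
#' The three divergence rungs target qualitatively different PhiST regimes
#' with study-like sampling (group A at 3500 BP, group B at 2450 BP):
#' \describe{
#'   \item{low}{panmixia — one deme of 10,000 lineages (continuity);
#'     expected PhiST ~ 0.}
#'   \item{medium}{discontinuity at 10,000 BP with both deme sizes 2,000;
#'     moderate differentiation.}
#'   \item{high}{discontinuity at 60,000 BP with deme sizes 1,000; strong
#'     differentiation (PhiST well above 0.3).}
#' }
#'
#' @param n_A,n_B Group sample sizes (defaults 8 and 17, the study design).
#' @param L Sites (default 16569).
#' @param regime `"low"`, `"medium"` or `"high"`.
#' @param mu Mutation rate per site per year (default 2.5e-8).
#' @param seed RNG seed (mandatory: fixtures must be reproducible).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_A = 8L, n_B = 17L, L = 16569L,
                             regime = c("low", "medium", "high"),
                             mu = 2.5e-8, seed) {
  regime <- match.arg(regime)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for fixtures")
  stopifnot(n_A >= 2, n_B >= 2, L > 0, mu > 0)
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 L = as.integer(L), regime = regime, mu = mu,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

regime_model <- function(cfg) {
  switch(cfg$regime,
         low = demographic_model("continuity", N_anc = 10000,
                                 mu = cfg$mu, L = cfg$L),
         medium = demographic_model("discontinuity", N_anc = 2000,
                                    N_sic = 2000, T_div = 10000,
                                    mu = cfg$mu, L = cfg$L),
         high = demographic_model("discontinuity", N_anc = 1000,
                                  N_sic = 1000, T_div = 60000,
                                  mu = cfg$mu, L = cfg$L))
}

#' Simulate a structured two-deme alignment at a divergence rung
#'
#' Wraps the coalescent simulator with fixed, documented parameters per
#' rung (see [synthetic_config()]). The realized PhiST of the simulated
#' dataset is attached as attribute `"realized_fst"`.
#'
#' @param cfg A `synthetic_config`.
#' @param compact Return the compact `sim_seqs` instead of the expanded
#'   `grouped_alignment`? Default `FALSE`.
#' @return A `grouped_alignment` (or `sim_seqs`) with two groups.
#' @export
make_structured_alignment <- function(cfg, compact = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  model <- regime_model(cfg)
  sampling <- sampling_config(n_A = cfg$n_A, n_B = cfg$n_B)
  set.seed(cfg$seed)
  gen <- simulate_genealogy(model, sampling)
  sim <- drop_mutations(gen, model$mu, model$L, compact = TRUE)
  fst <- unname(summary_vector(sim)["FST"])
  out <- if (compact) sim else sim_to_grouped(sim)
  attr(out, "realized_fst") <- fst
  out
}

#' Packaged study-like sample metadata
#'
#' Loads the packaged metadata table for the 36 analyzed ancient Sicilian
#' individuals (id, locality, culture/period, analysis group, printed date
#' estimate, haplogroup label), with ages derived by the documented
#' [parse_age_bp()] rule. The seven analysis groups combine locality with
#' cultural attribution (e.g. `Baucina_Sicanian`, n = 17;
#' `Motya_BronzeAge`, n = 8).
#'
#' @return A `sample_table` with 36 rows.
#' @export
make_study_metadata <- function() {
  path <- system.file("extdata", "sicily_ancient_samples.csv",
                      package = "mitostruct")
  if (!nzchar(path)) stop("packaged metadata not found")
  read_metadata(path)
}

#' Simulate a pseudo-observed dataset at known parameter values
#'
#' One dataset at a fixed, known truth (no priors), for model-recovery and
#' posterior-calibration experiments.
#'
#' @param topology `"continuity"` or `"discontinuity"`.
#' @param params Named list of fixed parameter values: `N_anc`, `mu`, and
#'   for discontinuity also `N_sic` and `T_div`.
#' @param sampling A `sampling_config` (default: study design).
#' @param L,gen_time Locus length and generation time.
#' @param seed Optional RNG seed.
#' @param compact Passed to [drop_mutations()].
#' @return A `grouped_alignment` (or `sim_seqs`).
#' @export
make_pseudo_observed <- function(topology, params,
                                 sampling = sampling_config(),
                                 L = 16569L, gen_time = 25, seed = NULL,
                                 compact = FALSE) {
  disc <- identical(topology, "discontinuity")
  model <- demographic_model(topology,
                             N_anc = params$N_anc,
                             N_sic = if (disc) params$N_sic,
                             T_div = if (disc) params$T_div,
                             mu = params$mu, L = L, gen_time = gen_time)
  if (!is.null(seed)) set.seed(seed)
  gen <- simulate_genealogy(model, sampling)
  drop_mutations(gen, model$mu, L, gen_time, compact = compact)
}
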