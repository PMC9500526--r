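# Serial-sampling haploid coalescent simulator with finite-sites mutation.
#
# Times run backwards from the present in years BP, converted internally to
# generations. N is the number of transmitting lineages (mtDNA effective
# size): the coalescence rate with k active lineages is choose(k,2)/N per
# generation.

#' Define a demographic model
#'
#' Two topologies over two sampled groups, A ("Bronze Age Sicilians", the
#' older sample) and B ("Sicanians", the younger):
#' \describe{
#'   \item{continuity}{a single panmictic deme of constant haploid size
#'     `N_anc` holds both groups serially — B descends directly from the
#'     population that A was drawn from.}
#'   \item{discontinuity}{group B lineages coalesce within their own deme of
#'     size `N_sic` until the divergence time `T_div` (years BP), at which
#'     point surviving lineages merge into the ancestral deme of size
#'     `N_anc`.}
#' }
#'
#' @param topology `"continuity"` or `"discontinuity"`.
#' @param N_anc Haploid effective size of the ancestral deme (> 0).
#' @param N_sic Size of the diverged source deme (discontinuity only).
#' @param T_div Divergence time in years BP (discontinuity only; must
#'   predate the oldest sample).
#' @param mu Mutation rate per site per year (> 0).
#' @param L Locus length in sites (default 16569, the rCRS mtDNA frame).
#' @param gen_time Years per generation (default 25).
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(topology = c("continuity", "discontinuity"),
                              N_anc, N_sic = NULL, T_div = NULL,
                              mu, L = 16569L, gen_time = 25) {
  topology <- match.arg(topology)
  stopifnot(N_anc > 0, mu > 0, L > 0, gen_time > 0)
  if (topology == "discontinuity") {
    if (is.null(N_sic) || is.null(T_div))
      stop("discontinuity model requires N_sic and T_div")
    stopifnot(N_sic > 0, T_div > 0)
  } else {
    N_sic <- NULL
    T_div <- NULL
  }
  structure(list(topology = topology, N_anc = N_anc, N_sic = N_sic,
                 T_div = T_div, mu = mu, L = as.integer(L),
                 gen_time = gen_time),
            class = "demographic_model")
}

#' Define the serial sampling configuration
#'
#' Two groups sampled at different ages. Defaults mirror the study design:
#' 8 Bronze Age individuals at 3500 BP and 17 Sicanian individuals at
#' 2450 BP.
#'
#' @param n_A,n_B Sample sizes (each >= 1, at least 2 in total; downstream
#'   summary statistics need >= 2 per group).
#' @param t_A,t_B Sampling ages in years BP; `t_A > t_B >= 0`.
#' @param label_A,label_B Group labels carried into simulated datasets.
#' @return Object of class `sampling_config`.
#' @export
sampling_config <- function(n_A = 8L, t_A = 3500, n_B = 17L, t_B = 2450,
                            label_A = "BronzeAge", label_B = "Sicanian") {
  stopifnot(n_A >= 1, n_B >= 1, n_A + n_B >= 2, t_B >= 0, t_A > t_B)
  structure(list(n_A = as.integer(n_A), t_A = t_A,
                 n_B = as.integer(n_B), t_B = t_B,
                 label_A = label_A, label_B = label_B),
            class = "sampling_config")
}

#' Simulate a genealogy under the serial coalescent
#'
#' Standard haploid coalescent with heterochronous sampling: lineages become
#' active when the (backwards) clock passes their sampling age; while more
#' than one lineage is active the next coalescence in a deme with k active
#' lineages and size N arrives at exponential rate choose(k,2)/N per
#' generation. Under the discontinuity topology, group-B lineages coalesce
#' in their own deme until `T_div`, then merge into the ancestral deme.
#'
#' @param model A `demographic_model`.
#' @param sampling A `sampling_config`.
#' @param seed Optional RNG seed.
#' @return Object of class `genealogy`: `n_tip`, `parent` (index vector,
#'   `NA` at the root), `time` (node times in generations before present;
#'   leaf depths equal their sampling ages), `tip_group`, `tip_age_gen`,
#'   `tip_label`, `gen_time`.
#' @export
simulate_genealogy <- function(model, sampling, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(sampling, "sampling_config"))
  if (!is.null(seed)) set.seed(seed)
  g <- model$gen_time
  n_A <- sampling$n_A
  n_B <- sampling$n_B
  n <- n_A + n_B
  tip_age <- c(rep(sampling$t_A / g, n_A), rep(sampling$t_B / g, n_B))
  tip_deme <- c(rep(1L, n_A), rep(2L, n_B))
  disc <- model$topology == "discontinuity"
  if (disc && model$T_div <= max(sampling$t_A, sampling$t_B))
    stop("T_div must predate the oldest sample")
  t_merge <- if (disc) model$T_div / g else Inf
  if (!disc) tip_deme <- rep(1L, n)

  nn <- 2L * n - 1L
  parent <- rep(NA_integer_, nn)
  ntime <- c(tip_age, rep(NA_real_, n - 1L))
  inactive <- order(tip_age)
  ptr <- 1L
  actA <- integer(0)
  actB <- integer(0)
  merged <- !disc
  nxt <- n
  t <- min(tip_age)

  repeat {
    while (ptr <= n && tip_age[inactive[ptr]] <= t) {
      tp <- inactive[ptr]
      if (merged || tip_deme[tp] == 1L) actA <- c(actA, tp)
      else actB <- c(actB, tp)
      ptr <- ptr + 1L
    }
    if (!merged && t >= t_merge) {
      actA <- c(actA, actB)
      actB <- integer(0)
      merged <- TRUE
    }
    if (ptr > n && merged && length(actA) == 1L) break
    kA <- length(actA)
    kB <- length(actB)
    rA <- if (kA >= 2L) kA * (kA - 1) / 2 / model$N_anc else 0
    rB <- if (kB >= 2L) kB * (kB - 1) / 2 / model$N_sic else 0
    R <- rA + rB
    bound <- if (ptr <= n) tip_age[inactive[ptr]] else Inf
    if (!merged) bound <- min(bound, t_merge)
    w <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + w < bound) {
      t <- t + w
      nxt <- nxt + 1L
      in_A <- R > 0 && stats::runif(1L) < rA / R
      if (in_A) {
        pick <- sample.int(kA, 2L)
        parent[actA[pick]] <- nxt
        actA <- c(actA[-pick], nxt)
      } else {
        pick <- sample.int(kB, 2L)
        parent[actB[pick]] <- nxt
        actB <- c(actB[-pick], nxt)
      }
      ntime[nxt] <- t
    } else {
      if (!is.finite(bound))
        stop("internal error: coalescent stalled")   # unreachable
      t <- bound
    }
  }

  tip_label <- c(paste0(sampling$label_A, "_", seq_len(n_A)),
                 paste0(sampling$label_B, "_", seq_len(n_B)))
  tip_group <- c(rep(sampling$label_A, n_A), rep(sampling$label_B, n_B))
  structure(list(n_tip = n, parent = parent, time = ntime,
                 tip_group = tip_group, tip_age_gen = tip_age,
                 tip_label = tip_label, gen_time = model$gen_time),
            class = "genealogy")
}

#' Time to the most recent common ancestor
#'
#' @param gen A `genealogy`.
#' @return Root time in generations before present.
#' @export
tmrca <- function(gen) max(gen$time)

#' Drop finite-sites mutations onto a genealogy
#'
#' Per branch of length b generations, the mutation count is Poisson with
#' mean `mu * gen_time * L * b`; each mutation hits a uniformly chosen site
#' and substitutes a uniformly chosen different base (finite-sites,
#' Jukes-Cantor). The ancestral sequence is drawn uniformly at the root.
#'
#' @param gen A `genealogy`.
#' @param mu Mutation rate per site per year.
#' @param L Locus length in sites.
#' @param gen_time Years per generation (defaults to the genealogy's value).
#' @param seed Optional RNG seed.
#' @param compact If `TRUE`, return a compact `sim_seqs` object holding only
#'   the ancestral sequence and the mutated columns (the representation used
#'   by the reference-table machinery); if `FALSE` (default), expand to a
#'   [build_grouped()]-style `grouped_alignment`.
#' @return A `grouped_alignment`, or a `sim_seqs` when `compact = TRUE`.
#' @export
drop_mutations <- function(gen, mu, L, gen_time = gen$gen_time, seed = NULL,
                           compact = FALSE) {
  stopifnot(inherits(gen, "genealogy"), mu >= 0, L > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- gen$n_tip
  nn <- 2L * n - 1L
  root <- which(is.na(gen$parent))
  bl <- gen$time[gen$parent] - gen$time
  bl[root] <- 0
  lam <- mu * gen_time * L * bl
  if (any(lam > 0.5 * L))
    warning("expected mutations exceed 0.5 * L on some branch ",
            "(saturation regime)")
  cnt <- stats::rpois(nn, lam)
  tot <- sum(cnt)
  anc <- sample.int(4L, L, replace = TRUE)
  if (tot == 0L) {
    P <- integer(0)
    tip <- matrix(integer(0), n, 0L)
  } else {
    pos_raw <- sample.int(L, tot, replace = TRUE)
    P <- sort(unique(pos_raw))
    pidx <- match(pos_raw, P)
    node_of <- rep.int(seq_len(nn), cnt)
    offs <- sample.int(3L, tot, replace = TRUE)
    m <- length(P)
    state <- matrix(0L, nn, m)
    state[root, ] <- anc[P]
    mut_by_node <- split(seq_len(tot), node_of)
    ord <- order(gen$time, decreasing = TRUE)   # parents strictly precede children
    for (v in ord) {
      if (v == root) next
      s <- state[gen$parent[v], ]
      mi <- mut_by_node[[as.character(v)]]
      if (!is.null(mi)) {
        for (k in mi) {
          j <- pidx[k]
          s[j] <- (s[j] - 1L + offs[k]) %% 4L + 1L
        }
      }
      state[v, ] <- s
    }
    tip <- state[seq_len(n), , drop = FALSE]
  }
  sim <- structure(list(anc = anc, pos = P, tip = tip, L = as.integer(L),
                        ids = gen$tip_label, group = gen$tip_group,
                        age_BP = gen$tip_age_gen * gen_time),
                   class = "sim_seqs")
  if (compact) sim else sim_to_grouped(sim)
}

#' Expand a compact simulated dataset to a grouped alignment
#'
#' @param sim A `sim_seqs` object from [drop_mutations()].
#' @return A `grouped_alignment` over the full L-site frame.
#' @export
sim_to_grouped <- function(sim) {
  stopifnot(inherits(sim, "sim_seqs"))
  n <- length(sim$ids)
  full <- matrix(MT_BASES[sim$anc], nrow = n, ncol = sim$L, byrow = TRUE)
  if (length(sim$pos)) full[, sim$pos] <- MT_BASES[sim$tip]
  rownames(full) <- sim$ids
  aln <- new_alignment(full)
  partition <- split(sim$ids, factor(sim$group, levels = unique(sim$group)))
  ages <- stats::setNames(sim$age_BP, sim$ids)
  structure(list(alignment = aln, partition = partition, ages = ages),
            class = "grouped_alignment")
}

#' @export
print.sim_seqs <- function(x, ...) {
  cat("sim_seqs:", length(x$ids), "sequences, L =", x$L, "sites,",
      length(x$pos), "mutated columns\n")
  invisible(x)
}

# ---- priors ----------------------------------------------------------------

#' Prior distribution constructors
#'
#' Independent one-dimensional priors for demographic parameters:
#' uniform or log-uniform over a positive support.
#'
#' @param min,max Support bounds (`min < max`; `min > 0` for log-uniform).
#' @return Object of class `prior`.
#' @export
prior_uniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), min < max)
  structure(list(dist = "uniform", min = min, max = max), class = "prior")
}

#' @rdname prior_uniform
#' @export
prior_loguniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), 0 < min, min < max)
  structure(list(dist = "loguniform", min = min, max = max), class = "prior")
}

draw_prior <- function(p, n = 1L) {
  switch(p$dist,
         uniform = stats::runif(n, p$min, p$max),
         loguniform = exp(stats::runif(n, log(p$min), log(p$max))),
         stop("unknown prior distribution: ", p$dist))
}

#' Bundle parameter priors for the two demographic models
#'
#' Defaults: effective sizes log-uniform over \[100, 100000\] transmitting
#' lineages; divergence time uniform over the Neolithic window
#' \[6000, 8000\] years BP; mutation rate log-uniform over
#' \[1e-8, 5e-8\] per site per year.
#'
#' @param N_anc,N_sic,T_div,mu `prior` objects (see [prior_uniform()]).
#' @return Object of class `prior_set` (named list of priors).
#' @export
prior_set <- function(N_anc = prior_loguniform(1e2, 1e5),
                      N_sic = prior_loguniform(1e2, 1e5),
                      T_div = prior_uniform(6000, 8000),
                      mu = prior_loguniform(1e-8, 5e-8)) {
  pri <- list(N_anc = N_anc, N_sic = N_sic, T_div = T_div, mu = mu)
  ok <- vapply(pri, inherits, logical(1), what = "prior")
  if (!all(ok)) stop("all prior_set entries must be priors")
  structure(pri, class = "prior_set")
}

#' Simulate one dataset from the prior predictive
#'
#' Draws one parameter vector from the priors, simulates a genealogy under
#' the requested topology and drops mutations, returning the dataset
#' together with the drawn parameters. With a fixed seed the result is
#' bit-identical across calls.
#'
#' @param topology `"continuity"` or `"discontinuity"`.
#' @param priors A `prior_set`.
#' @param sampling A `sampling_config`.
#' @param L Locus length (default 16569).
#' @param gen_time Years per generation (default 25).
#' @param seed Optional RNG seed.
#' @param compact Passed to [drop_mutations()].
#' @return List with `data` (grouped alignment or `sim_seqs`), `params`
#'   (one-row data frame of the draws) and `model` (the topology).
#' @export
simulate_dataset <- function(topology, priors, sampling, L = 16569L,
                             gen_time = 25, seed = NULL, compact = FALSE) {
  stopifnot(inherits(priors, "prior_set"),
            inherits(sampling, "sampling_config"))
  if (!is.null(seed)) set.seed(seed)
  par <- lapply(priors, draw_prior)
  disc <- identical(topology, "discontinuity")
  model <- demographic_model(topology,
                             N_anc = par$N_anc,
                             N_sic = if (disc) par$N_sic,
                             T_div = if (disc) par$T_div,
                             mu = par$mu, L = L, gen_time = gen_time)
  gen <- simulate_genealogy(model, sampling)
  dat <- drop_mutations(gen, model$mu, L, gen_time, compact = compact)
  list(data = dat, params = as.data.frame(par), model = topology)
}
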