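# Simulator unit tests use a short locus; closed-form expectations
# (Watterson, TMRCA) are scale-free in theta and N.

test_that("model and sampling constructors validate their invariants", {
  expect_error(demographic_model("discontinuity", N_anc = 100, mu = 1e-8),
               "N_sic")
  m <- demographic_model("continuity", N_anc = 100, N_sic = 50, T_div = 1,
                         mu = 1e-8)
  expect_null(m$N_sic)   # discontinuity-only parameters ignored
  expect_error(sampling_config(t_A = 100, t_B = 200), "t_A > t_B")
  disc <- demographic_model("discontinuity", N_anc = 100, N_sic = 100,
                            T_div = 3000, mu = 1e-8)
  expect_error(simulate_genealogy(disc, sampling_config()),
               "predate the oldest sample")
})

test_that("genealogies are ultrametric in sampling ages with ordered nodes", {
  model <- demographic_model("discontinuity", N_anc = 300, N_sic = 120,
                             T_div = 9000, mu = 1e-8)
  sc <- sampling_config(n_A = 4, t_A = 3500, n_B = 6, t_B = 2450)
  for (seed in 1:10) {
    g <- simulate_genealogy(model, sc, seed = seed)
    expect_equal(g$time[seq_len(g$n_tip)], g$tip_age_gen)  # leaf depths
    # every branch has non-negative length; root is the oldest node
    bl <- g$time[g$parent] - g$time
    expect_true(all(bl[!is.na(bl)] >= 0))
    expect_gte(tmrca(g), max(g$tip_age_gen))
    expect_gte(tmrca(g), model$T_div / model$gen_time)
  }
})

test_that("serial sampling bounds the TMRCA below by the oldest age", {
  model <- demographic_model("continuity", N_anc = 50, mu = 1e-8)
  sc <- sampling_config(n_A = 1, t_A = 4000, n_B = 1, t_B = 0)
  set.seed(2)
  for (r in 1:100) {
    g <- simulate_genealogy(model, sc)
    expect_gte(tmrca(g), 4000 / 25)
  }
})

test_that("mean TMRCA for two contemporaneous lineages is N generations", {
  N <- 500
  model <- demographic_model("continuity", N_anc = N, mu = 1e-8)
  sc <- sampling_config(n_A = 1, t_A = 1e-9, n_B = 1, t_B = 0)
  set.seed(3)
  tm <- replicate(5000, tmrca(simulate_genealogy(model, sc)))
  expect_lt(abs(mean(tm) / N - 1), 0.05)
})

test_that("degenerate discontinuity collapses onto continuity", {
  # T_div just past the oldest sample and N_sic = N_anc is the same process
  N <- 400
  sc <- sampling_config(n_A = 4, t_A = 3500, n_B = 4, t_B = 2450)
  cont <- demographic_model("continuity", N_anc = N, mu = 1e-8)
  disc <- demographic_model("discontinuity", N_anc = N, N_sic = N,
                            T_div = 3500.1, mu = 1e-8)
  set.seed(4)
  t_cont <- replicate(5000, tmrca(simulate_genealogy(cont, sc)))
  t_disc <- replicate(5000, tmrca(simulate_genealogy(disc, sc)))
  ks <- suppressWarnings(stats::ks.test(t_cont, t_disc))
  expect_gt(ks$p.value, 0.01)
})

test_that("mutation dropping respects zero rate and single-mutation identities", {
  model <- demographic_model("continuity", N_anc = 200, mu = 1e-8, L = 100)
  sc <- sampling_config(n_A = 3, t_A = 1, n_B = 5, t_B = 0)
  g <- simulate_genealogy(model, sc, seed = 5)
  ga <- drop_mutations(g, mu = 0, L = 100)
  expect_equal(nrow(unique(ga$alignment$seqs)), 1L)  # mu = 0: all identical

  # scan seeds for simulations with exactly one segregating site and check
  # the combinatorial identity Pi = 2 k (n - k) / (n (n - 1))
  n <- 8
  found <- 0L
  for (seed in 1:200) {
    sim <- drop_mutations(g, mu = 2e-7, L = 100, seed = seed, compact = TRUE)
    if (length(sim$pos) == 0L) next
    st <- within_group_stats(sim_to_grouped(sim)$alignment)
    if (st$S != 1L) next
    found <- found + 1L
    aln <- sim_to_grouped(sim)$alignment$seqs
    poly <- which(apply(aln, 2, function(col) length(unique(col)) > 1))
    k <- min(table(aln[, poly]))
    expect_equal(st$Pi, 2 * k * (n - k) / (n * (n - 1)), tolerance = 1e-12)
    if (found >= 5L) break
  }
  expect_gte(found, 1L)
})

test_that("segregating sites follow the Watterson expectation", {
  # n = 20 contemporaneous, theta = 2 N mu_seq = 5
  n <- 20
  N <- 1000
  L <- 1000
  theta <- 5
  mu <- theta / (2 * N * 25 * L)
  model <- demographic_model("continuity", N_anc = N, mu = mu, L = L)
  sc <- sampling_config(n_A = 1, t_A = 1e-9, n_B = n - 1, t_B = 0)
  set.seed(6)
  S <- replicate(2000, {
    g <- simulate_genealogy(model, sc)
    sim <- drop_mutations(g, mu, L, compact = TRUE)
    st <- within_group_stats(sim_to_grouped(sim)$alignment)
    st$S
  })
  a_n1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) / (theta * a_n1) - 1), 0.05)
})

test_that("expected pairwise differences match 2 N mu_seq for two lineages", {
  N <- 800
  L <- 500
  mu <- 4e-8
  theta <- 2 * N * mu * 25 * L  # = 2 N * per-generation sequence rate
  model <- demographic_model("continuity", N_anc = N, mu = mu, L = L)
  sc <- sampling_config(n_A = 1, t_A = 1e-9, n_B = 1, t_B = 0)
  set.seed(7)
  pw <- replicate(3000, {
    sim <- drop_mutations(simulate_genealogy(model, sc), mu, L,
                          compact = TRUE)
    if (length(sim$pos) == 0L) 0 else sum(sim$tip[1, ] != sim$tip[2, ])
  })
  expect_lt(abs(mean(pw) / theta - 1), 0.06)
})

test_that("prior draws stay in support and datasets are seed-reproducible", {
  pri <- prior_set()
  sc <- sampling_config(n_A = 2, n_B = 3)
  set.seed(8)
  for (r in 1:100) {
    par <- lapply(pri, mitostruct:::draw_prior)
    expect_true(par$N_anc >= 1e2 && par$N_anc <= 1e5)
    expect_true(par$T_div >= 6000 && par$T_div <= 8000)
    expect_true(par$mu >= 1e-8 && par$mu <= 5e-8)
  }
  s1 <- simulate_dataset("discontinuity", pri, sc, L = 2000, seed = 99,
                         compact = TRUE)
  s2 <- simulate_dataset("discontinuity", pri, sc, L = 2000, seed = 99,
                         compact = TRUE)
  expect_identical(s1$params, s2$params)
  expect_identical(s1$data$tip, s2$data$tip)
  expect_identical(s1$data$anc, s2$data$anc)
})

test_that("deme exchangeability: permuting ids within a deme is neutral", {
  # summary statistics only depend on the deme partition, not tip identity
  sim <- make_structured_alignment(synthetic_config(regime = "medium",
                                                    seed = 31), compact = TRUE)
  sv <- summary_vector(sim)
  perm <- sim
  idx <- seq_along(perm$ids)
  within_A <- which(perm$group == perm$group[1])
  set.seed(1)
  idx[within_A] <- sample(within_A)
  perm$ids <- perm$ids[idx]
  perm$tip <- perm$tip[idx, , drop = FALSE]
  perm$group <- perm$group[idx]
  expect_equal(summary_vector(perm), sv, tolerance = 1e-12,
               ignore_attr = TRUE)
})
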