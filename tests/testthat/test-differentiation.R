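test_that("pairwise difference matrix uses pairwise deletion", {
  m <- rbind(a = c("A", "C", "G", "T"),
             b = c("A", "C", "N", "T"),
             c = c("A", "C", "G", "T"))
  d <- difference_matrix(m)
  expect_equal(unname(d["a", "b"]), 0)   # N site dropped for this pair
  expect_equal(unname(d["b", "c"]), 0)
  expect_equal(unname(d["a", "c"]), 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(attr(d, "metric"), "raw_differences")
})

test_that("difference matrix equals an exhaustive recount on random data", {
  for (seed in 1:4) {
    m <- random_alignment(7, 80, p_missing = 0.05, seed = seed)
    d <- difference_matrix(m)
    expect_equal(matrix(as.vector(d), nrow(m), nrow(m)),
                 oracle_diff_matrix(m))
    expect_true(isSymmetric(matrix(as.vector(d), nrow(m), nrow(m))))
  }
})

test_that("pairs with no jointly complete site error unless allowed", {
  m <- rbind(a = c("A", "N"), b = c("N", "C"), c = c("A", "C"))
  expect_error(difference_matrix(m), "jointly complete")
  expect_warning(d <- difference_matrix(m, allow_null = TRUE), "NA")
  expect_true(is.na(d["a", "b"]))
})

test_that("K2P distances match the closed form and ape's implementation", {
  # P = 0.1, Q = 0 over 100 sites: d = -0.5 ln(0.8)
  s1 <- rep("A", 100)
  s2 <- c(rep("G", 10), rep("A", 90))
  d <- k2p_matrix(rbind(x = s1, y = s2))
  expect_equal(unname(d["x", "y"]), 0.11157177565710485, tolerance = 1e-12)
  # P = 0, Q = 0.1: d = -0.5 ln(0.9) - 0.25 ln(0.8)
  s3 <- c(rep("C", 10), rep("A", 90))
  d2 <- k2p_matrix(rbind(x = s1, y = s3))
  expect_equal(unname(d2["x", "y"]), -0.5 * log(0.9) - 0.25 * log(0.8),
               tolerance = 1e-12)
  expect_equal(unname(k2p_matrix(rbind(a = s1, b = s1))["a", "b"]), 0)

  for (seed in 11:13) {
    m <- random_alignment(6, 200, seed = seed)
    # perturb towards low divergence so no pair saturates
    base <- m[1, ]
    for (i in 2:6) {
      keep <- runif(200) < 0.9
      m[i, keep] <- base[keep]
    }
    d <- k2p_matrix(m)
    ora <- ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                         pairwise.deletion = TRUE, as.matrix = TRUE)
    expect_equal(matrix(as.vector(d), 6, 6), matrix(as.vector(ora), 6, 6),
                 tolerance = 1e-8)
    # and the scalar oracle on one pair
    expect_equal(unname(d[2, 3]), oracle_k2p_pair(m[2, ], m[3, ]),
                 tolerance = 1e-12)
  }
})

test_that("saturated pairs give NA with a warning", {
  s1 <- rep("A", 10)
  s2 <- rep("C", 10)   # Q = 1 -> log argument <= 0
  expect_warning(d <- k2p_matrix(rbind(a = s1, b = s2)), "saturated")
  expect_true(is.na(d["a", "b"]))
})

test_that("AMOVA reproduces hand-computed variance components", {
  # 3 groups of 2; within distances 0, 2, 4; all between distances 6.
  # Hand decomposition: SSD_total = 13, SSD_within = 3, sigma2_within = 1,
  # n' = 2, sigma2_among = 2, PhiST = 2/3.
  d <- matrix(6, 6, 6)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 2
  d[5, 6] <- d[6, 5] <- 4
  ids <- paste0("s", 1:6)
  dimnames(d) <- list(ids, ids)
  part <- list(g1 = ids[1:2], g2 = ids[3:4], g3 = ids[5:6])
  res <- amova(d, part, n_perm = 0)
  expect_equal(res$sigma2_among, 2, tolerance = 1e-12)
  expect_equal(res$sigma2_within, 1, tolerance = 1e-12)
  expect_equal(res$phi_st, 2 / 3, tolerance = 1e-12)
  expect_equal(res$ssd_among + res$ssd_within, res$ssd_total,
               tolerance = 1e-9)
})

test_that("AMOVA components equal the brute-force oracle on random data", {
  for (seed in 21:23) {
    m <- random_alignment(9, 60, seed = seed)
    d <- difference_matrix(m)
    part <- list(a = rownames(m)[1:3], b = rownames(m)[4:6],
                 c = rownames(m)[7:9])
    res <- amova(d, part, n_perm = 0)
    g <- rep(c("a", "b", "c"), each = 3)
    ora <- oracle_amova(d, g)
    expect_equal(res$sigma2_among, ora$sigma2_among, tolerance = 1e-9)
    expect_equal(res$sigma2_within, ora$sigma2_within, tolerance = 1e-9)
    expect_equal(res$phi_st, ora$phi, tolerance = 1e-9)
    expect_equal(res$ssd_among + res$ssd_within, res$ssd_total,
                 tolerance = 1e-9)
  }
})

test_that("two groups fixed for distinct haplotypes give PhiST = 1", {
  m <- rbind(a1 = rep("A", 20), a2 = rep("A", 20),
             b1 = rep(c("A", "G"), 10), b2 = rep(c("A", "G"), 10))
  d <- difference_matrix(m)
  res <- amova(d, list(A = c("a1", "a2"), B = c("b1", "b2")), n_perm = 0)
  expect_equal(res$phi_st, 1, tolerance = 1e-12)
})

test_that("permutation p-values are seeded, label-invariant and valid", {
  m <- random_alignment(10, 50, seed = 31)
  d <- difference_matrix(m)
  part <- list(x = rownames(m)[1:5], y = rownames(m)[6:10])
  r1 <- amova(d, part, n_perm = 200, seed = 7)
  r2 <- amova(d, part, n_perm = 200, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  part2 <- list(banana = part$x, apple = part$y)
  r3 <- amova(d, part2, n_perm = 200, seed = 7)
  expect_identical(r1$p_value, r3$p_value)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_equal(r1$p_se, sqrt(r1$p_value * (1 - r1$p_value) / 200),
               tolerance = 1e-12)
  expect_warning(amova(d, part, n_perm = 50, seed = 1), "coarse")
  expect_error(amova(d, list(x = part$x, y = part$y[1])), "at least 2")
})

test_that("random labels on panmictic data give PhiST near 0 and diffuse p", {
  set.seed(404)
  phis <- numeric(30)
  ps <- numeric(30)
  for (r in seq_len(30)) {
    m <- random_alignment(12, 60)
    d <- difference_matrix(m)
    ids <- sample(rownames(m))
    part <- list(a = ids[1:6], b = ids[7:12])
    res <- amova(d, part, n_perm = 199)
    phis[r] <- res$phi_st
    ps[r] <- res$p_value
  }
  expect_lt(abs(mean(phis)), 0.05)
  expect_gt(mean(ps), 0.3)        # roughly uniform p under the null
  expect_lt(mean(ps), 0.8)
})

test_that("pairwise PhiST is symmetric, zero-diagonal and order-invariant", {
  sim <- make_structured_alignment(synthetic_config(regime = "high", seed = 12))
  d <- difference_matrix(sim$alignment)
  f <- pairwise_fst(d, sim$partition)
  expect_equal(diag(f), stats::setNames(c(0, 0), names(sim$partition)))
  expect_true(isSymmetric(unname(f)))
  f2 <- pairwise_fst(d, rev(sim$partition))
  expect_equal(f2[names(sim$partition), names(sim$partition)], f)
})

test_that("classical MDS recovers planar configurations exactly", {
  set.seed(5)
  pts <- matrix(runif(8, -3, 3), 4, 2)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("g", 1:4), paste0("g", 1:4))
  fit <- classical_mds(D, k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(fit$points)) - unname(D))), 1e-8)
  # against the independent double-centering oracle (up to axis sign)
  ora <- oracle_mds(unname(D), 2)
  for (j in 1:2) {
    s <- fit$points[, j]; o <- ora[, j]
    expect_lt(min(max(abs(s - o)), max(abs(s + o))), 1e-8)
  }
})

test_that("MDS handles two points, negatives and rank deficits", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit <- classical_mds(D, k = 1)
  expect_equal(sort(unname(fit$points[, 1])), c(-1.5, 1.5),
               tolerance = 1e-10)

  Dneg <- matrix(c(0, -0.02, 1, -0.02, 0, 1, 1, 1, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_message(suppressWarnings(classical_mds(Dneg, k = 2)), "clamping")

  # collinear points: only 1 positive eigenvalue, k = 2 requested
  pts <- cbind(c(0, 1, 2.5), 0)
  D1 <- as.matrix(stats::dist(pts))
  dimnames(D1) <- list(letters[1:3], letters[1:3])
  expect_warning(fit1 <- classical_mds(D1, k = 2), "dimension")
  expect_lt(ncol(fit1$points), 2)
})
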