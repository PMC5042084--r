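# Topology sampling, Potts construction, Gibbs sampling fidelity and the
# N_eff-targeted family generator.

test_that("topologies are deterministic, respect the separation rule, and grow with L", {
  t1 <- sample_topology(30, seed = 1)
  t2 <- sample_topology(30, seed = 1)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$contacts, t2$contacts)
  expect_true(all(t1$contacts[, 2] - t1$contacts[, 1] >= 4))
  # bond lengths constant, excluded volume respected
  bonds <- sqrt(rowSums(diff(t1$coords)^2))
  expect_equal(bonds, rep(3.8, 29), tolerance = 1e-9)
  d <- as.matrix(dist(t1$coords))
  nonadj <- abs(row(d) - col(d)) >= 2
  expect_gte(min(d[nonadj]), 4.0)

  n20 <- vapply(1:12, function(s) nrow(sample_topology(20, s)$contacts), numeric(1))
  n60 <- vapply(1:12, function(s) nrow(sample_topology(60, s)$contacts), numeric(1))
  expect_gt(median(n60), median(n20))
})

test_that("Potts construction puts couplings only on contacts, in zero-sum gauge", {
  topo <- sample_topology(20, seed = 4)
  model <- build_potts(topo, beta = 1.0, seed = 4)
  keys <- paste(topo$contacts[, 1], topo$contacts[, 2])
  for (i in 1:19) for (j in (i + 1):20) {
    blk <- coupling_block(model, i, j)
    if (paste(i, j) %in% keys) {
      expect_gt(max(abs(blk)), 0)
      expect_equal(max(abs(rowSums(blk))), 0, tolerance = 1e-9)
      expect_equal(max(abs(colSums(blk))), 0, tolerance = 1e-9)
    } else {
      expect_equal(max(abs(blk)), 0)
    }
  }
  zero <- build_potts(topo, beta = 0, seed = 4)
  expect_equal(max(abs(zero$Jm)), 0)
})

test_that("Gibbs sampling matches exact enumeration on a two-site model", {
  # two-site Potts concentrated on two states per site, exact enumeration
  # over all q^2 joint states gives the stationary distribution
  q <- n_states()
  h <- matrix(-4, q, 2)
  h[1, ] <- 1.5   # state A
  h[2, ] <- 1.0   # state C (index 2 in the alphabet = C)
  Jm <- matrix(0, 2 * q, 2 * q)
  blk <- matrix(0, q, q)
  blk[1, 1] <- 1.2; blk[2, 2] <- 1.2; blk[1, 2] <- -1.2; blk[2, 1] <- -1.2
  Jm[1:q, (q + 1):(2 * q)] <- blk
  Jm[(q + 1):(2 * q), 1:q] <- t(blk)

  # exact joint by enumeration
  E <- outer(h[, 1], h[, 2], "+") + blk
  P <- exp(E); P <- P / sum(P)

  set.seed(99)
  n <- 5000
  msa <- metacontact:::gibbs_sample_cpp(h, Jm, n, 200L, 5L)
  emp <- table(factor(msa[, 1], levels = 1:q), factor(msa[, 2], levels = 1:q)) / n
  for (a in 1:2) for (b in 1:2) {
    se <- sqrt(P[a, b] * (1 - P[a, b]) / n)
    expect_lt(abs(emp[a, b] - P[a, b]), 3 * se + 1e-12)
  }
  # chi-square goodness of fit over the visited cells
  cells <- which(P > 5 / n)
  chi <- sum((as.vector(emp)[cells] * n - n * as.vector(P)[cells])^2 /
               (n * as.vector(P)[cells]))
  p <- stats::pchisq(chi, df = length(cells) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("independent sites show vanishing mutual information at depth", {
  q <- n_states()
  h <- matrix(0, q, 2); h[q, ] <- -3  # rare gaps
  Jm <- matrix(0, 2 * q, 2 * q)
  set.seed(12)
  msa <- metacontact:::gibbs_sample_cpp(h, Jm, 5000L, 50L, 2L)
  aln <- metacontact:::alignment_from_matrix(msa)
  wa <- list(alignment = aln, weights = rep(1, 5000), neff = 5000L,
             identity_threshold = 0.62)
  class(wa) <- "weighted_alignment"
  # relative pseudocount 0.5 (lambda = total weight) damps the finite-sample
  # MI bias of the 21-state table
  mi <- mutual_information(compute_frequencies(wa, sum(wa$weights)),
                           min_separation = 1L)
  expect_lt(mi$scores[1, 2], 0.01)
})

test_that("fixed seeds reproduce alignments bit-identically", {
  cfg <- sim_config(L = 12, n_sequences = 40, seed = 8)
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1$alignment$rows, f2$alignment$rows)
  expect_identical(f1$topology$contacts, f2$topology$contacts)
})

test_that("the family generator reaches N_eff targets and keeps its truth", {
  fam <- generate_family(sim_config(L = 15, n_sequences = 120,
                                    target_neff = 10, seed = 21))
  expect_lte(abs(fam$neff - 10), 2)
  expect_equal(fam$alignment$N, 120L)
  # every contact used to build J is reported in the truth
  q <- n_states()
  for (k in seq_len(nrow(fam$topology$contacts))) {
    i <- fam$topology$contacts[k, 1]; j <- fam$topology$contacts[k, 2]
    expect_gt(max(abs(coupling_block(fam$model, i, j))), 0)
  }
  # duplicates of a single sequence give N_eff 1
  one <- generate_family(sim_config(L = 15, n_sequences = 30, target_neff = 1,
                                    mutation_rate = 0.02, seed = 22))
  expect_equal(one$neff, 1L)
})

test_that("higher mutation rates give non-decreasing N_eff at fixed N", {
  rates <- c(0.02, 0.1, 0.3, 0.45)
  neffs <- vapply(rates, function(r) {
    suppressWarnings(
      generate_family(sim_config(L = 15, n_sequences = 80, target_neff = 5,
                                 mutation_rate = r, seed = 30))$neff)
  }, integer(1))
  expect_true(all(diff(neffs) >= 0))
})
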