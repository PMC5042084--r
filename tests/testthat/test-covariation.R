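# Frequency model, MI, APC, mean-field DCA, graphical lasso and
# pseudolikelihood couplings, each against an independent oracle.

test_that("frequency model normalizes, marginalizes and hits the pseudocount limit", {
  wa <- weight_alignment(alignment("q", "AC"))
  q <- n_states()
  f0 <- compute_frequencies(wa, 0)
  expect_equal(f0$f1[1, 1], 1)          # f_1(A) = 1
  expect_equal(f0$f1[2, 2], 1)          # f_2(C) = 1
  expect_equal(f0$f2[1, q + 2], 1)      # f_12(A, C) = 1
  expect_equal(colSums(f0$f1), c(1, 1))

  # two equally weighted sequences "AA" / "CC"
  wa2 <- weight_alignment(alignment(c("q", "s"), c("AA", "CC")))
  f <- compute_frequencies(wa2, 0)
  expect_equal(f$f2[1, q + 1], 0.5)     # f_12(A, A)
  expect_equal(f$f2[2, q + 2], 0.5)     # f_12(C, C)

  # enormous pseudocount drives every frequency to 1/q
  finf <- compute_frequencies(wa2, 1e9)
  expect_equal(max(abs(finf$f1 - 1 / q)), 0, tolerance = 1e-6)

  # marginalization: sum_b f_ij(a, b) = f_i(a)
  fam <- small_family()
  wf <- compute_frequencies(weight_alignment(fam$alignment), 1)
  i <- 3; j <- 17
  blk <- wf$f2[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)]
  expect_equal(rowSums(blk), wf$f1[, i], tolerance = 1e-9)
  expect_equal(colSums(blk), wf$f1[, j], tolerance = 1e-9)
  expect_equal(sum(blk), 1, tolerance = 1e-9)
})

test_that("mutual information matches analytic and brute-force oracles", {
  # perfectly correlated two-state columns: MI = ln 2
  wa <- weight_alignment(correlated_toy_alignment())
  mi <- mutual_information(compute_frequencies(wa, 0), min_separation = 1L)
  expect_equal(mi$scores[1, 4], log(2), tolerance = 1e-12)

  # independent columns: MI = 0 when the joint factorizes
  ind <- weight_alignment(alignment(paste0("s", 1:4),
                                    c("AAAA", "ACAC", "CACA", "CCCC"),
                                    query_index = 1))
  mi0 <- mutual_information(compute_frequencies(ind, 0), min_separation = 1L)
  expect_equal(mi0$scores[1, 2], 0, tolerance = 1e-12)

  # 4-sequence toy with joint {AA, AA, AC, CC}: brute-force summation oracle
  toy <- alignment(paste0("s", 1:4), c("AAAA", "AAAA", "AACC", "CCCC"))
  # force equal weights via threshold 1 clustering (all rows distinct pairs
  # stay separate only if identity < 1; duplicates still cluster) -- use
  # explicit uniform weights through a degenerate threshold instead:
  wa3 <- weight_alignment(toy, threshold = 1)
  f <- compute_frequencies(wa3, 0)
  got <- mutual_information(f, min_separation = 1L)$scores[1, 4]
  # oracle: direct summation over the empirical 21 x 21 joint
  w <- sequence_weights(toy, 1); w <- w / sum(w)
  states <- cbind(c("A", "A", "A", "C"), c("A", "A", "C", "C"))
  joint <- table(factor(states[, 1], levels = c("A", "C")),
                 factor(states[, 2], levels = c("A", "C")))
  pj <- as.matrix(joint)
  pj <- pj * NA
  for (a in 1:2) for (b in 1:2)
    pj[a, b] <- sum(w[states[, 1] == c("A", "C")[a] &
                      states[, 2] == c("A", "C")[b]])
  pa <- rowSums(pj); pb <- colSums(pj)
  oracle <- 0
  for (a in 1:2) for (b in 1:2)
    if (pj[a, b] > 0) oracle <- oracle + pj[a, b] * log(pj[a, b] / (pa[a] * pb[b]))
  expect_equal(got, unname(oracle), tolerance = 1e-12)
  expect_true(oracle > 0)
})

test_that("APC zeroes constant matrices and matches the direct formula", {
  const <- score_matrix(matrix(3, 8, 8), "MI", min_separation = 2L)
  cor1 <- apc(const)
  expect_equal(max(abs(cor1$scores), na.rm = TRUE), 0, tolerance = 1e-12)
  # idempotent on the constant matrix
  expect_equal(max(abs(apc(cor1)$scores), na.rm = TRUE), 0, tolerance = 1e-12)

  # 4x4 toy, spreadsheet-style oracle with min_separation 1
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(1, 2, 5, 3, 4, 2)
  m <- m + t(m)
  sm <- score_matrix(m, "MI", min_separation = 1L)
  got <- apc(sm)$scores
  s <- sm$scores
  rmean <- rowMeans(s, na.rm = TRUE)
  gmean <- mean(s, na.rm = TRUE)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(got[i, j], s[i, j] - rmean[i] * rmean[j] / gmean,
                 tolerance = 1e-12)
  expect_equal(got, t(got))
  expect_error(apc(score_matrix(matrix(1, 3, 3), "MI", min_separation = 5L)),
               "masked")
})

test_that("mean-field DCA agrees with an independent inversion oracle", {
  fam <- small_family()
  wa <- weight_alignment(fam$alignment)
  freq <- compute_frequencies(wa, sum(wa$weights))
  got <- mfdca(freq)

  # oracle: rebuild the 20-state connected correlation by explicit loops,
  # invert, gauge, Frobenius, APC -- all in plain R
  L <- freq$L; q <- freq$q; p <- q - 1
  C <- matrix(0, L * p, L * p)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    fij <- freq$f2[((i - 1) * q + 1):((i - 1) * q + p),
                   ((j - 1) * q + 1):((j - 1) * q + p)]
    C[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p)] <-
      fij - outer(freq$f1[1:p, i], freq$f1[1:p, j])
  }
  invC <- solve(C)
  raw <- matrix(0, L, L)
  zsg <- function(B) B - outer(rowMeans(B), rep(1, ncol(B))) -
    outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    blk <- -invC[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p)]
    raw[i, j] <- raw[j, i] <- sqrt(sum(zsg(blk)^2))
  }
  rmean <- rowMeans(replace(raw, abs(row(raw) - col(raw)) < 4, NA), na.rm = TRUE)
  keep <- abs(row(raw) - col(raw)) >= 4
  gmean <- mean(raw[keep])
  expected <- raw - outer(rmean, rmean) / gmean
  ut <- which(upper.tri(raw) & keep, arr.ind = TRUE)
  expect_equal(got$scores[ut], expected[ut], tolerance = 1e-8)
})

test_that("mean-field scores vanish for independent columns", {
  # beta = 0: no couplings, scores should carry no structure
  topo <- sample_topology(20, seed = 3)
  model0 <- build_potts(topo, 0, seed = 3)
  aln <- gibbs_sample_msa(model0, sim_config(L = 20, n_sequences = 1500, seed = 3))
  wa <- weight_alignment(aln)
  sc_null <- mfdca(compute_frequencies(wa, sum(wa$weights)))
  fam <- small_family()
  wa1 <- weight_alignment(fam$alignment)
  sc_sig <- mfdca(compute_frequencies(wa1, sum(wa1$weights)))
  # coupled family's top score dwarfs the null family's
  expect_gt(max(sc_sig$scores, na.rm = TRUE),
            3 * max(abs(sc_null$scores), na.rm = TRUE))
})

test_that("graphical lasso matches the direct inverse at rho 0 and the 2x2 closed form", {
  # well-conditioned covariance from a small random SPD matrix
  set.seed(42)
  A <- matrix(rnorm(36), 6, 6)
  S <- crossprod(A) / 6 + diag(6) * 0.5
  fit <- metacontact:::glasso_cpp(S, 0, 1e-9, 200L)
  expect_true(fit$converged)
  expect_equal(fit$theta, solve(S), tolerance = 1e-5)

  # 2x2 closed form: w12 = soft(S12, rho), Theta from the 2x2 inverse
  S2 <- matrix(c(2, 0.8, 0.8, 1.5), 2, 2)
  rho <- 0.3
  fit2 <- metacontact:::glasso_cpp(S2, rho, 1e-12, 200L)
  w12 <- sign(S2[1, 2]) * max(abs(S2[1, 2]) - rho, 0)
  W <- matrix(c(S2[1, 1] + rho, w12, w12, S2[2, 2] + rho), 2, 2)
  expect_equal(fit2$w, W, tolerance = 1e-10)
  expect_equal(fit2$theta, solve(W), tolerance = 1e-8)

  # full shrinkage: huge rho forces a diagonal precision -> zero pair scores
  fam <- small_family()
  wa <- weight_alignment(fam$alignment)
  freq <- compute_frequencies(wa, 1)
  big <- psicov_glasso(freq, rho = 10)
  expect_equal(max(abs(big$scores), na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("graphical lasso objective improves monotonically across sweeps", {
  set.seed(7)
  A <- matrix(rnorm(400), 20, 20)
  S <- crossprod(A) / 20 + 0.2 * diag(20)
  fit <- metacontact:::glasso_cpp(S, 0.05, 1e-8, 100L, track_obj = TRUE)
  obj <- fit$obj_trace
  expect_true(all(is.finite(obj)))
  expect_true(all(diff(obj) > -1e-8))

  fam <- small_family()
  wa <- weight_alignment(fam$alignment)
  ps <- psicov_glasso(compute_frequencies(wa, 1))
  expect_true(attr(ps, "converged"))
})

test_that("pseudolikelihood gradient matches central finite differences", {
  set.seed(1)
  L <- 3; q <- n_states()
  msa <- matrix(sample.int(q, 5 * L, replace = TRUE), 5, L)
  w <- runif(5, 0.5, 1)
  npar <- L * q + choose(L, 2) * q * q
  par <- rnorm(npar, sd = 0.1)
  res <- metacontact:::plm_obj_grad_cpp(par, msa, w, q, 0.01, 0.05)
  # probe a deterministic spread of coordinates
  probes <- unique(round(seq(1, npar, length.out = 60)))
  h <- 1e-5
  for (k in probes) {
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    fd <- (metacontact:::plm_obj_grad_cpp(pp, msa, w, q, 0.01, 0.05)$obj -
           metacontact:::plm_obj_grad_cpp(pm, msa, w, q, 0.01, 0.05)$obj) / (2 * h)
    expect_equal(res$grad[k], fd, tolerance = 1e-5)
  }
})

test_that("strong regularization on a single sequence kills all couplings", {
  wa <- weight_alignment(alignment("q", "MKVAWMKVAW"))
  fit <- suppressWarnings(plm_couplings(wa, l2_field = 0.01, l2_coupling = 200,
                                        max_iter = 200))
  q <- n_states()
  maxJ <- 0
  for (i in 1:9) for (j in (i + 1):10)
    maxJ <- max(maxJ, max(abs(coupling_block(fit$model, i, j))))
  expect_lt(maxJ, 1e-3)
})

test_that("pseudolikelihood couplings track the exact two-site log-odds", {
  # two informative columns; the exact maximum-entropy coupling contrast for
  # a 2-site model is the log odds ratio ln(f(AA) f(CC) / (f(AC) f(CA)))
  rows <- c(rep("AAMK", 12), rep("CCMK", 12), rep("ACMK", 3), rep("CAMK", 3))
  aln <- alignment(paste0("s", seq_along(rows)), rows)
  wa <- list(alignment = aln, weights = rep(1, length(rows)),
             neff = length(rows), identity_threshold = 1)
  class(wa) <- "weighted_alignment"
  fit <- suppressWarnings(plm_couplings(wa, l2_coupling = 0.01, max_iter = 200,
                                        min_separation = 1L))
  blk <- metacontact:::zero_sum_gauge_block(coupling_block(fit$model, 1, 2))
  a <- 1; c_ <- 2  # state indices of A and C in the alphabet
  contrast <- blk[a, a] + blk[c_, c_] - blk[a, c_] - blk[c_, a]
  logodds <- log((12 * 12) / (3 * 3))
  expect_gt(contrast, 0)            # sign agrees with positive association
  # shrunk toward zero by the L2 penalty but the same order of magnitude
  expect_gt(contrast, 0.3 * logodds)
  expect_lt(contrast, 1.5 * logodds)

  # an uninformative pair scores below the associated pair
  sc <- fit$scores$scores
  expect_gt(sc[1, 2] - min(sc, na.rm = TRUE), 0)
})

test_that("score matrices are symmetric with a masked near-diagonal", {
  fam <- small_family()
  fs <- family_scores(fam)
  for (nm in names(fs$scores)) {
    s <- fs$scores[[nm]]$scores
    expect_equal(s, t(s), info = nm)
    expect_true(all(is.na(s[abs(row(s) - col(s)) < 4])), info = nm)
    if (nm == "mi") expect_true(all(s[!is.na(s)] >= 0))
  }
})

test_that("the engines produce non-identical top-L/5 contact lists", {
  fam <- small_family()
  fs <- family_scores(fam)
  k <- floor(30 / 5)
  tops <- lapply(fs$scores[c("mip", "mfdca", "psicov", "plm")], function(sm) {
    rp <- ranked_pairs(sm)[seq_len(k), ]
    paste(rp$i, rp$j)
  })
  combos <- utils::combn(length(tops), 2)
  identical_all <- all(apply(combos, 2, function(ix)
    identical(sort(tops[[ix[1]]]), sort(tops[[ix[2]]]))))
  expect_false(identical_all)
})
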