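# Two-stage network: training determinism, prediction contracts, stage-2
# windowing, outlier suppression and gap filling.

test_that("stage 1 learns a linearly separable toy problem", {
  set.seed(3)
  n <- 300
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  X <- X[abs(rowSums(X)) > 0.2, ]        # margin makes separability strict
  y <- as.integer(X[, 1] + X[, 2] > 0)
  cfg <- metanet_config(hidden1 = 8L, epochs1 = 200L, learning_rate = 0.02,
                        train_seed = 2L, negative_ratio = 1)
  m <- train_stage1(list(X = X), y, cfg)
  p <- metacontact:::predict_mlp(m, X)
  expect_equal(mean((p > 0.5) == y), 1.0)
})

test_that("training is bitwise deterministic under a fixed seed", {
  set.seed(4)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.integer(X[, 1] > 0)
  cfg <- metanet_config(hidden1 = 6L, epochs1 = 30L, train_seed = 11L)
  m1 <- train_stage1(list(X = X), y, cfg)
  m2 <- train_stage1(list(X = X), y, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  m3 <- train_stage1(list(X = X), y, metanet_config(hidden1 = 6L,
                                                    epochs1 = 30L,
                                                    train_seed = 12L))
  expect_false(identical(m1$W1, m3$W1))
})

test_that("degenerate labels are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(train_stage1(list(X = X), rep(0L, 20)), "degenerate")
})

test_that("stage-1 maps are symmetric with probabilities in (0, 1)", {
  fam <- small_family()
  fs <- family_scores(fam)
  feats <- assemble_pair_features(fs$walign, fs$scores)
  labels <- pair_labels(feats$pairs, fam$topology)
  cfg <- metanet_config(hidden1 = 10L, epochs1 = 5L, train_seed = 1L)
  m <- train_stage1(feats, labels, cfg)
  map <- predict_stage1(m, feats)
  expect_equal(map$probs, t(map$probs))
  vals <- map$probs[!is.na(map$probs)]
  expect_true(all(vals > 0 & vals < 1))
  expect_true(all(is.na(map$probs[abs(row(map$probs) - col(map$probs)) < 4])))
})

test_that("a zero-weight network outputs the logistic of its bias", {
  m <- structure(list(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
                      w2 = rep(0, 4), b2 = 0.7, n_input = 3L, hidden = 4L,
                      train_seed = 1L), class = "mlp_model")
  p <- metacontact:::predict_mlp(m, matrix(rnorm(30), 10, 3))
  expect_equal(p, rep(plogis(0.7), 10), tolerance = 1e-12)
})

test_that("stage-2 windows are extracted with padding and globals appended", {
  probs <- matrix(runif(900), 30, 30)
  probs <- (probs + t(probs)) / 2
  map <- contact_map(probs, min_separation = 4L)
  v <- extract_stage2_features(map, c(10, 20), depth = c(1.5, 2.5),
                               window = 11L)
  expect_length(v, 121 + 2 + 6)
  # center cell equals the map probability
  expect_equal(v[61], map$probs[10, 20])

  # corner pair: out-of-map cells carry the pad value
  vc <- extract_stage2_features(map, c(1, 5), depth = c(1.5, 2.5),
                                window = 11L, pad_value = -9)
  expect_true(sum(vc[1:121] == -9) > 0)

  # window 1 reduces to the single stage-1 probability
  v1 <- extract_stage2_features(map, c(8, 25), depth = numeric(0), window = 1L)
  expect_equal(v1[1], map$probs[8, 25])
})

test_that("stage 2 suppresses isolated outliers and fills gaps", {
  # modify genuine stage-1 maps from held-out families: inject an isolated
  # bright pixel into a quiet neighborhood, or knock a hole into a dense
  # predicted-contact block, and compare stage-2 against the altered value
  model <- trained_model()
  cfg <- model$net_config
  outlier_delta <- gap_delta <- numeric(0)
  for (s in c(5, 6)) {
    fam <- small_family(seed = s, L = 30, n = 400)
    fs <- family_scores(fam)
    feats <- assemble_pair_features(fs$walign, fs$scores,
                                    config = model$feat_config)
    map1 <- predict_stage1(model$stage1, feats)
    depth <- c(log1p(fs$walign$neff), log1p(fam$alignment$N))
    pr <- map1$probs
    ut <- which(upper.tri(pr) & !is.na(pr), arr.ind = TRUE)

    # quiet pixels: low probability and low neighborhood mean
    nbr_mean <- vapply(seq_len(nrow(ut)), function(k) {
      i <- ut[k, 1]; j <- ut[k, 2]
      w <- pr[max(1, i - 2):min(30, i + 2), max(1, j - 2):min(30, j + 2)]
      mean(w, na.rm = TRUE)
    }, numeric(1))
    quiet <- ut[order(nbr_mean)[1:3], , drop = FALSE]
    for (k in seq_len(nrow(quiet))) {
      i <- quiet[k, 1]; j <- quiet[k, 2]
      m1 <- map1
      m1$probs[i, j] <- m1$probs[j, i] <- 0.95
      map2 <- predict_stage2(model$stage2, m1, rbind(c(i, j)), depth, cfg)
      outlier_delta <- c(outlier_delta, map2$probs[i, j] - 0.95)
    }

    # dense pixels: high neighborhood mean; knock the center out
    dense <- ut[order(-nbr_mean)[1:3], , drop = FALSE]
    for (k in seq_len(nrow(dense))) {
      i <- dense[k, 1]; j <- dense[k, 2]
      m1 <- map1
      m1$probs[i, j] <- m1$probs[j, i] <- 0.02
      map2 <- predict_stage2(model$stage2, m1, rbind(c(i, j)), depth, cfg)
      gap_delta <- c(gap_delta, map2$probs[i, j] - 0.02)
    }
  }
  expect_lt(mean(outlier_delta), 0)   # outlier probability reduced
  expect_gt(mean(gap_delta), 0)       # gap probability raised
})

test_that("end-to-end prediction handles a single-sequence alignment", {
  model <- trained_model()
  aln <- alignment("q", paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = ""))
  map <- suppressWarnings(predict_contacts(aln, model, plm_max_iter = 5))
  vals <- map$probs[!is.na(map$probs)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(map$stage, 2L)
})

test_that("prediction is reproducible and models reload bit-exactly", {
  model <- trained_model()
  fam <- small_family()
  fs <- family_scores(fam)
  m1 <- predict_contacts(fam$alignment, model, scores = fs$scores)
  m2 <- predict_contacts(fam$alignment, model, scores = fs$scores)
  expect_identical(m1$probs, m2$probs)
  p <- tempfile(fileext = ".rds")
  write_model(model, p)
  back <- read_model(p)
  expect_identical(back$stage1$W1, model$stage1$W1)
  expect_identical(back$stage2$W1, model$stage2$W1)
  m3 <- predict_contacts(fam$alignment, back, scores = fs$scores)
  expect_identical(m1$probs, m3$probs)
})
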