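# Two-stage neural-network meta-predictor. Stage 1 maps per-pair feature
# vectors to an initial contact probability map; stage 2 re-scores each pair
# from a window of the stage-1 map (plus depth and separation terms),
# removing isolated outliers and filling gaps in contiguous contact blocks.

#' Meta-predictor network configuration
#'
#' @param stage2_window odd window width (>= 3) of the stage-1 contact map
#'   patch fed to stage 2 (default 11).
#' @param hidden1,hidden2 hidden-layer sizes of the two stages (default 50).
#' @param epochs1,epochs2 training epochs (defaults 30 and 60; the second
#'   stage sees fewer effective patterns per family and benefits from the
#'   longer schedule).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param batch_size mini-batch size (default 64).
#' @param l2 L2 weight penalty (default 1e-5).
#' @param negative_ratio effective non-contact:contact weighting ratio used
#'   to down-weight the abundant negative class (default 5).
#' @param pad_value sentinel for out-of-map cells in the stage-2 patch
#'   (default 0).
#' @param augment_fraction fraction of stage-2 training windows duplicated
#'   with a corrupted center pixel (non-contact centers raised, contact
#'   centers lowered, labels kept) so the second stage learns to overrule
#'   an isolated center from its neighborhood -- the mechanism behind
#'   outlier removal and gap filling (default 0.03; corrupted-contact
#'   copies carry reduced weight so gap filling does not inflate
#'   bright-neighborhood non-contacts).
#' @param train_seed integer seed governing all training stochasticity
#'   (initialization, shuffling and augmentation).
#' @return a `metanet_config` list.
#' @export
metanet_config <- function(stage2_window = 11L, hidden1 = 50L, hidden2 = 50L,
                           epochs1 = 30L, epochs2 = 60L,
                           learning_rate = 0.005, batch_size = 64L,
                           l2 = 1e-5, negative_ratio = 5,
                           pad_value = 0, augment_fraction = 0.03,
                           train_seed = 1L) {
  if (stage2_window %% 2 != 1 || stage2_window < 3)
    stop("stage2_window must be odd and >= 3")
  if (augment_fraction < 0 || augment_fraction > 1)
    stop("augment_fraction must be in [0, 1]")
  structure(list(stage2_window = as.integer(stage2_window),
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 epochs1 = as.integer(epochs1), epochs2 = as.integer(epochs2),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l2 = l2,
                 negative_ratio = negative_ratio, pad_value = pad_value,
                 augment_fraction = augment_fraction,
                 train_seed = as.integer(train_seed)),
            class = "metanet_config")
}

# class-balance sample weights: negatives down-weighted to ratio:1
balance_weights <- function(labels, ratio) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  w <- rep(1, length(labels))
  if (npos > 0 && nneg > 0) w[labels == 0] <- ratio * npos / nneg
  w
}

train_mlp <- function(X, labels, hidden, epochs, config, seed_offset,
                      weight_mult = NULL) {
  if (length(unique(labels)) < 2)
    stop("training labels are degenerate (single class)")
  if (any(!is.finite(X))) stop("non-finite training features")
  sw <- balance_weights(labels, config$negative_ratio)
  if (!is.null(weight_mult)) sw <- sw * weight_mult
  fit <- mlp_train_cpp(X, as.numeric(labels), sw, hidden, epochs,
                       config$learning_rate, config$batch_size, config$l2,
                       config$train_seed + seed_offset)
  structure(list(W1 = fit$W1, b1 = as.numeric(fit$b1),
                 w2 = as.numeric(fit$w2), b2 = as.numeric(fit$b2),
                 n_input = ncol(X), hidden = hidden,
                 train_seed = config$train_seed + seed_offset),
            class = "mlp_model")
}

predict_mlp <- function(model, X) {
  if (ncol(X) != model$n_input)
    stop("feature length does not match model input dimension")
  as.numeric(mlp_predict_cpp(model$W1, model$b1, model$w2, model$b2, X))
}

#' Train the stage-1 network
#'
#' @param features an [assemble_pair_features()] result (or any matrix-like
#'   list with `X`).
#' @param labels binary contact labels (0/1) per feature row.
#' @param config a [metanet_config()].
#' @return an `mlp_model`; training is deterministic given
#'   `config$train_seed`.
#' @export
train_stage1 <- function(features, labels, config = metanet_config()) {
  train_mlp(features$X, labels, config$hidden1, config$epochs1, config, 0L)
}

#' Construct a contact probability map object
#'
#' @param probs L x L matrix of probabilities; near-diagonal masked to NA.
#' @param min_separation mask width (default 4).
#' @param stage which network stage produced it (1 or 2).
#' @return a `contact_map`.
#' @export
contact_map <- function(probs, min_separation = 4L, stage = 1L) {
  probs <- (probs + t(probs)) / 2
  mask <- abs(row(probs) - col(probs)) < min_separation
  probs[mask] <- NA_real_
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    stop("contact probabilities must lie in [0, 1]")
  structure(list(probs = probs, min_separation = as.integer(min_separation),
                 stage = as.integer(stage), L = nrow(probs)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact probability map (stage %d): L = %d\n", x$stage, x$L))
  invisible(x)
}

#' Predict the stage-1 contact map
#'
#' @param model a trained stage-1 `mlp_model`.
#' @param features an [assemble_pair_features()] result for the target.
#' @param L target length.
#' @param min_separation mask width (default 4).
#' @return a [contact_map()] with `stage = 1`.
#' @export
predict_stage1 <- function(model, features, L = features$L,
                           min_separation = 4L) {
  p <- predict_mlp(model, features$X)
  probs <- matrix(0, L, L)
  probs[features$pairs] <- p
  probs[features$pairs[, c(2, 1), drop = FALSE]] <- p
  contact_map(probs, min_separation, stage = 1L)
}

#' Extract stage-2 features for one pair
#'
#' The `window x window` patch of stage-1 probabilities centered at (i, j),
#' row-major, with out-of-map (or masked) cells padded, concatenated with
#' the global depth terms and the one-hot separation bin.
#'
#' @param map a stage-1 [contact_map()].
#' @param pair integer pair `c(i, j)`.
#' @param depth numeric vector of global depth features
#'   (`ln(1+N_eff)`, `ln(1+N)`).
#' @param window odd patch width (default 11).
#' @param pad_value fill for out-of-map cells (default 0).
#' @param sep_breaks separation-bin upper bounds, as in [feature_config()].
#' @return numeric feature vector of length `window^2 + length(depth) +
#'   number of separation bins`.
#' @export
extract_stage2_features <- function(map, pair, depth, window = 11L,
                                    pad_value = 0,
                                    sep_breaks = c(8L, 13L, 18L, 23L, 38L)) {
  if (window %% 2 != 1) stop("window must be odd")
  w2 <- (window - 1L) %/% 2L
  i <- pair[1]; j <- pair[2]
  L <- map$L
  ri <- (i - w2):(i + w2)
  rj <- (j - w2):(j + w2)
  patch <- matrix(pad_value, window, window)
  okr <- ri >= 1 & ri <= L
  okc <- rj >= 1 & rj <= L
  sub <- map$probs[ri[okr], rj[okc], drop = FALSE]
  sub[is.na(sub)] <- pad_value
  patch[okr, okc] <- sub
  c(as.vector(t(patch)), depth, sep_bin_onehot(abs(j - i), sep_breaks))
}

stage2_feature_matrix <- function(map, pairs, depth, config) {
  t(apply(pairs, 1, function(p)
    extract_stage2_features(map, p, depth, config$stage2_window,
                            config$pad_value)))
}

#' Train the stage-2 network
#'
#' @param stage1_maps list of stage-1 [contact_map()]s (one per training
#'   family).
#' @param pair_sets list of pair matrices matching `stage1_maps`.
#' @param depth_sets list of depth feature vectors matching `stage1_maps`.
#' @param label_sets list of binary label vectors matching `pair_sets`.
#' @param config a [metanet_config()].
#' @return an `mlp_model` for stage 2.
#' @export
train_stage2 <- function(stage1_maps, pair_sets, depth_sets, label_sets,
                         config = metanet_config()) {
  Xs <- mapply(stage2_feature_matrix, stage1_maps, pair_sets, depth_sets,
               MoreArgs = list(config = config), SIMPLIFY = FALSE)
  X <- do.call(rbind, Xs)
  labels <- unlist(label_sets)
  weight_mult <- NULL
  if (config$augment_fraction > 0) {
    # denoising augmentation: corrupted-center copies teach the network to
    # weigh the window against an inconsistent center pixel. Spuriously
    # bright non-contact centers (the outlier case) are the main target;
    # knocked-out contact centers (the gap case) are added at reduced
    # weight so gap filling does not inflate bright-neighborhood
    # non-contacts on clean maps.
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$train_seed + 977L)
    n <- nrow(X)
    pick <- which(stats::runif(n) < config$augment_fraction)
    if (length(pick) > 0) {
      center <- (config$stage2_window^2 + 1) %/% 2
      Xa <- X[pick, , drop = FALSE]
      la <- labels[pick]
      Xa[, center] <- ifelse(la == 1, stats::runif(length(pick), 0, 0.1),
                             stats::runif(length(pick), 0.85, 1))
      X <- rbind(X, Xa)
      labels <- c(labels, la)
      weight_mult <- c(rep(1, n), ifelse(la == 1, 0.25, 1))
    }
  }
  train_mlp(X, labels, config$hidden2, config$epochs2, config, 1L,
            weight_mult = weight_mult)
}

#' Predict the stage-2 contact map
#'
#' @param model a trained stage-2 `mlp_model`.
#' @param stage1_map the stage-1 [contact_map()] for the target.
#' @param pairs pair matrix of pairs to score.
#' @param depth global depth feature vector.
#' @param config a [metanet_config()].
#' @return a [contact_map()] with `stage = 2`.
#' @export
predict_stage2 <- function(model, stage1_map, pairs, depth,
                           config = metanet_config()) {
  X <- stage2_feature_matrix(stage1_map, pairs, depth, config)
  p <- predict_mlp(model, X)
  L <- stage1_map$L
  probs <- matrix(0, L, L)
  probs[pairs] <- p
  probs[pairs[, c(2, 1), drop = FALSE]] <- p
  contact_map(probs, stage1_map$min_separation, stage = 2L)
}

#' Train the full two-stage meta-predictor on simulated families
#'
#' Generates (or accepts) training families, computes covariation scores and
#' pair features, trains stage 1, produces stage-1 maps, and trains stage 2
#' on map windows. Labels are taken from the generating topology: contact
#' iff pair distance <= 8 in the ground-truth chain.
#'
#' @param families list of [generate_family()] results.
#' @param feat_config a [feature_config()].
#' @param net_config a [metanet_config()].
#' @param min_separation pair mask width (default 4).
#' @param ... passed through to [coupling_scores()].
#' @return a `metanet_model` bundling both stages and the configs.
#' @export
train_metanet <- function(families, feat_config = feature_config(),
                          net_config = metanet_config(),
                          min_separation = 4L, ...) {
  feats <- list(); labels <- list(); depths <- list()
  for (k in seq_along(families)) {
    fam <- families[[k]]
    wa <- weight_alignment(fam$alignment)
    sc <- coupling_scores(wa, methods = feat_config$include_methods,
                          min_separation = min_separation, ...)
    fs <- assemble_pair_features(wa, sc, config = feat_config,
                                 min_separation = min_separation)
    feats[[k]] <- fs
    labels[[k]] <- pair_labels(fs$pairs, fam$topology)
    depths[[k]] <- c(log1p(wa$neff), log1p(fam$alignment$N))
  }
  allX <- do.call(rbind, lapply(feats, `[[`, "X"))
  s1 <- train_mlp(allX, unlist(labels), net_config$hidden1,
                  net_config$epochs1, net_config, 0L)
  maps <- lapply(feats, function(fs) predict_stage1(s1, fs, fs$L, min_separation))
  s2 <- train_stage2(maps, lapply(feats, `[[`, "pairs"), depths, labels,
                     net_config)
  structure(list(stage1 = s1, stage2 = s2, feat_config = feat_config,
                 net_config = net_config, min_separation = min_separation,
                 train_seed = net_config$train_seed,
                 feature_names = feats[[1]]$feature_names,
                 version = "1"),
            class = "metanet_model")
}

#' Binary contact labels for a pair matrix from a ground-truth topology
#' @param pairs two-column pair matrix (`i < j`).
#' @param topology a [sample_topology()] result.
#' @return 0/1 vector.
#' @export
pair_labels <- function(pairs, topology) {
  truth <- paste(topology$contacts[, 1], topology$contacts[, 2])
  as.integer(paste(pairs[, 1], pairs[, 2]) %in% truth)
}

#' End-to-end contact prediction for an alignment
#'
#' Runs weighting, the configured covariation engines, feature assembly and
#' both network stages. Deterministic for fixed inputs and models.
#'
#' @param aln an [alignment()].
#' @param model a [train_metanet()] result.
#' @param scores optional precomputed [coupling_scores()] list (to avoid
#'   re-running the covariation engines when their outputs already exist).
#' @param ... passed through to [coupling_scores()].
#' @return the stage-2 [contact_map()].
#' @export
predict_contacts <- function(aln, model, scores = NULL, ...) {
  wa <- weight_alignment(aln)
  sc <- if (!is.null(scores)) scores
    else coupling_scores(wa, methods = model$feat_config$include_methods,
                         min_separation = model$min_separation, ...)
  fs <- assemble_pair_features(wa, sc, config = model$feat_config,
                               min_separation = model$min_separation)
  map1 <- predict_stage1(model$stage1, fs, fs$L, model$min_separation)
  depth <- c(log1p(wa$neff), log1p(aln$N))
  predict_stage2(model$stage2, map1, fs$pairs, depth, model$net_config)
}

#' Save / load a meta-predictor model
#'
#' Models are serialized with R's native serialization so reloading is
#' bit-exact; the container records both stage architectures, weights,
#' feature configuration and the training seed.
#'
#' @param model a `metanet_model`.
#' @param path file path.
#' @return `read_model` returns the `metanet_model`.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "metanet_model")) stop("not a metanet model file: ", path)
  m
}
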