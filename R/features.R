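# Per-pair feature assembly: covariation scores, windowed column profiles
# (frequencies, gap fraction, entropy), one-hot sequence-separation bins,
# global alignment-depth terms, and optional per-residue secondary
# structure / accessibility inputs.

#' Feature layout configuration
#'
#' @param column_window odd window width around each of the two residues for
#'   column-profile features (default 5, i.e. +/-2 columns).
#' @param include_methods method tags whose score matrices feed the feature
#'   vector; must match the names of the score list passed to
#'   [assemble_pair_features()].
#' @param use_ss include 3-state secondary-structure probabilities from the
#'   auxiliary table (default FALSE).
#' @param use_acc include the relative solvent accessibility column from the
#'   auxiliary table (default FALSE).
#' @param rank_scores also include each method's within-family percentile
#'   rank at (i, j) alongside the raw score (default FALSE). Raw coupling
#'   scores have family-dependent scales; the rank is a scale-free
#'   alternative view of the same evidence.
#' @param pad_value sentinel written for out-of-range window columns
#'   (default -1).
#' @param sep_breaks upper bounds of the one-hot sequence-separation bins;
#'   the default bins are 4-8, 9-13, 14-18, 19-23, 24-38, >=39.
#' @return a `feature_config` list.
#' @export
feature_config <- function(column_window = 5L,
                           include_methods = c("mip", "mfdca", "psicov", "plm"),
                           use_ss = FALSE, use_acc = FALSE,
                           rank_scores = FALSE, pad_value = -1,
                           sep_breaks = c(8L, 13L, 18L, 23L, 38L)) {
  if (column_window %% 2 != 1) stop("column_window must be odd")
  if (length(include_methods) < 1) stop("at least one method must be included")
  structure(list(column_window = as.integer(column_window),
                 include_methods = include_methods,
                 use_ss = use_ss, use_acc = use_acc,
                 rank_scores = rank_scores,
                 pad_value = pad_value, sep_breaks = as.integer(sep_breaks)),
            class = "feature_config")
}

sep_bin_onehot <- function(sep, breaks) {
  nb <- length(breaks) + 1
  bin <- findInterval(sep, breaks + 1L) + 1L
  out <- numeric(nb)
  out[bin] <- 1
  out
}

# per-column profile block: 21 frequencies + gap fraction + entropy
column_profiles <- function(freq) {
  f1 <- freq$f1
  rownames(f1) <- paste0("f", sub("-", "gap", AA_ALPHABET))
  ent <- apply(f1, 2, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  rbind(f1, gapfrac = f1[nrow(f1), ], entropy = ent)
}

#' Assemble per-pair feature vectors
#'
#' For every eligible pair (i, j) with `|i - j| >= min_separation` the
#' vector contains: each included method's score at (i, j); the windowed
#' column profiles (21 state frequencies, gap fraction, Shannon entropy per
#' column) around i and around j; a one-hot sequence-separation bin; global
#' depth terms `ln(1 + N_eff)` and `ln(1 + N)`; and, if configured, 3-state
#' secondary-structure probabilities and accessibility per windowed column.
#' Out-of-range window columns are filled with `pad_value`. Features are
#' computed for canonical ordering `i < j`; the pair is symmetric under the
#' convention that the first window belongs to the lower index.
#'
#' @param walign a [weight_alignment()] result.
#' @param scores named list of [score_matrix()] objects sharing the
#'   alignment's L; names must cover `config$include_methods`.
#' @param aux optional per-residue data.frame with columns
#'   `index, aa, ss3_H, ss3_E, ss3_C, acc` (1-based indices).
#' @param config a [feature_config()].
#' @param min_separation minimum pair separation (default 4).
#' @param pseudocount pseudocount for the profile frequencies (default 1).
#' @return list with `X` (pairs x features matrix), `pairs` (two-column
#'   matrix, `i < j`), `feature_names`, and `L`.
#' @export
assemble_pair_features <- function(walign, scores, aux = NULL,
                                   config = feature_config(),
                                   min_separation = 4L, pseudocount = 1) {
  aln <- walign$alignment
  L <- aln$L
  missing_m <- setdiff(config$include_methods, names(scores))
  if (length(missing_m) > 0)
    stop("score matrices missing for method(s): ", paste(missing_m, collapse = ", "))
  for (m in config$include_methods)
    if (scores[[m]]$L != L) stop("score matrix L mismatch for method ", m)
  if ((config$use_ss || config$use_acc) && is.null(aux))
    stop("auxiliary table required when use_ss or use_acc is set")
  if (!is.null(aux) && nrow(aux) != L)
    stop("auxiliary table must have one row per residue")

  freq <- compute_frequencies(walign, pseudocount)
  prof <- column_profiles(freq)          # (q + 2) x L
  if (any(!is.finite(prof))) stop("non-finite profile features")
  w2 <- (config$column_window - 1L) %/% 2L
  nprof <- nrow(prof)

  auxblock <- NULL
  if (config$use_ss || config$use_acc) {
    cols <- c(if (config$use_ss) c("ss3_H", "ss3_E", "ss3_C"),
              if (config$use_acc) "acc")
    auxblock <- t(as.matrix(aux[order(aux$index), cols, drop = FALSE]))
    if (any(!is.finite(auxblock))) stop("non-finite auxiliary features")
  }

  window_block <- function(center, block) {
    cols <- (center - w2):(center + w2)
    out <- matrix(config$pad_value, nrow(block), length(cols))
    inr <- cols >= 1 & cols <= L
    out[, inr] <- block[, cols[inr], drop = FALSE]
    as.vector(out)
  }

  ut <- which(upper.tri(diag(L)) & abs(row(diag(L)) - col(diag(L))) >= min_separation,
              arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  npairs <- nrow(ut)

  # scale-free within-family percentile ranks of each method's scores
  rankmat <- NULL
  if (isTRUE(config$rank_scores)) {
    rankmat <- lapply(config$include_methods, function(m) {
      s <- scores[[m]]$scores
      r <- matrix(NA_real_, L, L)
      vals <- s[ut]
      r[ut] <- rank(vals, ties.method = "average") / length(vals)
      r[ut[, c(2, 1), drop = FALSE]] <- r[ut]
      r
    })
    names(rankmat) <- config$include_methods
  }

  nb <- length(config$sep_breaks) + 1
  nm <- length(config$include_methods) * (1 + isTRUE(config$rank_scores))
  naux <- if (is.null(auxblock)) 0 else nrow(auxblock) * 2 * config$column_window
  nfeat <- nm + 2 * config$column_window * nprof + nb + 2 + naux
  X <- matrix(0, npairs, nfeat)
  depth <- c(log1p(walign$neff), log1p(aln$N))

  for (k in seq_len(npairs)) {
    i <- ut[k, 1]; j <- ut[k, 2]
    v <- c(vapply(config$include_methods,
                  function(m) scores[[m]]$scores[i, j], numeric(1)),
           if (!is.null(rankmat))
             vapply(config$include_methods,
                    function(m) rankmat[[m]][i, j], numeric(1)),
           window_block(i, prof), window_block(j, prof),
           sep_bin_onehot(j - i, config$sep_breaks), depth)
    if (!is.null(auxblock))
      v <- c(v, window_block(i, auxblock), window_block(j, auxblock))
    X[k, ] <- v
  }
  if (any(!is.finite(X))) stop("non-finite feature values")

  feature_names <- c(
    paste0("score_", config$include_methods),
    if (!is.null(rankmat)) paste0("rank_", config$include_methods),
    paste0(rep(rownames(prof), 2 * w2 + 1), "_i_w",
           rep(seq_len(2 * w2 + 1), each = nprof)),
    paste0(rep(rownames(prof), 2 * w2 + 1), "_j_w",
           rep(seq_len(2 * w2 + 1), each = nprof)),
    paste0("sepbin_", seq_len(nb)), "log1p_neff", "log1p_n")
  if (!is.null(auxblock))
    feature_names <- c(feature_names,
                       paste0(rep(rownames(auxblock), 2 * w2 + 1), "_aux_i_w",
                              rep(seq_len(2 * w2 + 1), each = nrow(auxblock))),
                       paste0(rep(rownames(auxblock), 2 * w2 + 1), "_aux_j_w",
                              rep(seq_len(2 * w2 + 1), each = nrow(auxblock))))
  colnames(X) <- feature_names
  list(X = X, pairs = unname(ut), feature_names = feature_names, L = L)
}

#' Read a per-residue auxiliary feature table
#'
#' Whitespace-delimited file with columns
#' `index aa ss3_H ss3_E ss3_C acc` (1-based indices).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_aux_table <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("index", "aa", "ss3_H", "ss3_E", "ss3_C", "acc"))
  df
}
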