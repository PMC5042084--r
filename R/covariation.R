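# Covariation engines: mutual information (with average product correction),
# mean-field direct coupling analysis, sparse inverse covariance (graphical
# lasso), and pseudolikelihood Potts-model inference. Each produces an L x L
# symmetric coupling score matrix with the near-diagonal masked.

#' Weighted single-site and pairwise frequency model
#'
#' Frequencies over 21 states (20 amino acids + gap; unknowns count as gap)
#' with a symmetric pseudocount: `f_i(a) = (lambda/q + n_i(a)) / (lambda + W)`
#' and `f_ij(a,b) = (lambda/q^2 + n_ij(a,b)) / (lambda + W)` where `n` are
#' weighted counts and `W` the total sequence weight. With this split the
#' pair frequencies marginalize exactly to the single-site ones.
#'
#' @param walign a [weight_alignment()] result.
#' @param pseudocount pseudocount mass `lambda >= 0` (default 1).
#' @return a `frequency_model` with fields `f1` (q x L), `f2`
#'   ((L*q) x (L*q) block matrix), `pseudocount`, `weighted_n`, `L`, `q`.
#' @export
compute_frequencies <- function(walign, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  aln <- walign$alignment
  q <- n_states()
  counts <- freq_counts_cpp(encode_alignment(aln), walign$weights, q)
  W <- sum(walign$weights)
  f1 <- (pseudocount / q + counts$c1) / (pseudocount + W)
  f2 <- (pseudocount / q^2 + counts$c2) / (pseudocount + W)
  # diagonal blocks: the joint of a column with itself is exactly diagonal
  # (e_a e_b = 0 for a != b); this keeps the full f2 a genuine mixture
  # second-moment matrix, so the connected correlation is positive
  # semi-definite, and marginalization to f1 is exact
  for (i in seq_len(aln$L)) {
    idx <- ((i - 1) * q + 1):(i * q)
    f2[idx, idx] <- diag(f1[, i])
  }
  structure(list(f1 = f1, f2 = f2, pseudocount = pseudocount,
                 weighted_n = W, L = aln$L, q = q),
            class = "frequency_model")
}

#' Construct a coupling score matrix
#'
#' @param scores L x L numeric matrix (symmetrized; near-diagonal set to NA).
#' @param method method tag, e.g. `"MI"`, `"MIp"`, `"mfDCA"`, `"PSICOV"`,
#'   `"PLM"`.
#' @param min_separation pairs with `|i - j| < min_separation` are masked
#'   (default 4, i.e. scored pairs are four or more residues apart).
#' @return a `score_matrix` object.
#' @export
score_matrix <- function(scores, method, min_separation = 4L) {
  L <- nrow(scores)
  scores <- (scores + t(scores)) / 2
  mask <- abs(row(scores) - col(scores)) < min_separation
  scores[mask] <- NA_real_
  structure(list(scores = scores, method = method,
                 min_separation = as.integer(min_separation), L = L),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("%s coupling scores: L = %d, min separation %d\n",
              x$method, x$L, x$min_separation))
  invisible(x)
}

#' Mutual information between alignment columns
#'
#' `MI(i,j) = sum_ab f_ij(a,b) ln( f_ij(a,b) / (f_i(a) f_j(b)) )` in nats,
#' with the convention `0 ln 0 = 0`.
#'
#' @param freq a [compute_frequencies()] result.
#' @param min_separation near-diagonal mask width (default 4).
#' @return a [score_matrix()] tagged `"MI"`.
#' @export
mutual_information <- function(freq, min_separation = 4L) {
  L <- freq$L; q <- freq$q
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    fi <- freq$f1[, i]
    for (j in (i + 1):L) {
      fij <- freq$f2[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)]
      prod <- outer(fi, freq$f1[, j])
      term <- fij * log(fij / prod)
      term[fij == 0] <- 0
      mi[i, j] <- mi[j, i] <- sum(term)
    }
  }
  score_matrix(mi, "MI", min_separation)
}

#' Average product correction (APC)
#'
#' Subtracts the product of row/column mean scores over the global mean:
#' `S'(i,j) = S(i,j) - mean_i * mean_j / mean`, means taken over unmasked
#' entries only. Removes per-column background (phylogenetic/entropic) bias.
#'
#' @param sm a [score_matrix()].
#' @return a corrected [score_matrix()]; tag gains an `"p"`/`"-APC"` suffix.
#' @export
apc <- function(sm) {
  s <- sm$scores
  if (all(is.na(s))) stop("cannot apply APC: all entries are masked")
  rmean <- rowMeans(s, na.rm = TRUE)
  gmean <- mean(s, na.rm = TRUE)
  corr <- if (gmean == 0) matrix(0, nrow(s), ncol(s)) else outer(rmean, rmean) / gmean
  out <- s - corr
  tag <- if (sm$method == "MI") "MIp" else paste0(sm$method, "-APC")
  res <- score_matrix(ifelse(is.na(s), 0, out), tag, sm$min_separation)
  res$scores[is.na(s)] <- NA_real_
  res
}

# indices of the 20 amino-acid states (gap dropped) for column i
aa_block_idx <- function(i, q) ((i - 1) * q + 1):((i - 1) * q + q - 1)

# connected-correlation (covariance) matrix over 20 states per column
connected_correlation <- function(freq) {
  L <- freq$L; q <- freq$q
  keep <- as.vector(vapply(seq_len(L), aa_block_idx, integer(q - 1), q = q))
  f2 <- freq$f2[keep, keep]
  f1v <- as.vector(freq$f1[-q, ])
  f2 - outer(f1v, f1v)
}

# zero-sum gauge for a coupling block: remove row/column means
zero_sum_gauge_block <- function(B) {
  B - outer(rowMeans(B), rep(1, ncol(B))) -
    outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
}

# assemble an L x L score matrix from per-pair block norms + APC
block_norm_scores <- function(blocknorm, method, min_separation) {
  apc(score_matrix(blocknorm, method, min_separation))
}

#' Mean-field direct coupling analysis
#'
#' Inverts the connected-correlation matrix `C_ij(a,b) = f_ij(a,b) -
#' f_i(a) f_j(b)` built over 20 amino-acid states per column (the gap state
#' is dropped to remove the simplex degeneracy); the coupling estimate is
#' `e_ij = -(C^-1)_ij`. Pair scores are the Frobenius norms of the
#' zero-sum-gauged coupling blocks, followed by APC.
#'
#' @param freq a [compute_frequencies()] result; its pseudocount must be
#'   positive so the correlation matrix is invertible.
#' @param min_separation near-diagonal mask width (default 4).
#' @return a [score_matrix()] tagged `"mfDCA-APC"`.
#' @export
mfdca <- function(freq, min_separation = 4L) {
  if (freq$pseudocount <= 0)
    stop("mfDCA requires a positive pseudocount for invertibility")
  L <- freq$L; p <- freq$q - 1
  if (L < 2) stop("mfDCA requires at least two columns")
  C <- connected_correlation(freq)
  invC <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is singular; increase the pseudocount"))
  raw <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    ri <- ((i - 1) * p + 1):(i * p)
    for (j in (i + 1):L) {
      blk <- -invC[ri, ((j - 1) * p + 1):(j * p)]
      raw[i, j] <- raw[j, i] <- sqrt(sum(zero_sum_gauge_block(blk)^2))
    }
  }
  block_norm_scores(raw, "mfDCA", min_separation)
}

#' Sparse inverse covariance couplings (graphical lasso)
#'
#' Estimates `Theta = argmax log det(Theta) - tr(S Theta) - rho ||Theta||_1`
#' over the 20L-dimensional amino-acid indicator covariance by block
#' coordinate descent. Before estimation the sample covariance is shrunk
#' toward its diagonal, `S' = (1-g) S + g diag(S)`, with `g` increased from
#' `shrinkage` until `S'` is positive definite. The pair score is the L1
#' norm of the (i,j) precision block, followed by APC.
#'
#' @param freq a [compute_frequencies()] result.
#' @param rho L1 penalty (default 0.005).
#' @param shrinkage initial diagonal shrinkage coefficient in \[0, 1)
#'   (default 0.1).
#' @param tol convergence tolerance on the covariance update (default 1e-4).
#' @param max_iter maximum outer sweeps (default 30).
#' @param min_separation near-diagonal mask width (default 4).
#' @return a [score_matrix()] tagged `"PSICOV-APC"`, with attributes
#'   `converged` and `sweeps`; non-convergence produces a warning, not an
#'   error.
#' @export
psicov_glasso <- function(freq, rho = 0.005, shrinkage = 0.1, tol = 1e-4,
                          max_iter = 30L, min_separation = 4L) {
  if (rho < 0) stop("rho must be >= 0")
  if (shrinkage < 0 || shrinkage >= 1) stop("shrinkage must be in [0, 1)")
  L <- freq$L; p <- freq$q - 1
  S <- connected_correlation(freq)
  g <- shrinkage
  repeat {
    Ssh <- (1 - g) * S + g * diag(diag(S))
    mineig <- min(eigen(Ssh, symmetric = TRUE, only.values = TRUE)$values)
    if (mineig > 1e-10) break
    g <- if (g == 0) 0.05 else min(g * 1.5, 0.95)
    if (g >= 0.95 && mineig <= 1e-10)
      stop("covariance not positive definite even after maximal shrinkage")
  }
  fit <- glasso_cpp(Ssh, rho, tol, as.integer(max_iter))
  if (!fit$converged)
    warning("graphical lasso did not converge within max_iter sweeps")
  theta <- fit$theta
  raw <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    ri <- ((i - 1) * p + 1):(i * p)
    for (j in (i + 1):L) {
      blk <- theta[ri, ((j - 1) * p + 1):(j * p)]
      raw[i, j] <- raw[j, i] <- sum(abs(blk))
    }
  }
  out <- block_norm_scores(raw, "PSICOV", min_separation)
  attr(out, "converged") <- fit$converged
  attr(out, "sweeps") <- fit$sweeps
  attr(out, "theta") <- theta
  out
}

#' Construct a Potts model
#'
#' @param h q x L matrix of single-site fields.
#' @param Jm (L*q) x (L*q) coupling matrix in full symmetric block storage:
#'   block (i,j) holds `J_ij(a,b)` and equals the transpose of block (j,i).
#' @param gauge gauge tag (default `"zero_sum"`).
#' @return a `potts_model` object with fields `L`, `q`, `h`, `Jm`, `gauge`.
#' @export
potts_model <- function(h, Jm, gauge = "zero_sum") {
  q <- nrow(h); L <- ncol(h)
  stopifnot(nrow(Jm) == L * q, ncol(Jm) == L * q)
  structure(list(L = L, q = q, h = h, Jm = Jm, gauge = gauge),
            class = "potts_model")
}

#' Extract the coupling block J_ij of a Potts model
#' @param model a [potts_model()].
#' @param i,j column indices.
#' @return q x q matrix `J_ij(a,b)`.
#' @export
coupling_block <- function(model, i, j) {
  q <- model$q
  model$Jm[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)]
}

# pack/unpack the PLM parameter vector (h then i<j blocks, a fastest)
plm_npar <- function(L, q) L * q + L * (L - 1) / 2 * q * q

plm_unpack <- function(par, L, q) {
  h <- matrix(par[seq_len(L * q)], q, L)
  Jm <- matrix(0, L * q, L * q)
  off <- L * q
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      blk <- matrix(par[(off + 1):(off + q * q)], q, q)
      Jm[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)] <- blk
      Jm[((j - 1) * q + 1):(j * q), ((i - 1) * q + 1):(i * q)] <- t(blk)
      off <- off + q * q
    }
  }
  potts_model(h, Jm, gauge = "plm")
}

#' Pseudolikelihood Potts couplings
#'
#' Maximizes the weighted L2-regularized log-pseudolikelihood
#' `sum_s w_s sum_i ln P(x_si | x_s,-i; h, J)` by L-BFGS from a zero
#' initialization (deterministic: no random restarts). Pair scores are
#' Frobenius norms of the zero-sum-gauged coupling blocks, followed by APC.
#'
#' @param walign a [weight_alignment()] result.
#' @param l2_field L2 penalty on fields (default 0.01).
#' @param l2_coupling L2 penalty on couplings (default 0.05).
#' @param max_iter L-BFGS iteration cap (default 50); hitting the cap is
#'   flagged with a warning, not an error. Early stopping under the L2
#'   penalty acts as additional regularization; coupling rankings stabilize
#'   well before full convergence.
#' @param tol relative convergence tolerance passed to the optimizer
#'   (default 1e-7, as `factr = tol / .Machine$double.eps`).
#' @param min_separation near-diagonal mask width (default 4).
#' @return list with elements `model` (a [potts_model()]) and `scores`
#'   (a [score_matrix()] tagged `"PLM-APC"` with attribute `converged`).
#' @export
plm_couplings <- function(walign, l2_field = 0.01, l2_coupling = 0.05,
                          max_iter = 50L, tol = 1e-7, min_separation = 4L) {
  if (l2_field <= 0 || l2_coupling <= 0)
    stop("regularization strengths must be positive")
  aln <- walign$alignment
  L <- aln$L; q <- n_states()
  msa <- encode_alignment(aln)
  w <- walign$weights

  cache <- new.env(parent = emptyenv())
  evalboth <- function(par) {
    key <- c(par[1], par[length(par)], sum(par))
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    val <- plm_obj_grad_cpp(par, msa, w, q, l2_field, l2_coupling)
    cache$key <- key; cache$val <- val
    val
  }
  fn <- function(par) evalboth(par)$obj
  gr <- function(par) evalboth(par)$grad

  par0 <- numeric(plm_npar(L, q))
  fit <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter),
                                     factr = tol / .Machine$double.eps))
  if (!is.finite(fit$value)) stop("pseudolikelihood objective is non-finite")
  if (fit$convergence == 1)
    warning("pseudolikelihood optimizer hit the iteration cap")
  model <- plm_unpack(fit$par, L, q)
  raw <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      blk <- zero_sum_gauge_block(coupling_block(model, i, j))
      raw[i, j] <- raw[j, i] <- sqrt(sum(blk^2))
    }
  }
  scores <- block_norm_scores(raw, "PLM", min_separation)
  attr(scores, "converged") <- fit$convergence == 0
  list(model = model, scores = scores)
}

#' Compute a set of covariation score matrices for one alignment
#'
#' Convenience wrapper running the requested engines off a shared frequency
#' model.
#'
#' @param walign a [weight_alignment()] result.
#' @param methods subset of `c("mi", "mip", "mfdca", "psicov", "plm")`.
#' @param pseudocount pseudocount for the MI/PSICOV frequency model
#'   (default 1).
#' @param mfdca_pseudocount pseudocount for the mean-field engine; default
#'   `NULL` means half the total relative mass (`lambda` = sum of sequence
#'   weights), the customary large mean-field pseudocount that keeps the
#'   connected-correlation matrix well conditioned.
#' @param min_separation near-diagonal mask width (default 4).
#' @param ... further arguments passed to [psicov_glasso()] and
#'   [plm_couplings()] (matched by name prefix `psicov_` / `plm_`).
#' @return named list of [score_matrix()] objects in the order requested.
#' @export
coupling_scores <- function(walign,
                            methods = c("mi", "mip", "mfdca", "psicov", "plm"),
                            pseudocount = 1, mfdca_pseudocount = NULL,
                            min_separation = 4L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  dots <- list(...)
  freq <- compute_frequencies(walign, pseudocount)
  out <- list()
  mi <- NULL
  if (any(c("mi", "mip") %in% methods)) mi <- mutual_information(freq, min_separation)
  if ("mi" %in% methods) out$mi <- mi
  if ("mip" %in% methods) out$mip <- apc(mi)
  if ("mfdca" %in% methods) {
    if (is.null(mfdca_pseudocount)) mfdca_pseudocount <- sum(walign$weights)
    out$mfdca <- mfdca(compute_frequencies(walign, mfdca_pseudocount),
                       min_separation)
  }
  if ("psicov" %in% methods) {
    args <- c(list(freq = freq, min_separation = min_separation),
              dots[grepl("^psicov_", names(dots))])
    names(args) <- sub("^psicov_", "", names(args))
    out$psicov <- do.call(psicov_glasso, args)
  }
  if ("plm" %in% methods) {
    args <- c(list(walign = walign, min_separation = min_separation),
              dots[grepl("^plm_", names(dots))])
    names(args) <- sub("^plm_", "", names(args))
    out$plm <- do.call(plm_couplings, args)$scores
  }
  out
}

#' Ranked residue pairs from a score matrix
#'
#' @param sm a [score_matrix()].
#' @return data.frame with columns `i`, `j` (1-based, `i < j`) and `score`,
#'   sorted by score descending; ties broken by lexicographic `(i, j)`.
#' @export
ranked_pairs <- function(sm) {
  L <- sm$L
  ut <- which(upper.tri(sm$scores) & !is.na(sm$scores), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2],
                   score = sm$scores[ut])
  df[order(-df$score, df$i, df$j), , drop = FALSE]
}
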