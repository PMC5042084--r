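# Sequence redundancy weighting and the effective sequence count N_eff.
#
# Alignment depth is measured as the number of clusters obtained by
# single-linkage clustering at 62% pairwise identity -- the same threshold
# used to compile the BLOSUM62 substitution matrix. Per-sequence weights are
# the reciprocal cluster sizes, so the weights sum exactly to N_eff.

#' Pairwise sequence identity
#'
#' Fraction of matching positions over the columns where at least one of the
#' two sequences is non-gap; columns where both are gaps are ignored. Returns
#' 0 when no column qualifies.
#'
#' @param s1,s2 aligned strings of equal length.
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("sequences differ in length")
  a <- strsplit(canonicalize_rows(s1), "")[[1]]
  b <- strsplit(canonicalize_rows(s2), "")[[1]]
  gap <- a == "-" & b == "-"
  denom <- sum(!gap)
  if (denom == 0) return(0)
  sum(a[!gap] == b[!gap]) / denom
}

# 22-state encoding for identity: X stays distinct from the gap (it is a
# residue for identity purposes; only frequency counting folds it into the
# gap state)
encode_for_identity <- function(aln) {
  chars <- c(AA_ALPHABET, "X")
  lookup <- stats::setNames(seq_along(chars), chars)
  m <- matrix(lookup[unlist(strsplit(aln$rows, ""), use.names = FALSE)],
              nrow = aln$N, ncol = aln$L, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

# single-linkage connected components over the identity graph (union-find)
identity_clusters <- function(idmat, threshold) {
  n <- nrow(idmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- which(idmat >= threshold & upper.tri(idmat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), match(roots, unique(roots)))
}

#' Cluster aligned sequences by single-linkage at an identity threshold
#'
#' Two sequences belong to the same cluster iff they are connected by a
#' chain of pairs with identity >= `threshold` (transitive closure).
#'
#' @param aln an [alignment()].
#' @param threshold identity threshold in (0, 1\]; default 0.62.
#' @return list of integer vectors, a partition of `1:N`.
#' @export
cluster_sequences <- function(aln, threshold = 0.62) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  idmat <- identity_matrix_cpp(encode_for_identity(aln),
                               match("-", AA_ALPHABET))
  identity_clusters(idmat, threshold)
}

#' Effective sequence count N_eff
#'
#' The number of clusters at 62% pairwise identity (single linkage).
#'
#' @param aln an [alignment()].
#' @param threshold identity threshold; default 0.62.
#' @return integer >= 1.
#' @export
effective_sequences <- function(aln, threshold = 0.62) {
  length(cluster_sequences(aln, threshold))
}

#' Per-sequence redundancy weights
#'
#' Weight of a sequence = 1 / (size of its cluster), so the weights sum to
#' the cluster count N_eff.
#'
#' @param aln an [alignment()].
#' @param threshold identity threshold; default 0.62.
#' @return numeric vector of length N in (0, 1\].
#' @export
sequence_weights <- function(aln, threshold = 0.62) {
  cl <- cluster_sequences(aln, threshold)
  w <- numeric(aln$N)
  for (members in cl) w[members] <- 1 / length(members)
  w
}

#' Attach redundancy weights and N_eff to an alignment
#'
#' @param aln an [alignment()].
#' @param threshold identity threshold; default 0.62.
#' @return a `weighted_alignment` with fields `alignment`, `weights`,
#'   `neff` and `identity_threshold`.
#' @export
weight_alignment <- function(aln, threshold = 0.62) {
  cl <- cluster_sequences(aln, threshold)
  w <- numeric(aln$N)
  for (members in cl) w[members] <- 1 / length(members)
  structure(list(alignment = aln, weights = w, neff = length(cl),
                 identity_threshold = threshold),
            class = "weighted_alignment")
}

#' @export
print.weighted_alignment <- function(x, ...) {
  cat(sprintf("Weighted alignment: N = %d, L = %d, N_eff = %d (%.0f%% identity clustering)\n",
              x$alignment$N, x$alignment$L, x$neff, 100 * x$identity_threshold))
  invisible(x)
}
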