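# Synthetic protein-family generator: compact self-avoiding chain topologies
# with ground-truth contact maps, Potts models whose couplings live only on
# contact pairs, Gibbs sampling of alignments, and redundancy padding to hit
# a target effective sequence count.

#' Simulation configuration
#'
#' @param L chain length (columns); at least 5.
#' @param n_sequences number of sequences to emit.
#' @param beta coupling strength scaling the contact blocks (default 1.2).
#' @param mutation_rate per-site mutation probability used when padding with
#'   near-duplicate rows for N_eff control (default 0.1; identities of
#'   padded copies to their parent stay well above the 62% clustering
#'   threshold).
#' @param target_neff optional target effective sequence count; when set,
#'   `target_neff` diverse sequences are sampled and the rest of the
#'   alignment is filled with near-duplicates.
#' @param burn_in Gibbs burn-in sweeps (default 100).
#' @param thinning sweeps between retained sequences (default 10).
#' @param seed mandatory integer seed; all stage sub-seeds derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(L, n_sequences, beta = 1.2, mutation_rate = 0.1,
                       target_neff = NULL, burn_in = 100L, thinning = 10L,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(L >= 5, n_sequences >= 1, beta >= 0, mutation_rate >= 0,
            burn_in >= 1, thinning >= 1)
  if (!is.null(target_neff)) {
    stopifnot(target_neff >= 1, target_neff <= n_sequences)
    target_neff <- as.integer(target_neff)
  }
  structure(list(L = as.integer(L), n_sequences = as.integer(n_sequences),
                 beta = beta, mutation_rate = mutation_rate,
                 target_neff = target_neff, burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed)),
            class = "sim_config")
}

# fixed fan-out of the global seed into per-stage sub-seeds (double
# arithmetic: products of large seeds overflow 32-bit integers)
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage * 10007) %% 2147483647)
}

#' Sample a compact self-avoiding chain topology
#'
#' Grows a 3D chain with fixed bond length 3.8 (Calpha-like), excluded
#' volume 4.0 between non-adjacent residues, confined to a sphere whose
#' radius scales as L^(1/3) so the chain collapses and forms long-range
#' contacts. Contacts are residue pairs with `|i-j| >= 4` and distance
#' <= 8 (distance units are read as Angstroms by convention).
#'
#' @param L chain length (>= 5).
#' @param seed integer seed; topologies are deterministic per seed.
#' @param contact_distance contact threshold (default 8).
#' @return a `contact_topology` with fields `L`, `coords` (L x 3),
#'   `contacts` (two-column matrix, `i < j`), `contact_distance`.
#' @export
sample_topology <- function(L, seed, contact_distance = 8) {
  if (L < 5) stop("L must be >= 5")
  bond <- 3.8; excl <- 4.0
  # confinement radius for ~150 cubic-Angstrom per residue packing density,
  # compact enough that chains form long-range contacts
  radius <- max(9, (3 * 150 * L / (4 * pi))^(1/3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, 1L))
  for (attempt in 1:200) {
    coords <- matrix(NA_real_, L, 3)
    coords[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in 1:60) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- coords[i - 1, ] + bond * dir
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2) {
          d2 <- rowSums((coords[1:(i - 2), , drop = FALSE] -
                           matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (min(d2) < excl^2) next
        }
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("failed to grow a self-avoiding chain; try another seed")
  dmat <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(dmat) & dmat <= contact_distance &
                   abs(row(dmat) - col(dmat)) >= 4, arr.ind = TRUE)
  contacts <- unname(cbind(pairs[, 1], pairs[, 2]))
  contacts <- contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
  structure(list(L = as.integer(L), coords = coords, contacts = contacts,
                 contact_distance = contact_distance),
            class = "contact_topology")
}

#' @export
print.contact_topology <- function(x, ...) {
  cat(sprintf("Contact topology: L = %d, %d contacts (<= %.1f A, |i-j| >= 4)\n",
              x$L, nrow(x$contacts), x$contact_distance))
  invisible(x)
}

# save/restore the global RNG state so simulator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build a generative Potts model on a contact topology
#'
#' Couplings `J_ij` are nonzero only for contact pairs: random Gaussian
#' 21 x 21 blocks projected to the zero-sum gauge and scaled by `beta`.
#' Fields are drawn from a fixed background amino-acid composition (gap
#' state down-weighted) with small per-site noise.
#'
#' @param topology a [sample_topology()] result.
#' @param beta coupling strength (>= 0); `beta = 0` gives independent sites.
#' @param seed integer seed.
#' @return a [potts_model()].
#' @export
build_potts <- function(topology, beta, seed) {
  if (beta < 0) stop("beta must be >= 0")
  L <- topology$L; q <- n_states()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, 2L))
  bg <- c(rep(1, q - 1), 0.15)      # near-uniform amino acids, rare gaps
  bg <- bg / sum(bg)
  h <- matrix(log(bg), q, L) + matrix(stats::rnorm(q * L, sd = 0.2), q, L)
  Jm <- matrix(0, L * q, L * q)
  if (nrow(topology$contacts) > 0 && beta > 0) {
    for (k in seq_len(nrow(topology$contacts))) {
      i <- topology$contacts[k, 1]; j <- topology$contacts[k, 2]
      blk <- beta * zero_sum_gauge_block(matrix(stats::rnorm(q * q), q, q))
      ri <- ((i - 1) * q + 1):(i * q); rj <- ((j - 1) * q + 1):(j * q)
      Jm[ri, rj] <- blk
      Jm[rj, ri] <- t(blk)
    }
  }
  potts_model(h, Jm, gauge = "zero_sum")
}

#' Gibbs-sample an alignment from a Potts model
#'
#' Single-site Gibbs sweeps; after `burn_in` sweeps one sequence is kept
#' every `thinning` sweeps. Deterministic per config seed.
#'
#' @param model a [potts_model()].
#' @param config a [sim_config()].
#' @return an [alignment()]; the first (query) row is re-sampled until
#'   gap-free if needed, by taking the first gap-free row as query.
#' @export
gibbs_sample_msa <- function(model, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, 3L))
  msa <- gibbs_sample_cpp(model$h, model$Jm, config$n_sequences,
                          config$burn_in, config$thinning)
  alignment_from_matrix(msa)
}

# integer state matrix -> alignment; the first gap-free row becomes the query
# (gaps in a would-be query are recoded to the most frequent state in the
# column so the query invariant holds)
alignment_from_matrix <- function(msa) {
  q <- n_states()
  N <- nrow(msa); L <- ncol(msa)
  gapfree <- which(rowSums(msa == q) == 0)
  if (length(gapfree) >= 1 && gapfree[1] != 1) {
    msa[c(1, gapfree[1]), ] <- msa[c(gapfree[1], 1), ]
  } else if (length(gapfree) == 0) {
    for (i in which(msa[1, ] == q)) {
      tab <- tabulate(msa[, i], nbins = q)[-q]
      msa[1, i] <- which.max(tab)
    }
  }
  rows <- apply(msa, 1, function(r) paste(AA_ALPHABET[r], collapse = ""))
  alignment(sprintf("seq%d", seq_len(N)), rows)
}

#' Generate a synthetic protein family with known contacts
#'
#' Pipeline: topology -> Potts model -> Gibbs alignment. When
#' `config$target_neff` is set, only `target_neff` diverse sequences are
#' Gibbs-sampled and the alignment is padded to `n_sequences` with
#' near-duplicate rows (per-site mutation at `mutation_rate`), emulating a
#' shallow, redundant family; the achieved N_eff is checked against the
#' target within 10% (a miss produces a warning, not an error).
#'
#' @param config a [sim_config()].
#' @return list with elements `alignment`, `topology`, `model`, `neff`.
#' @export
generate_family <- function(config) {
  topo <- sample_topology(config$L, config$seed)
  model <- build_potts(topo, config$beta, config$seed)
  if (is.null(config$target_neff)) {
    aln <- gibbs_sample_msa(model, config)
  } else {
    # equilibrium sequences of a coupled Potts model can exceed 62%
    # identity, so N_eff of m samples is below m: extend the (deterministic)
    # Gibbs stream until the core reaches the target cluster count, then
    # trim whole clusters so the core N_eff is exact
    target <- config$target_neff
    m <- target
    repeat {
      core_cfg <- config
      core_cfg$n_sequences <- as.integer(m)
      aln <- gibbs_sample_msa(model, core_cfg)
      cl <- cluster_sequences(aln)
      if (length(cl) >= target || m >= config$n_sequences) break
      m <- min(config$n_sequences,
               ceiling(m * (target + 1) / max(length(cl), 1)))
    }
    if (length(cl) > target) {
      has_query <- vapply(cl, function(m_) 1L %in% m_, logical(1))
      keep <- sort(unlist(cl[order(!has_query)][seq_len(target)]))
      aln <- alignment(aln$ids[keep], aln$rows[keep],
                       query_index = match(1L, keep))
    }
  }
  n_core <- aln$N
  if (!is.null(config$target_neff) && config$n_sequences > n_core) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(stage_seed(config$seed, 4L))
    q <- n_states()
    msa <- encode_alignment(aln)
    n_pad <- config$n_sequences - n_core
    pad <- matrix(0L, n_pad, config$L)
    parents <- rep(seq_len(n_core), length.out = n_pad)
    for (k in seq_len(n_pad)) {
      row <- msa[parents[k], ]
      mut <- stats::runif(config$L) < config$mutation_rate
      if (any(mut)) row[mut] <- sample.int(q - 1, sum(mut), replace = TRUE)
      pad[k, ] <- row
    }
    all_rows <- rbind(msa, pad)
    rows <- apply(all_rows, 1, function(r) paste(AA_ALPHABET[r], collapse = ""))
    aln <- alignment(sprintf("seq%d", seq_len(nrow(all_rows))), rows)
  }
  neff <- effective_sequences(aln)
  if (!is.null(config$target_neff) &&
      abs(neff - config$target_neff) > 0.1 * config$target_neff + 1)
    warning(sprintf("achieved N_eff = %d misses target %d by more than 10%%",
                    neff, config$target_neff))
  list(alignment = aln, topology = topo, model = model, neff = neff)
}

#' Ground-truth contact set as a character key vector (internal helper)
#' @noRd
contact_keys <- function(contacts) paste(contacts[, 1], contacts[, 2])
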