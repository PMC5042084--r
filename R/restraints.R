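# Contact restraint energies: convert a contact probability map into
# square-well pair potentials (depth = predicted probability, decay above
# the 8 A contact threshold) split into short-range and long-range classes,
# and score 3D coordinate models against them.

#' Restraint configuration
#'
#' @param p_min minimum predicted probability (PPV) for a pair to become a
#'   restraint (default 0.5).
#' @param d0 contact distance threshold in Angstroms, the square-well edge
#'   (default 8.0; Cbeta-Cbeta, Calpha for glycine).
#' @param decay_sigma decay length scale in Angstroms above `d0`
#'   (default 2.0).
#' @param decay decay functional form above the well: `"gaussian"`
#'   (`exp(-(d-d0)^2 / (2 sigma^2))`, default) or `"exponential"`
#'   (`exp(-(d-d0)/sigma)`); both are continuous at `d0`.
#' @param sr_max_separation largest sequence separation of the short-range
#'   class (default 23); pairs with separation >= 24 are long-range.
#' @return a `restraint_config` list.
#' @export
restraint_config <- function(p_min = 0.5, d0 = 8.0, decay_sigma = 2.0,
                             decay = c("gaussian", "exponential"),
                             sr_max_separation = 23L) {
  decay <- match.arg(decay)
  if (p_min <= 0 || p_min > 1) stop("p_min must be in (0, 1]")
  if (d0 <= 0 || decay_sigma <= 0) stop("d0 and decay_sigma must be positive")
  structure(list(p_min = p_min, d0 = d0, decay_sigma = decay_sigma,
                 decay = decay, sr_max_separation = as.integer(sr_max_separation)),
            class = "restraint_config")
}

#' Build contact restraints from a probability map
#'
#' Keeps pairs with probability >= `p_min` and splits them into short-range
#' (separation 4..`sr_max_separation`) and long-range (separation >
#' `sr_max_separation`) classes; each restraint's weight (well depth) is its
#' predicted probability.
#'
#' @param map a [contact_map()] (or [contact_list()]).
#' @param config a [restraint_config()].
#' @return data.frame with columns `i`, `j`, `weight`, `class`
#'   (`"SR"`/`"LR"`).
#' @export
build_restraints <- function(map, config = restraint_config()) {
  cl <- if (inherits(map, "contact_list")) map else map_to_contact_list(map)
  keep <- cl[cl$probability >= config$p_min, , drop = FALSE]
  sep <- keep$j - keep$i
  data.frame(i = keep$i, j = keep$j, weight = keep$probability,
             class = ifelse(sep <= config$sr_max_separation, "SR", "LR"),
             stringsAsFactors = FALSE)
}

#' Pair restraint energy
#'
#' Square well with decay: `E = -weight` for `distance <= d0`;
#' `E = -weight * exp(-(distance - d0)^2 / (2 decay_sigma^2))` (Gaussian
#' form, default) or `-weight * exp(-(distance - d0)/decay_sigma)`
#' (exponential form) beyond. Continuous at `d0`, tends to 0 at large
#' distance.
#'
#' @param distance Cbeta-Cbeta distance in Angstroms (>= 0); vectorized.
#' @param weight well depth (the predicted contact probability).
#' @param config a [restraint_config()].
#' @return energy (<= 0); vectorized over `distance`.
#' @export
pair_energy <- function(distance, weight, config = restraint_config()) {
  if (any(distance < 0)) stop("distance must be >= 0")
  excess <- pmax(distance - config$d0, 0)
  decay <- switch(config$decay,
    gaussian = exp(-excess^2 / (2 * config$decay_sigma^2)),
    exponential = exp(-excess / config$decay_sigma))
  -weight * decay
}

#' Score a 3D structure against contact restraints
#'
#' Sums the pair energies separately over the short-range and long-range
#' restraint classes.
#'
#' @param coords per-residue coordinates: data.frame or matrix with columns
#'   `resno`, `x`, `y`, `z` (one row per residue, unique indices), e.g. from
#'   [read_structure_coords()].
#' @param restraints a [build_restraints()] result.
#' @param config a [restraint_config()].
#' @return a `restraint_energy` list: `e_sr`, `e_lr`, `total`, and
#'   `per_pair` (the restraint table with `distance` and `energy` columns).
#' @export
score_structure <- function(coords, restraints, config = restraint_config()) {
  coords <- as.data.frame(coords)
  if (anyDuplicated(coords$resno)) stop("duplicate residue indices in coords")
  idx <- match(c(restraints$i, restraints$j), coords$resno)
  if (anyNA(idx)) {
    missing <- unique(c(restraints$i, restraints$j)[is.na(idx)])
    stop("residue(s) missing from coordinates: ", paste(missing, collapse = ", "))
  }
  n <- nrow(restraints)
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[idx[seq_len(n)], , drop = FALSE] -
                       xyz[idx[n + seq_len(n)], , drop = FALSE])^2))
  e <- pair_energy(d, restraints$weight, config)
  per_pair <- cbind(restraints, distance = d, energy = e)
  e_sr <- sum(e[restraints$class == "SR"])
  e_lr <- sum(e[restraints$class == "LR"])
  structure(list(e_sr = e_sr, e_lr = e_lr, total = e_sr + e_lr,
                 per_pair = per_pair),
            class = "restraint_energy")
}

#' @export
print.restraint_energy <- function(x, ...) {
  cat(sprintf("Restraint energy: E_SR-RR = %.3f, E_LR-RR = %.3f, total = %.3f (%d pairs)\n",
              x$e_sr, x$e_lr, x$total, nrow(x$per_pair)))
  invisible(x)
}

#' Read per-residue Cbeta coordinates from a PDB file
#'
#' Uses the first model and first alternate location; takes the Cbeta atom
#' per residue, falling back to Calpha for glycine (or whenever Cbeta is
#' absent). Residues with neither atom cause an error.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default: first chain in file.
#' @return data.frame with columns `resno`, `x`, `y`, `z`.
#' @export
read_structure_coords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt == "" | at$alt == "A", , drop = FALSE]
  resnos <- unique(at$resno)
  rows <- lapply(resnos, function(r) {
    sub <- at[at$resno == r, , drop = FALSE]
    hit <- sub[sub$elety == "CB", , drop = FALSE]
    if (nrow(hit) == 0) hit <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(hit) == 0)
      stop("residue ", r, " has neither CB nor CA atom")
    data.frame(resno = r, x = hit$x[1], y = hit$y[1], z = hit$z[1])
  })
  do.call(rbind, rows)
}

#' Shuffled-coordinate decoy energies
#'
#' Permutes the residue-to-coordinate assignment and rescores, giving a
#' null distribution of restraint energies for a structure.
#'
#' @param coords coordinate table as in [score_structure()].
#' @param restraints restraint table.
#' @param n_decoys number of decoys (default 100).
#' @param seed RNG seed.
#' @param config a [restraint_config()].
#' @return numeric vector of decoy total energies.
#' @export
decoy_energies <- function(coords, restraints, n_decoys = 100, seed = 1,
                           config = restraint_config()) {
  coords <- as.data.frame(coords)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_decoys), function(k) {
    dec <- coords
    dec$resno <- sample(coords$resno)
    score_structure(dec, restraints, config)$total
  }, numeric(1))
}
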