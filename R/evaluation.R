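# CASP-style evaluation: ranked contact lists, top-L/k precision with
# long-range/short-range separation classes, RR file I/O, contact-ranking
# AUC, and the precision-vs-N_eff benchmark harness.

#' Construct a ranked contact list
#'
#' @param i,j 1-based residue indices with `i < j` (no duplicates).
#' @param probability contact probabilities in \[0, 1\].
#' @param L target sequence length.
#' @return a `contact_list`: data.frame sorted by probability descending,
#'   ties broken by lexicographic `(i, j)`, with attribute `L`.
#' @export
contact_list <- function(i, j, probability, L) {
  if (any(j <= i)) stop("contact list requires i < j")
  if (any(probability < 0 | probability > 1))
    stop("probabilities must lie in [0, 1]")
  key <- paste(i, j)
  if (anyDuplicated(key)) stop("duplicate residue pairs in contact list")
  df <- data.frame(i = as.integer(i), j = as.integer(j),
                   probability = probability)
  df <- df[order(-df$probability, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "L") <- as.integer(L)
  class(df) <- c("contact_list", "data.frame")
  df
}

#' Convert a contact probability map to a ranked contact list
#'
#' @param map a [contact_map()].
#' @return a [contact_list()] over all unmasked pairs.
#' @export
map_to_contact_list <- function(map) {
  ut <- which(upper.tri(map$probs) & !is.na(map$probs), arr.ind = TRUE)
  contact_list(ut[, 1], ut[, 2], map$probs[ut], map$L)
}

#' Evaluation configuration
#'
#' @param k_fraction fraction of L predictions scored (default 1/5, the
#'   top-L/5 convention).
#' @param lr_min_separation minimum separation of the long-range class
#'   (default 24, i.e. separation > 23); short-range covers 4..23 so the
#'   two classes partition the eligible range.
#' @param sr_min_separation lower bound of the short-range class (default 4).
#' @return an `eval_config` list.
#' @export
eval_config <- function(k_fraction = 1 / 5, lr_min_separation = 24L,
                        sr_min_separation = 4L) {
  if (k_fraction <= 0 || k_fraction > 1) stop("k_fraction must be in (0, 1]")
  if (lr_min_separation <= 4) stop("lr_min_separation must be > 4")
  structure(list(k_fraction = k_fraction,
                 lr_min_separation = as.integer(lr_min_separation),
                 sr_min_separation = as.integer(sr_min_separation)),
            class = "eval_config")
}

sep_class_filter <- function(df, config, class) {
  sep <- df$j - df$i
  keep <- switch(class,
    lr = sep >= config$lr_min_separation,
    sr = sep >= config$sr_min_separation & sep < config$lr_min_separation,
    all = sep >= config$sr_min_separation)
  df[keep, , drop = FALSE]
}

#' Top-L/k contact precision
#'
#' Filters predictions to a separation class (long-range: separation > 23),
#' takes the top `floor(L * k_fraction)` (at least 1) by probability, and
#' returns `100 * true positives / selected`.
#'
#' @param pred a [contact_list()].
#' @param truth two-column matrix of true contact pairs (`i < j`).
#' @param config an [eval_config()].
#' @param class `"lr"`, `"sr"` or `"all"`.
#' @return precision as a percentage.
#' @export
topk_precision <- function(pred, truth, config = eval_config(),
                           class = c("lr", "sr", "all")) {
  class <- match.arg(class)
  L <- attr(pred, "L")
  if (nrow(truth) > 0 && (max(truth) > L || min(truth) < 1))
    stop("truth pairs out of range for L")
  cand <- sep_class_filter(pred, config, class)
  if (nrow(cand) == 0) stop("no predictions in separation class ", class)
  k <- max(1L, floor(L * config$k_fraction))
  top <- utils::head(cand, k)
  truth_keys <- paste(truth[, 1], truth[, 2])
  100 * sum(paste(top$i, top$j) %in% truth_keys) / nrow(top)
}

#' Contact-ranking AUC of a score matrix
#'
#' Probability that a randomly chosen true contact pair outranks a randomly
#' chosen non-contact pair (rank-sum form), over all unmasked pairs.
#'
#' @param sm a [score_matrix()] (or [contact_map()]; anything with `scores`
#'   or `probs` and `L`).
#' @param topology a [sample_topology()] result supplying the truth.
#' @return AUC in \[0, 1\].
#' @export
contact_auc <- function(sm, topology) {
  m <- if (!is.null(sm$scores)) sm$scores else sm$probs
  ut <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
  s <- m[ut]
  lab <- pair_labels(ut, topology)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) stop("degenerate truth: need both classes")
  r <- rank(s)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Top-L/k precision of a raw coupling score matrix
#'
#' Ranks unmasked pairs by score (score ranks stand in for probabilities)
#' and scores them against the truth like [topk_precision()].
#'
#' @param sm a [score_matrix()].
#' @param truth two-column matrix of true contact pairs.
#' @param config an [eval_config()].
#' @param class separation class (default `"lr"`).
#' @return precision as a percentage.
#' @export
score_topk_precision <- function(sm, truth, config = eval_config(),
                                 class = "lr") {
  rp <- ranked_pairs(sm)  # already sorted, ties lexicographic
  p <- 1 - (seq_len(nrow(rp)) - 1) / nrow(rp)
  cl <- contact_list(rp$i, rp$j, p, sm$L)
  topk_precision(cl, truth, config, class)
}

#' Write a contact list in CASP RR format
#'
#' Emits `PFRMAT RR`, `MODEL 1`, one `i j 0 8 p` line per pair (probability
#' to 3 decimals), then `END`.
#'
#' @param pred a [contact_list()].
#' @param path output path.
#' @export
write_rr <- function(pred, path) {
  lines <- c("PFRMAT RR", "MODEL  1",
             sprintf("%d %d 0 8 %.3f", pred$i, pred$j, pred$probability),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file
#'
#' @param path input path.
#' @param L target length; if missing, inferred as the largest index seen.
#' @return a [contact_list()].
#' @export
read_rr <- function(path, L = NULL) {
  lines <- readLines(path)
  dat <- lines[grepl("^\\s*\\d", lines)]
  if (length(dat) == 0) stop("no contact records in ", path)
  parts <- strsplit(trimws(dat), "\\s+")
  bad <- vapply(parts, length, integer(1)) != 5
  if (any(bad)) stop("malformed RR line(s): ", paste(which(bad), collapse = ", "))
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (any(!is.finite(m))) stop("non-numeric fields in RR records")
  if (any(m[, 2] <= m[, 1])) stop("RR records must satisfy i < j")
  if (is.null(L)) L <- max(m[, 2])
  contact_list(m[, 1], m[, 2], m[, 5], L)
}

#' Benchmark mean precision across N_eff strata
#'
#' For each simulation configuration, generates the family, predicts
#' contacts with the given model, and scores top-L/k precision; results are
#' averaged per N_eff stratum (`target_neff`).
#'
#' @param sim_grid list of [sim_config()]s (>= 2 distinct `target_neff`
#'   strata).
#' @param model a [train_metanet()] model.
#' @param config an [eval_config()].
#' @param class separation class scored (default `"lr"`).
#' @param ... passed to [predict_contacts()].
#' @return data.frame with columns `neff_stratum`, `mean_precision`, `n`,
#'   plus a `per_family` attribute (one row per family, with seeds).
#' @export
benchmark_by_neff <- function(sim_grid, model, config = eval_config(),
                              class = "lr", ...) {
  strata <- vapply(sim_grid, function(cf)
    if (is.null(cf$target_neff)) NA_integer_ else cf$target_neff, integer(1))
  if (length(unique(strata)) < 2) stop("need at least two N_eff strata")
  rows <- lapply(sim_grid, function(cf) {
    fam <- generate_family(cf)
    map <- predict_contacts(fam$alignment, model, ...)
    prec <- topk_precision(map_to_contact_list(map), fam$topology$contacts,
                           config, class)
    data.frame(neff_stratum = cf$target_neff, seed = cf$seed,
               neff_achieved = fam$neff, precision = prec)
  })
  per_family <- do.call(rbind, rows)
  agg <- stats::aggregate(precision ~ neff_stratum, per_family, mean)
  n <- stats::aggregate(precision ~ neff_stratum, per_family, length)
  out <- data.frame(neff_stratum = agg$neff_stratum,
                    mean_precision = agg$precision, n = n$precision)
  out <- out[order(out$neff_stratum), , drop = FALSE]
  attr(out, "per_family") <- per_family
  out
}
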