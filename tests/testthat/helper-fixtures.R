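# Shared fixtures. Heavy objects (trained model, covariation benchmark,
# N_eff-stratified benchmark) are computed once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small alignment with two perfectly correlated two-state columns repeated;
# equal cluster weights give joint f(A,A) = f(C,C) = 1/2 per column pair
correlated_toy_alignment <- function() {
  alignment(paste0("s", 1:4), c("AAAA", "AAAA", "CCCC", "CCCC"))
}

# deterministic small family for quick module tests
small_family <- function(seed = 5, L = 30, n = 400, target_neff = NULL) {
  memoise_fixture(sprintf("fam_%d_%d_%d_%s", seed, L, n,
                          ifelse(is.null(target_neff), "full", target_neff)),
                  function() suppressWarnings(generate_family(
                    sim_config(L = L, n_sequences = n,
                               target_neff = target_neff, seed = seed))))
}

# per-family coupling scores for the default engine set
family_scores <- function(fam, plm_max_iter = 30) {
  wa <- weight_alignment(fam$alignment)
  sc <- suppressWarnings(
    coupling_scores(wa, methods = c("mi", "mip", "mfdca", "psicov", "plm"),
                    plm_max_iter = plm_max_iter))
  list(walign = wa, scores = sc)
}

# ---- heavy fixture 1: covariation AUC at study-scale depth ---------------
# L = 30 columns, 2000 sequences, 10 replicate families
auc_benchmark <- function() {
  memoise_fixture("auc_benchmark", function() {
    rows <- lapply(1:10, function(seed) {
      fam <- generate_family(sim_config(L = 30, n_sequences = 2000,
                                        seed = 100 + seed))
      fs <- family_scores(fam)
      vapply(fs$scores, function(sm) contact_auc(sm, fam$topology), numeric(1))
    })
    do.call(rbind, rows)
  })
}

# ---- heavy fixture 2: trained two-stage meta-predictor -------------------
# 24 training families spanning alignment depths
trained_model <- function() {
  memoise_fixture("trained_model", function() {
    depths <- rep(c(NA, 500, 200, 50, 10, NA), 4)
    fams <- lapply(seq_along(depths), function(k) {
      tn <- if (is.na(depths[k])) NULL else depths[k]
      n_seq <- if (is.null(tn)) 600 else max(600, 3 * tn)
      suppressWarnings(
        generate_family(sim_config(L = 30, n_sequences = n_seq,
                                   target_neff = tn, seed = 200 + k)))
    })
    suppressWarnings(train_metanet(
      fams, feat_config = feature_config(),
      net_config = metanet_config(train_seed = 7L),
      plm_max_iter = 30))
  })
}

# ---- heavy fixture 3: held-out benchmark across N_eff strata -------------
# Topology seeds are shared across strata (paired design): each seed's
# family differs between strata only in alignment depth, which isolates
# the depth effect from topology-to-topology variation.
strata_benchmark <- function() {
  memoise_fixture("strata_benchmark", function() {
    model <- trained_model()
    ec <- eval_config()
    strata <- c(10, 50, 200, 500)
    seeds <- 1:10
    rows <- list()
    for (s in seeds) {
      for (tn in strata) {
        fam <- suppressWarnings(
          generate_family(sim_config(L = 30, n_sequences = max(600, 3 * tn),
                                     target_neff = tn, seed = 300 + s)))
        fs <- family_scores(fam)
        truth <- fam$topology$contacts
        per_method <- vapply(fs$scores, function(sm)
          score_topk_precision(sm, truth, ec, "lr"), numeric(1))
        map <- predict_contacts(fam$alignment, model, scores = fs$scores)
        meta <- topk_precision(map_to_contact_list(map), truth, ec, "lr")
        rows[[length(rows) + 1]] <- data.frame(
          stratum = tn, seed = s, t(per_method), meta = meta)
      }
    }
    do.call(rbind, rows)
  })
}
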