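# End-to-end orchestration: predict from an alignment file to an RR file
# with a reproducibility manifest, and the aggregate-statistics utility for
# per-domain benchmark tables.

#' Predict contacts end to end and write an RR file plus manifest
#'
#' parse -> weight -> covariation -> features -> stage 1 -> stage 2 -> RR.
#' A JSON manifest recording inputs, configuration and per-stage status is
#' written beside the output; reruns with identical inputs give
#' byte-identical RR files.
#'
#' @param msa_path alignment file (FASTA, A3M or flat).
#' @param model_path path to a [write_model()] file.
#' @param out_path output RR path; the manifest goes to
#'   `paste0(out_path, ".manifest.json")`.
#' @param format alignment format passed to [parse_msa()].
#' @return the [contact_list()] written, invisibly.
#' @export
run_predict <- function(msa_path, model_path, out_path, format = "auto") {
  manifest <- list(inputs = list(msa = msa_path, model = model_path),
                   output = out_path,
                   package_version = as.character(utils::packageVersion("metacontact")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      write_manifest(manifest, out_path)
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  if (!file.exists(model_path)) {
    manifest$stages[["load_model"]] <- list(status = "error",
                                            message = "model file not found")
    write_manifest(manifest, out_path)
    stop("stage 'load_model' failed: model file not found: ", model_path)
  }
  model <- run_stage("load_model", read_model(model_path))
  aln <- run_stage("parse", parse_msa(msa_path, format))
  manifest$train_seed <- model$train_seed
  map <- run_stage("predict", predict_contacts(aln, model))
  cl <- run_stage("rank", map_to_contact_list(map))
  run_stage("write_rr", write_rr(cl, out_path))
  write_manifest(manifest, out_path)
  invisible(cl)
}

write_manifest <- function(manifest, out_path) {
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Aggregate statistics over a per-domain benchmark table
#'
#' @param table data.frame with (at least) columns `precision` (top-L/5
#'   long-range precision, percent) and `neff`.
#' @return list with `mean_precision_pct` (arithmetic mean rounded to the
#'   nearest integer percent), `median_neff` (median, fractional values
#'   truncated to integer), and `n_domains`.
#' @export
table_stats <- function(table) {
  if (nrow(table) < 1) stop("empty table")
  list(mean_precision_pct = round(mean(table$precision)),
       median_neff = trunc(stats::median(table$neff)),
       n_domains = nrow(table))
}

#' Per-domain CASP11 contact-prediction results for the CONSIP2 server
#'
#' The published per-domain summary of the server's CASP11 residue-residue
#' contact predictions: domain identifier, domain length, top-L/5 long-range
#' precision (percent) and the effective sequence count of the server's
#' alignment. Packaged so aggregate statistics are computable offline.
#'
#' @return data.frame with columns `domain`, `length`, `precision`, `neff`.
#' @export
casp11_results <- function() {
  path <- system.file("extdata", "casp11_rr_domains.tsv",
                      package = "metacontact")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
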