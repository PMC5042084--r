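# Alignment container, parsers, and the alignment-pipeline decision rules.

#' Amino-acid alphabet used throughout the package
#'
#' Twenty amino acids, the gap character `-`, and the dedicated unknown
#' character `X`. Ambiguity and non-standard codes (`B`, `Z`, `U`, `O`, `J`)
#' are canonicalized to `X` on parsing; `X` is treated as a gap in all
#' frequency counting so the statistical state space stays at 21.
#' @export
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

AMBIGUITY_CODES <- c("B", "Z", "U", "O", "J")
VALID_CHARS <- c(AA_ALPHABET, "X")

#' Construct a multiple sequence alignment object
#'
#' @param ids character vector of sequence identifiers (duplicates permitted).
#' @param rows character vector of aligned sequences, all the same length,
#'   over the 20 amino acids, `-` (gap) and `X` (unknown).
#' @param query_index 1-based index of the query row (default 1). The query
#'   row must contain no gaps.
#' @return An object of class `msa_alignment` with fields `ids`, `rows`,
#'   `L` (columns), `N` (rows) and `query_index`.
#' @export
alignment <- function(ids, rows, query_index = 1L) {
  if (length(rows) < 1L) stop("alignment must contain at least one sequence")
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  rows <- canonicalize_rows(unname(rows))
  ids <- unname(ids)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: rows have differing lengths after canonicalization")
  L <- lens[1]
  if (L < 1L) stop("alignment has zero columns")
  bad <- !vapply(strsplit(rows, ""), function(ch) all(ch %in% VALID_CHARS), logical(1))
  if (any(bad))
    stop("invalid characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  if (grepl("-", rows[query_index], fixed = TRUE))
    stop("query row must not contain gap characters")
  structure(
    list(ids = as.character(ids), rows = rows, L = as.integer(L),
         N = length(rows), query_index = as.integer(query_index)),
    class = "msa_alignment"
  )
}

canonicalize_rows <- function(rows) {
  rows <- toupper(rows)
  chartr(paste(AMBIGUITY_CODES, collapse = ""),
         strrep("X", length(AMBIGUITY_CODES)), rows)
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n", x$N, x$L))
  cat(sprintf("  query: %s\n", x$ids[x$query_index]))
  invisible(x)
}

#' Parse a multiple sequence alignment
#'
#' Reads FASTA, A3M or flat (one raw aligned sequence per line, query first)
#' alignments. For A3M, lowercase characters mark insertions relative to the
#' query and are deleted so every row matches the query length. All
#' characters are uppercased and ambiguity codes mapped to `X`.
#'
#' @param path path to the alignment file.
#' @param format one of `"auto"`, `"fasta"`, `"a3m"`, `"flat"`. `"auto"`
#'   guesses from the file extension (`.a3m` -> a3m, `.fa`/`.fasta`/`.mfa`
#'   -> fasta, otherwise flat).
#' @return an [alignment()] object; the first record is the query.
#' @export
parse_msa <- function(path, format = c("auto", "fasta", "a3m", "flat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "a3m") "a3m"
      else if (ext %in% c("fa", "fasta", "mfa", "afa")) "fasta"
      else "flat"
  }
  if (format == "flat") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) == 0L) stop("empty alignment file: ", path)
    return(alignment(sprintf("seq%d", seq_along(rows)), trimws(rows)))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  rows <- as.character(seqs)
  ids <- sub("\\s.*$", "", names(seqs))
  if (format == "a3m") rows <- gsub("[a-z.]", "", rows)
  rows <- gsub("\\.", "-", rows)
  alignment(ids, rows)
}

#' Write an alignment to disk
#'
#' @param aln an [alignment()] object.
#' @param path output path.
#' @param format `"fasta"` or `"flat"` (one raw sequence per line).
#' @export
write_msa <- function(aln, path, format = c("fasta", "flat")) {
  format <- match.arg(format)
  if (format == "flat") {
    writeLines(aln$rows, path)
  } else {
    x <- Biostrings::BStringSet(aln$rows)
    names(x) <- aln$ids
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Alignment-pipeline parameter record
#'
#' Records the parameters of the hybrid homology-search protocol (HHblits
#' against a clustered database, supplemented by jackHMMer when the first
#' alignment is shallow). The external tools themselves are not executed;
#' the record makes the branch decision machine-checkable.
#'
#' @param hhblits_evalue HHblits E-value threshold (default `1e-3`).
#' @param hhblits_coverage_pct HHblits minimum coverage percent (default 50).
#' @param hhblits_iterations HHblits iterations (default 3).
#' @param jackhmmer_evalue jackHMMer E-value threshold (default 10).
#' @param jackhmmer_iterations jackHMMer iterations (default 3).
#' @param depth_threshold sequence count below which the jackHMMer
#'   supplementation branch is taken (default 2000).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(hhblits_evalue = 1e-3, hhblits_coverage_pct = 50,
                            hhblits_iterations = 3L, jackhmmer_evalue = 10,
                            jackhmmer_iterations = 3L, depth_threshold = 2000L) {
  vals <- c(hhblits_evalue, hhblits_coverage_pct, hhblits_iterations,
            jackhmmer_evalue, jackhmmer_iterations, depth_threshold)
  if (any(vals <= 0)) stop("all pipeline parameters must be positive")
  structure(list(hhblits_evalue = hhblits_evalue,
                 hhblits_coverage_pct = hhblits_coverage_pct,
                 hhblits_iterations = as.integer(hhblits_iterations),
                 jackhmmer_evalue = jackhmmer_evalue,
                 jackhmmer_iterations = as.integer(jackhmmer_iterations),
                 depth_threshold = as.integer(depth_threshold)),
            class = "pipeline_config")
}

#' Should the alignment be supplemented with a second search?
#'
#' TRUE iff the alignment has strictly fewer sequences than the configured
#' depth threshold (default: fewer than 2000 sequences).
#'
#' @param aln an [alignment()].
#' @param config a [pipeline_config()].
#' @return logical.
#' @export
needs_supplement <- function(aln, config = pipeline_config()) {
  aln$N < config$depth_threshold
}

#' Select the deeper of two alignments for the same query
#'
#' Returns the alignment with more sequences; ties go to the first argument
#' (the primary-database branch). Errors if the two queries differ.
#'
#' @param a,b [alignment()] objects sharing the same query sequence.
#' @return one of `a`, `b`.
#' @export
select_deeper_alignment <- function(a, b) {
  if (a$rows[a$query_index] != b$rows[b$query_index])
    stop("alignments have different query sequences")
  if (b$N > a$N) b else a
}

#' Encode an alignment as an integer state matrix
#'
#' States 1..21 with 21 = gap; the unknown character `X` is encoded as gap
#' so all downstream statistics run over 21 states.
#'
#' @param aln an [alignment()].
#' @return integer matrix, N rows x L columns.
#' @export
encode_alignment <- function(aln) {
  q <- length(AA_ALPHABET)
  lookup <- stats::setNames(seq_len(q), AA_ALPHABET)
  lookup["X"] <- q  # unknowns counted as gap
  m <- matrix(lookup[unlist(strsplit(aln$rows, ""), use.names = FALSE)],
              nrow = aln$N, ncol = aln$L, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Number of states in the encoded alphabet (20 amino acids + gap)
#' @export
n_states <- function() length(AA_ALPHABET)
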