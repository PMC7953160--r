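#' Read BLAST tabular (outfmt 6) protein similarity hits
#'
#' Reads the standard 12-column BLAST tabular format, optionally followed by
#' `qlen` and `slen` columns. Query/subject coverage is computed as alignment
#' length divided by the full protein length when `qlen`/`slen` are present;
#' otherwise the file must carry precomputed `qcovs`/`scovs` columns.
#'
#' @param path path to a tab-separated BLAST hit table without header.
#' @param has_lengths logical; if `TRUE` (default) columns 13 and 14 are
#'   `qlen` and `slen` in residues.
#' @return a `data.frame` of similarity edges with columns `query_id`,
#'   `subject_id`, `identity_pct`, `evalue`, `bitscore`,
#'   `query_coverage_pct`, `subject_coverage_pct`.
#' @export
read_blast_tab <- function(path, has_lengths = TRUE) {
  cols <- c("query_id", "subject_id", "identity_pct", "aln_len", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (has_lengths) {
    if (ncol(df) < 14L)
      stop("expected 14 columns (outfmt 6 + qlen,slen), got ", ncol(df))
    names(df)[1:14] <- c(cols, "qlen", "slen")
    df$query_coverage_pct <- 100 * df$aln_len / df$qlen
    df$subject_coverage_pct <- 100 * df$aln_len / df$slen
  } else {
    if (ncol(df) < 14L)
      stop("expected 14 columns (outfmt 6 + qcovs,scovs), got ", ncol(df))
    names(df)[1:14] <- c(cols, "query_coverage_pct", "subject_coverage_pct")
  }
  df[, c("query_id", "subject_id", "identity_pct", "evalue", "bitscore",
         "query_coverage_pct", "subject_coverage_pct")]
}

#' Filter pairwise similarity edges
#'
#' Applies the strict homology filters used to admit a pairwise protein hit
#' into the family graph: E-value strictly below `max_evalue`, both query and
#' subject coverage strictly above `min_coverage_pct`, and alignment identity
#' strictly above `min_identity_pct`. Self-hits are dropped, and for each
#' unordered gene pair only the highest-bitscore record is kept.
#'
#' @param edges data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `identity_pct`, `query_coverage_pct`, `subject_coverage_pct`, `bitscore`.
#' @param max_evalue keep hits with `evalue < max_evalue` (default `1e-5`).
#' @param min_coverage_pct keep hits with both coverages `>` this (default 75).
#' @param min_identity_pct keep hits with identity `>` this (default 50).
#' @return the filtered, deduplicated edge data.frame.
#' @export
filter_similarity_edges <- function(edges, max_evalue = 1e-5,
                                    min_coverage_pct = 75,
                                    min_identity_pct = 50) {
  req <- c("query_id", "subject_id", "evalue", "identity_pct",
           "query_coverage_pct", "subject_coverage_pct", "bitscore")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("edges missing columns: ", paste(miss, collapse = ", "))
  for (col in c("identity_pct", "query_coverage_pct", "subject_coverage_pct")) {
    bad <- which(edges[[col]] < 0 | edges[[col]] > 100)
    if (length(bad))
      stop(sprintf("%s outside [0,100] for edge %s -> %s (row %d)", col,
                   edges$query_id[bad[1]], edges$subject_id[bad[1]], bad[1]))
  }
  if (any(edges$evalue < 0)) stop("negative E-value in edges")

  keep <- edges$query_id != edges$subject_id &
    edges$evalue < max_evalue &
    edges$query_coverage_pct > min_coverage_pct &
    edges$subject_coverage_pct > min_coverage_pct &
    edges$identity_pct > min_identity_pct
  out <- edges[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)

  ## unordered pair key; keep best-bitscore direction
  key <- ifelse(out$query_id < out$subject_id,
                paste(out$query_id, out$subject_id, sep = "\r"),
                paste(out$subject_id, out$query_id, sep = "\r"))
  ord <- order(key, -out$bitscore)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
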