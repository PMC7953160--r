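#' Hypergeometric term over-representation test
#'
#' For each term with at least one hit in the gene set, computes the exact
#' upper-tail hypergeometric probability of seeing that many or more hits
#' in a random set of the same size drawn from the background:
#' `P(X >= k)` with `k` hits in the set of size `n`, `K` term genes in the
#' background of size `N`. No multiple-testing correction is applied by
#' default; Benjamini-Hochberg adjusted values are added with
#' `bh = TRUE`.
#'
#' @param gene_set character vector, subset of `background`.
#' @param term_map data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_label`.
#' @param background character vector of all eligible genes.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param bh also compute BH-adjusted p-values (default `FALSE`).
#' @return data.frame `term_id`, `term_label`, `k`, `n`, `K`, `N`,
#'   `p_value`, `significant` (and `p_adjusted` when `bh`), sorted by
#'   ascending p.
#' @export
hypergeometric_enrichment <- function(gene_set, term_map, background,
                                      alpha = 0.05, bh = FALSE) {
  gene_set <- unique(gene_set)
  background <- unique(background)
  outside <- setdiff(gene_set, background)
  if (length(outside))
    stop("genes in set missing from background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  tm <- unique(tm[, intersect(c("gene_id", "term_id", "term_label"),
                              names(tm)), drop = FALSE])
  N <- length(background)
  n <- length(gene_set)
  k_by_term <- table(tm$term_id[tm$gene_id %in% gene_set])
  K_by_term <- table(tm$term_id)
  terms <- names(k_by_term)
  if (!length(terms))
    return(data.frame(term_id = character(0), term_label = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      significant = logical(0)))
  k <- as.integer(k_by_term[terms])
  K <- as.integer(K_by_term[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  labels <- if ("term_label" %in% names(tm))
    tm$term_label[match(terms, tm$term_id)] else terms
  out <- data.frame(term_id = terms, term_label = labels, k = k, n = n,
                    K = K, N = N, p_value = p, significant = p < alpha,
                    stringsAsFactors = FALSE)
  if (bh) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  }
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Per-cluster term enrichment summary
#'
#' Runs one over-representation test per trajectory cluster, with the gene
#' set taken as the union of member genes of the cluster's families.
#'
#' @param clustering a [cluster_trajectories()] result (or any named
#'   integer vector family id -> cluster).
#' @param families family table mapping families to genes.
#' @param term_map gene -> term data.frame as in
#'   [hypergeometric_enrichment()].
#' @param background background gene set; default all genes in `families`.
#' @param alpha significance threshold (default 0.05).
#' @param bh Benjamini-Hochberg flag, passed through.
#' @return data.frame keyed (cluster, term) with the per-test columns;
#'   only significant terms are returned when `significant_only`.
#' @param significant_only keep only rows with `significant == TRUE`
#'   (default `FALSE`).
#' @export
summarize_cluster_terms <- function(clustering, families, term_map,
                                    background = NULL, alpha = 0.05,
                                    bh = FALSE, significant_only = FALSE) {
  assign <- if (inherits(clustering, "trajectory_clustering"))
    clustering$assignments else clustering
  if (is.null(background)) background <- unique(families$gene_id)
  res <- list()
  for (cl in sort(unique(assign))) {
    fams <- names(assign)[assign == cl]
    genes <- intersect(unique(families$gene_id[families$family_id %in% fams]),
                       background)
    if (!length(genes)) next
    e <- hypergeometric_enrichment(genes, term_map, background,
                                   alpha = alpha, bh = bh)
    if (nrow(e)) {
      e <- cbind(cluster = cl, e)
      res[[as.character(cl)]] <- e
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cluster = integer(0), term_id = character(0),
               term_label = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_value = numeric(0),
               significant = logical(0))
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
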