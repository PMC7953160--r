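## Markov clustering (MCL) on a weighted undirected graph.
##
## Plain dense-matrix implementation of the classic flow-simulation
## algorithm: alternate expansion (matrix squaring) and inflation
## (entry-wise power followed by column normalization) until the matrix
## stops changing, then read clusters off the limiting matrix. Suitable for
## the graph sizes a family analysis produces per connected component.

#' Markov clustering of a weighted adjacency matrix
#'
#' @param adj symmetric non-negative adjacency matrix with dimnames.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param prune entries below this are zeroed after each inflation
#'   (default `1e-5`).
#' @param tol convergence threshold on the maximum absolute column change
#'   (default `1e-8`).
#' @param max_iter iteration cap (default 100).
#' @param add_self_loops add a self-loop per node equal to its maximum
#'   incident weight (1 for isolated nodes), the usual MCL regularization.
#' @return integer vector of cluster labels named by node.
#' @export
mcl_cluster <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                        tol = 1e-8, max_iter = 100L, add_self_loops = TRUE) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (is.null(rownames(adj))) {
    rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  }
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  if (any(adj < 0)) stop("adjacency weights must be non-negative")
  M <- (adj + t(adj)) / 2
  if (add_self_loops) {
    loops <- apply(M, 1L, max)
    diag(M) <- pmax(loops, 1)
  }
  ## column-stochastic start
  M <- sweep(M, 2L, pmax(colSums(M), .Machine$double.eps), "/")
  for (iter in seq_len(max_iter)) {
    prev <- M
    ## expansion
    E <- M
    for (p in seq_len(expansion - 1L)) E <- E %*% M
    ## inflation + pruning + renormalization
    E <- E ^ inflation
    E[E < prune] <- 0
    cs <- colSums(E)
    dead <- cs <= 0
    if (any(dead)) {  # restore dead columns as self-attractors
      E[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M <- sweep(E, 2L, cs, "/")
    if (max(abs(M - prev)) < tol) break
  }
  ## clusters: connected components of the support of the limit matrix;
  ## attractor overlap (a node drawn by two attractor systems) merges them,
  ## so labels are deterministic; relabel by lowest member node name.
  supp <- (M > prune) | (t(M) > prune)
  g <- igraph::graph_from_adjacency_matrix(supp * 1, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  names(comp) <- rownames(adj)
  relabel_by_lowest(comp)
}

## Deterministic relabelling: clusters numbered by the lexicographically
## smallest member name.
relabel_by_lowest <- function(membership) {
  reps <- tapply(names(membership), membership, min)
  new_id <- rank(reps, ties.method = "first")
  out <- as.integer(new_id[as.character(membership)])
  names(out) <- names(membership)
  out
}
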