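## Independent reference implementations used to cross-check the package.
## These deliberately take different code paths from the package internals.

## Brute-force Markov clustering: explicit loop-based matrix iteration to
## convergence, clusters read off row-wise from attractor rows.
mcl_oracle <- function(adj, inflation = 2, max_iter = 200, tol = 1e-8,
                       prune = 1e-5) {
  n <- nrow(adj)
  M <- (adj + t(adj)) / 2
  loops <- numeric(n)
  for (i in seq_len(n)) loops[i] <- max(M[i, ], 1)
  diag(M) <- loops
  norm_cols <- function(A) {
    for (j in seq_len(ncol(A))) {
      s <- sum(A[, j])
      if (s > 0) A[, j] <- A[, j] / s else A[j, j] <- 1
    }
    A
  }
  M <- norm_cols(M)
  for (it in seq_len(max_iter)) {
    old <- M
    M <- M %*% M            # expansion
    M <- M ^ inflation      # inflation
    M[M < prune] <- 0
    M <- norm_cols(M)
    if (max(abs(M - old)) < tol) break
  }
  ## same-cluster relation from the limit support, symmetrized
  related <- (M > prune) | (t(M) > prune)
  diag(related) <- TRUE
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    cl <- cl + 1L
    frontier <- i
    while (length(frontier)) {
      labels[frontier] <- cl
      nxt <- which(apply(related[frontier, , drop = FALSE], 2, any))
      frontier <- nxt[is.na(labels[nxt])]
    }
  }
  names(labels) <- rownames(adj)
  labels
}

## Monte-Carlo oracle for the posterior fold-change statistic: direct
## rgamma sampling (package uses inverse-CDF coupling instead).
gfold_oracle <- function(count_a, lib_a, count_b, lib_b,
                         credibility = 0.01, n = 1e6, seed = 99) {
  set.seed(seed)
  la <- rgamma(n, shape = count_a + 1, rate = lib_a)
  lb <- rgamma(n, shape = count_b + 1, rate = lib_b)
  d <- log2(la / lb)
  qlo <- unname(quantile(d, credibility))
  qhi <- unname(quantile(d, 1 - credibility))
  if (qlo > 0) qlo else if (qhi < 0) qhi else 0
}

## Exact upper-tail hypergeometric probability by direct enumeration of
## overlap configurations.
hyper_oracle <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Map built families to per-gene partition labels, aligned to a gene order.
partition_of <- function(families, gene_ids) {
  families$family_id[match(gene_ids, families$gene_id)]
}

## Random weighted undirected graph on n nodes as an adjacency matrix.
random_adj <- function(n, p_edge = 0.25, wmin = 1, wmax = 10) {
  A <- matrix(0, n, n, dimnames = list(paste0("g", seq_len(n)),
                                       paste0("g", seq_len(n))))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) A[i, j] <- A[j, i] <- runif(1, wmin, wmax)
  }
  A
}

## Small gene-table fixture builder.
make_genes <- function(ids, species = "spA", chrom = "c1", start = NULL,
                       len = 1200, strand = "+", annotation = "") {
  n <- length(ids)
  if (is.null(start)) start <- seq(0, by = 5000, length.out = n)
  gene_table(data.frame(
    gene_id = ids, species_id = rep_len(species, n),
    chromosome = rep_len(chrom, n), start = start,
    end = start + rep_len(len, n), strand = rep_len(strand, n),
    annotation = rep_len(annotation, n), stringsAsFactors = FALSE))
}

## Similarity-edge fixture builder (passes default filters).
make_edges <- function(pairs, bitscore = 500, evalue = 1e-20,
                       identity = 80, cov = 90) {
  data.frame(query_id = pairs[, 1], subject_id = pairs[, 2],
             evalue = rep_len(evalue, nrow(pairs)),
             identity_pct = rep_len(identity, nrow(pairs)),
             query_coverage_pct = rep_len(cov, nrow(pairs)),
             subject_coverage_pct = rep_len(cov, nrow(pairs)),
             bitscore = rep_len(bitscore, nrow(pairs)),
             stringsAsFactors = FALSE)
}

clique_pairs <- function(ids) t(combn(ids, 2))
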