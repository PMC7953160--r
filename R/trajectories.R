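#' Fold-change trajectories against a reference time point
#'
#' For every family and species, computes the uncertainty-penalized log2
#' fold change of each later time point versus the reference time point
#' (on family-summed counts), together with the up/down/unchanged call.
#' Seeds for the per-comparison Monte Carlo are derived deterministically
#' from `seed` and the comparison's position in sorted order, so the result
#' does not depend on input row order.
#'
#' @param profiles family expression table from
#'   [aggregate_family_expression()].
#' @param reference_h reference time point in hours (default 1).
#' @param credibility,n_draws passed to [gfold_statistic()].
#' @param seed master seed.
#' @return data.frame `family_id`, `species_id`, `timepoint_h`, `gfold`,
#'   `raw_log2fc`, `call`, with the reference time point recorded in
#'   attribute `reference_h`.
#' @export
build_trajectories <- function(profiles, reference_h = 1,
                               credibility = 0.01, n_draws = 10000L,
                               seed = 17L) {
  key <- paste(profiles$family_id, profiles$species_id, sep = "\r")
  has_ref <- tapply(profiles$timepoint_h == reference_h, key, any)
  if (!all(has_ref)) {
    bad <- sub("\r.*", "", names(has_ref)[!has_ref])
    stop("reference time point ", reference_h, " h missing for families: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  later <- profiles[profiles$timepoint_h != reference_h, , drop = FALSE]
  later <- later[order(later$family_id, later$species_id, later$timepoint_h), ]
  ref <- profiles[profiles$timepoint_h == reference_h, , drop = FALSE]
  rkey <- paste(ref$family_id, ref$species_id, sep = "\r")
  idx <- match(paste(later$family_id, later$species_id, sep = "\r"), rkey)

  n <- nrow(later)
  gf <- numeric(n); raw <- numeric(n)
  for (i in seq_len(n)) {
    st <- gfold_statistic(later$count_sum[i], later$library_size[i],
                          ref$count_sum[idx[i]], ref$library_size[idx[i]],
                          credibility = credibility, n_draws = n_draws,
                          seed = derive_seed(seed, i))
    gf[i] <- st$gfold; raw[i] <- st$raw_log2fc
  }
  out <- data.frame(family_id = later$family_id,
                    species_id = later$species_id,
                    timepoint_h = later$timepoint_h,
                    gfold = gf, raw_log2fc = raw, call = call_de(gf),
                    stringsAsFactors = FALSE)
  attr(out, "reference_h") <- reference_h
  out
}

#' Families differential at one or more time points
#'
#' @param trajectories output of [build_trajectories()] (possibly several
#'   species' worth).
#' @return character vector of family ids with at least one nonzero call
#'   in any species.
#' @export
differential_families <- function(trajectories) {
  hit <- tapply(trajectories$call != 0L, trajectories$family_id, any)
  sort(names(hit)[hit])
}

#' Cross-species trajectory feature matrix
#'
#' One row per family shared by both species: the species-A fold-change
#' vector followed by the species-B vector, time points in ascending order.
#' Only families differential in at least one entry are retained when
#' `differential_only = TRUE`.
#'
#' @param trajectories output of [build_trajectories()].
#' @param species_a,species_b the two species, in feature order.
#' @param differential_only keep families with >= 1 nonzero call (default
#'   `TRUE`).
#' @return numeric matrix, rownames = family ids, columns named
#'   `<species>_<time>h`.
#' @export
trajectory_features <- function(trajectories, species_a, species_b,
                                differential_only = TRUE) {
  tps <- sort(unique(trajectories$timepoint_h))
  sub <- trajectories[trajectories$species_id %in% c(species_a, species_b), ]
  shared <- intersect(
    unique(sub$family_id[sub$species_id == species_a]),
    unique(sub$family_id[sub$species_id == species_b]))
  cols <- c(paste0(species_a, "_", tps, "h"), paste0(species_b, "_", tps, "h"))
  mat <- matrix(NA_real_, length(shared), length(cols),
                dimnames = list(sort(shared), cols))
  for (sp in c(species_a, species_b)) {
    for (j in seq_along(tps)) {
      rows <- sub$species_id == sp & sub$timepoint_h == tps[j]
      cn <- paste0(sp, "_", tps[j], "h")
      v <- sub$gfold[rows]
      names(v) <- sub$family_id[rows]
      mat[, cn] <- v[rownames(mat)]
    }
  }
  if (anyNA(mat)) stop("incomplete trajectories for shared families")
  if (differential_only) {
    calls <- sub$call != 0L
    hit <- tapply(calls, sub$family_id, any)
    mat <- mat[rownames(mat) %in% names(hit)[hit], , drop = FALSE]
  }
  mat
}

#' K-means clustering of fold-change trajectories
#'
#' Lloyd iterations with k-means++ seeding on squared Euclidean distance,
#' repeated `restarts` times; the lowest-inertia run wins. Clusters that
#' empty out during an iteration are re-seeded from the point farthest from
#' its assigned centroid. Deterministic given `seed`.
#'
#' @param features numeric matrix (families x features), e.g. from
#'   [trajectory_features()].
#' @param k number of clusters (default 12).
#' @param seed RNG seed.
#' @param restarts independent restarts (default 25).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return object of class `trajectory_clustering`: list with
#'   `assignments` (named integer vector), `centroids` (k x p matrix),
#'   `inertia`, `inertia_trace` (per-iteration inertia of the winning
#'   run), `k`.
#' @export
cluster_trajectories <- function(features, k = 12L, seed = 17L,
                                 restarts = 25L, max_iter = 100L) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite features")
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds number of families (", n, ")")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, r),
                     kmeans_lloyd(features, k, max_iter))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(k = k,
                 assignments = stats::setNames(best$assign, rownames(features)),
                 centroids = best$centroids,
                 inertia = best$inertia,
                 inertia_trace = best$trace),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  sizes <- tabulate(x$assignments, nbins = x$k)
  cat(sprintf("trajectory_clustering: k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$assignments), x$inertia))
  cat("cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

## One k-means run: k-means++ init then Lloyd updates. Uses the current
## RNG stream (callers wrap in with_seed).
kmeans_lloyd <- function(x, k, max_iter) {
  n <- nrow(x)
  ## k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      pick <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
    }
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  assign <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dist2 <- dist_to_centers(x, centers)
    assign_new <- max.col(-dist2, ties.method = "first")
    ## re-seed empty clusters from the farthest point; when every point
    ## already sits on its centroid there is nothing to gain and the
    ## cluster is left empty (degenerate identical-input case)
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        cur <- dist2[cbind(seq_len(n), assign_new)]
        if (max(cur) <= 0) next
        far <- which.max(cur)
        centers[j, ] <- x[far, ]
        assign_new[far] <- j
        dist2 <- dist_to_centers(x, centers)
      }
    }
    inertia <- sum(dist2[cbind(seq_len(n), assign_new)])
    trace <- c(trace, inertia)
    converged <- identical(assign_new, assign)
    assign <- assign_new
    for (j in seq_len(k))
      if (any(assign == j))
        centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    if (converged) break
  }
  dist2 <- dist_to_centers(x, centers)
  inertia <- sum(dist2[cbind(seq_len(n), assign)])
  trace <- c(trace, inertia)
  list(assign = assign, centroids = centers, inertia = inertia, trace = trace)
}

dist_to_centers <- function(x, centers) {
  ## squared Euclidean distances, n x k
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}
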