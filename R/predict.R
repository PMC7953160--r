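#' Co-expression function transfer for species-specific families
#'
#' Guilt-by-association annotation: the Pearson correlation between a
#' species-specific family's expression profile and the profile of every
#' annotated gene is computed across the shared time grid; if the best
#' correlation exceeds `r_threshold` the best gene's annotation becomes the
#' candidate function of the family. Ties at the maximum go to the
#' lexicographically smallest gene id. Zero-variance profiles on either
#' side are skipped.
#'
#' @param kms_profiles numeric matrix, time points x families (FPKM).
#' @param annotated_profiles numeric matrix, time points x genes (FPKM),
#'   same rownames (time points) in the same order as `kms_profiles`.
#' @param annotations named character vector gene id -> functional label.
#' @param r_threshold minimum correlation for a prediction (default 0.8).
#' @param log_transform correlate `log2(FPKM + 1)` instead of raw FPKM
#'   (default `FALSE`).
#' @return data.frame `kms_family_id`, `predicted_gene_id`, `r`,
#'   `candidate_function`; families without a passing candidate carry
#'   `NA` in the last three columns.
#' @export
predict_function <- function(kms_profiles, annotated_profiles, annotations,
                             r_threshold = 0.8, log_transform = FALSE) {
  kms_profiles <- as.matrix(kms_profiles)
  annotated_profiles <- as.matrix(annotated_profiles)
  if (nrow(kms_profiles) != nrow(annotated_profiles) ||
      !identical(rownames(kms_profiles), rownames(annotated_profiles)))
    stop("mismatched time grids between family and gene profiles")
  if (log_transform) {
    kms_profiles <- log2(kms_profiles + 1)
    annotated_profiles <- log2(annotated_profiles + 1)
  }
  keep_gene <- apply(annotated_profiles, 2L, stats::sd) > 0
  if (!all(keep_gene))
    msg("%d annotated genes with zero-variance profiles skipped",
        sum(!keep_gene))
  ap <- annotated_profiles[, keep_gene, drop = FALSE]
  ## order candidate columns so which.max tie-breaks to the smallest id
  ap <- ap[, order(colnames(ap)), drop = FALSE]

  fams <- colnames(kms_profiles)
  out <- data.frame(kms_family_id = fams,
                    predicted_gene_id = NA_character_,
                    r = NA_real_, candidate_function = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    prof <- kms_profiles[, i]
    if (stats::sd(prof) == 0) {
      msg("family %s has a zero-variance profile; skipped", fams[i])
      next
    }
    r <- as.vector(stats::cor(prof, ap))
    best <- which.max(r)
    if (length(best) && r[best] > r_threshold) {
      gid <- colnames(ap)[best]
      out$predicted_gene_id[i] <- gid
      out$r[i] <- r[best]
      out$candidate_function[i] <- unname(annotations[gid])
    }
  }
  out
}
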