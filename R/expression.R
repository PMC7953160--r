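#' Assemble a count matrix object
#'
#' Bundles a gene-by-sample integer count matrix with its sample sheet,
#' gene lengths and library sizes. Library size is the total number of
#' mapped reads in the sample and may exceed the column sum of the table.
#'
#' @param counts integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data.frame with columns `sample`, `species_id`,
#'   `timepoint_h`, `replicate`, `library_size`.
#' @param gene_length_bp named numeric vector of transcript lengths in bp.
#' @return a list of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, gene_length_bp) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample", "species_id", "timepoint_h", "replicate", "library_size")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(colnames(counts), samples$sample))
    stop("count matrix columns and sample sheet disagree")
  counts <- counts[, samples$sample, drop = FALSE]
  miss_len <- setdiff(rownames(counts), names(gene_length_bp))
  if (length(miss_len))
    stop("gene length missing for: ", paste(utils::head(miss_len, 5), collapse = ", "))
  if (any(gene_length_bp[rownames(counts)] <= 0)) stop("non-positive gene length")
  if (any(samples$library_size <= 0)) stop("non-positive library size")
  structure(list(counts = counts, samples = as.data.frame(samples),
                 gene_length_bp = gene_length_bp[rownames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d species, %d time points)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$species_id)),
              length(unique(x$samples$timepoint_h))))
  invisible(x)
}

#' Compute FPKM from raw counts
#'
#' FPKM = count * 1e9 / (gene_length_bp * library_size): fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param cm a [count_matrix()].
#' @return numeric gene-by-sample matrix of FPKM values.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- cm$samples$library_size
  len <- cm$gene_length_bp
  fpkm <- sweep(cm$counts, 1L, len, "/")
  fpkm <- sweep(fpkm, 2L, lib, "/") * 1e9
  fpkm
}

#' Aggregate expression to the family level
#'
#' Family expression at each time point is the sum of member-gene FPKM
#' values; family counts are the sum of member-gene raw counts (used by the
#' fold-change statistic, which needs counts). Replicates at the same time
#' point are averaged for FPKM and summed (with their library sizes) for
#' counts. Family members absent from the count matrix contribute zero.
#'
#' @param fpkm matrix from [compute_fpkm()].
#' @param cm the [count_matrix()] the FPKM came from.
#' @param families family table (`family_id`, `species_id`, `gene_id`).
#' @return data.frame with one row per (family, species, timepoint):
#'   `family_id`, `species_id`, `timepoint_h`, `fpkm_sum`, `count_sum`,
#'   `library_size`.
#' @export
aggregate_family_expression <- function(fpkm, cm, families) {
  stopifnot(inherits(cm, "count_matrix"))
  ss <- cm$samples
  measured <- rownames(cm$counts)
  absent <- setdiff(families$gene_id, measured)
  if (length(absent))
    msg("%d family member genes absent from the count matrix contribute 0",
        length(absent))
  fams <- families[families$gene_id %in% measured, , drop = FALSE]

  combos <- unique(ss[, c("species_id", "timepoint_h")])
  combos <- combos[order(combos$species_id, combos$timepoint_h), ]
  res <- vector("list", nrow(combos))
  fam_ids <- sort(unique(families$family_id))
  for (i in seq_len(nrow(combos))) {
    sel <- ss$species_id == combos$species_id[i] &
      ss$timepoint_h == combos$timepoint_h[i]
    cols <- ss$sample[sel]
    nrep <- length(cols)
    gene_fpkm <- rowMeans(fpkm[, cols, drop = FALSE])
    gene_cnt <- rowSums(cm$counts[, cols, drop = FALSE])
    sp_fams <- fams[fams$species_id == combos$species_id[i], , drop = FALSE]
    fsum <- tapply(gene_fpkm[sp_fams$gene_id], sp_fams$family_id, sum)
    csum <- tapply(gene_cnt[sp_fams$gene_id], sp_fams$family_id, sum)
    fam_here <- sort(unique(families$family_id[
      families$species_id == combos$species_id[i]]))
    res[[i]] <- data.frame(
      family_id = fam_here,
      species_id = combos$species_id[i],
      timepoint_h = combos$timepoint_h[i],
      fpkm_sum = ifelse(is.na(fsum[fam_here]), 0, fsum[fam_here]),
      count_sum = round(ifelse(is.na(csum[fam_here]), 0, csum[fam_here])),
      library_size = sum(ss$library_size[sel]),
      stringsAsFactors = FALSE)
    if (nrep > 1L)
      msg("%s @ %gh: %d replicates averaged (FPKM) / summed (counts)",
          combos$species_id[i], combos$timepoint_h[i], nrep)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
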