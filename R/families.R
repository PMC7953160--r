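#' Construct a gene table
#'
#' Validates and normalizes a table of gene records. Coordinates are stored
#' 0-based half-open: `start < end`, and `end` is one past the last base.
#' Use `from = "gff"` when `start` is 1-based inclusive (the GFF3
#' convention) to convert on the way in.
#'
#' @param df data.frame with columns `gene_id`, `species_id`, `chromosome`,
#'   `start`, `end`, `strand` ("+"/"-"), and optionally `length_bp` and
#'   `annotation` (empty string means unannotated).
#' @param from coordinate convention of the input: `"zero"` (0-based
#'   half-open, default) or `"gff"` (1-based inclusive).
#' @return validated gene data.frame, 0-based half-open.
#' @export
gene_table <- function(df, from = c("zero", "gff")) {
  from <- match.arg(from)
  req <- c("gene_id", "species_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (from == "gff") df$start <- df$start - 1L
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$start >= df$end))
    stop("start >= end for gene ", df$gene_id[which(df$start >= df$end)[1]])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(df$length_bp)) df$length_bp <- df$end - df$start
  if (any(df$length_bp <= 0)) stop("non-positive length_bp")
  if (is.null(df$annotation)) df$annotation <- ""
  df$annotation[is.na(df$annotation)] <- ""
  rownames(df) <- NULL
  df
}

#' Build gene families by Markov clustering of the similarity graph
#'
#' Runs MCL (expansion 2, configurable inflation) on the bitscore-weighted
#' undirected graph of filtered similarity edges. Every cluster becomes a
#' family; genes with no surviving edges become singleton families. The
#' result is a partition of all input genes. Family ids are assigned in
#' order of each family's lexicographically smallest gene id, so output is
#' deterministic.
#'
#' @param genes gene table (see [gene_table()]).
#' @param edges filtered similarity edges (see [filter_similarity_edges()]).
#' @param inflation MCL inflation (default 2).
#' @return data.frame with columns `family_id`, `species_id`, `gene_id`,
#'   one row per gene.
#' @export
build_families <- function(genes, edges, inflation = 2) {
  ids <- genes$gene_id
  unknown <- setdiff(unique(c(edges$query_id, edges$subject_id)), ids)
  if (length(unknown))
    stop("edges reference unknown gene_id: ", paste(utils::head(unknown, 5), collapse = ", "))

  membership <- integer(0)
  if (nrow(edges)) {
    ## cluster each connected component separately (keeps matrices small)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$query_id, to = edges$subject_id,
                 weight = edges$bitscore, stringsAsFactors = FALSE),
      directed = FALSE)
    comp <- igraph::components(g)$membership
    labels <- character(0)
    offset <- 0L
    for (ci in sort(unique(comp))) {
      nodes <- names(comp)[comp == ci]
      sub <- igraph::induced_subgraph(g, nodes)
      adj <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                                   sparse = TRUE))
      cl <- mcl_cluster(adj, inflation = inflation)
      membership <- c(membership, cl + offset)
      labels <- c(labels, names(cl))
      offset <- offset + max(cl)
    }
    names(membership) <- labels
  }

  singletons <- setdiff(ids, names(membership))
  if (length(singletons)) {
    extra <- seq_along(singletons) + (if (length(membership)) max(membership) else 0L)
    names(extra) <- singletons
    membership <- c(membership, extra)
  }

  ## deterministic family ids ordered by smallest member gene_id
  membership <- relabel_by_lowest(membership)
  width <- max(4L, nchar(as.character(max(membership))))
  fam_id <- sprintf(paste0("F%0", width, "d"), membership)
  out <- data.frame(
    family_id = fam_id,
    species_id = genes$species_id[match(names(membership), genes$gene_id)],
    gene_id = names(membership),
    stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$species_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Families containing genes from a single species only
#'
#' @param families family table (`family_id`, `species_id`, `gene_id`).
#' @param target_species the focal species id.
#' @return the subset of rows belonging to families whose species set is
#'   exactly `{target_species}`, ordered by `family_id`.
#' @export
find_species_specific_families <- function(families, target_species) {
  if (!target_species %in% families$species_id)
    stop("unknown species_id: ", target_species)
  sp_by_fam <- tapply(families$species_id, families$family_id,
                      function(s) length(unique(s)) == 1L && s[1] == target_species)
  keep <- names(sp_by_fam)[sp_by_fam]
  out <- families[families$family_id %in% keep, , drop = FALSE]
  out <- out[order(out$family_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Copy numbers of replicated genes per family, annotation and species
#'
#' Within a family, same-species members sharing an identical normalized
#' annotation (case-folded, whitespace-collapsed) count as one replicated
#' gene group; the copy number is the group size. Genes with empty
#' annotations form their own group each. For every family that has a
#' replicated group (count > 1) in `target_species` (or in any species if
#' `target_species` is `NULL`), counts for that family are reported across
#' all species.
#'
#' @param families family table.
#' @param genes gene table supplying annotations.
#' @param target_species focal species whose replicated families select the
#'   reported rows; `NULL` reports every (family, annotation, species) row.
#' @return data.frame `family_id`, `annotation`, `species_id`, `copy_number`.
#' @export
copy_number_table <- function(families, genes, target_species = NULL) {
  missing_rec <- setdiff(families$gene_id, genes$gene_id)
  if (length(missing_rec))
    stop("no gene record for: ", paste(utils::head(missing_rec, 5), collapse = ", "))
  ann <- genes$annotation[match(families$gene_id, genes$gene_id)]
  norm <- normalize_annotation(ann)
  ## empty annotations never group: give each its own key
  empty <- !nzchar(norm)
  norm[empty] <- paste0("\r_unannotated_", families$gene_id[empty])
  agg <- stats::aggregate(
    list(copy_number = families$gene_id),
    by = list(family_id = families$family_id, annotation = norm,
              species_id = families$species_id),
    FUN = length)
  agg$display <- ifelse(startsWith(agg$annotation, "\r"), "", agg$annotation)

  if (!is.null(target_species)) {
    rep_fams <- unique(agg$family_id[agg$species_id == target_species &
                                       agg$copy_number > 1L])
    agg <- agg[agg$family_id %in% rep_fams, , drop = FALSE]
  }
  out <- data.frame(family_id = agg$family_id, annotation = agg$display,
                    species_id = agg$species_id,
                    copy_number = agg$copy_number,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$annotation, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Families with exactly one member in every listed species
#'
#' These single-copy (one gene per genome) families are the input to
#' supergene concatenation for phylogenetics.
#'
#' @param families family table.
#' @param species_list non-empty character vector of species ids.
#' @return subset of `families` rows for qualifying families.
#' @export
single_copy_families <- function(families, species_list) {
  if (!length(species_list)) stop("species_list must be non-empty")
  counts <- table(families$family_id, families$species_id)
  want <- matrix(0L, nrow(counts), length(species_list),
                 dimnames = list(rownames(counts), species_list))
  present <- intersect(colnames(counts), species_list)
  want[, present] <- counts[, present, drop = FALSE]
  extra_sp <- setdiff(colnames(counts), species_list)
  ok <- rowSums(want == 1L) == length(species_list)
  if (length(extra_sp))
    ok <- ok & rowSums(counts[, extra_sp, drop = FALSE]) == 0L
  ## a family qualifies if its members are exactly one per listed species
  tot <- rowSums(counts)
  ok <- ok & tot == length(species_list)
  keep <- rownames(counts)[ok]
  out <- families[families$family_id %in% keep, , drop = FALSE]
  out <- out[order(out$family_id, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Concatenate per-family aligned blocks into a supergene per species
#'
#' Blocks are concatenated in lexicographic `family_id` order, so the
#' output does not depend on input ordering. All sequences within a block
#' must have equal length (alignment and trimming happen upstream) and
#' every listed species must appear in every block.
#'
#' @param aligned_blocks named list (by family id) of named character
#'   vectors (by species id) of equal-length aligned sequences.
#' @param species_list species ids to emit.
#' @return named character vector of concatenated sequences, all equal length.
#' @export
concatenate_supergene <- function(aligned_blocks, species_list) {
  if (!length(species_list)) stop("species_list must be non-empty")
  fams <- sort(names(aligned_blocks))
  out <- stats::setNames(rep("", length(species_list)), species_list)
  for (f in fams) {
    blk <- aligned_blocks[[f]]
    miss <- setdiff(species_list, names(blk))
    if (length(miss))
      stop("block ", f, " missing species: ", paste(miss, collapse = ", "))
    lens <- nchar(blk[species_list])
    if (length(unique(lens)) != 1L)
      stop("block ", f, " is ragged (unequal aligned lengths)")
    out <- paste0(out, blk[species_list])
  }
  stats::setNames(out, species_list)
}

#' Flag telomere-proximal genes
#'
#' A gene is flagged when its span lies within `window_bp` of either
#' chromosome end: `min(start, chromosome_length - end) < window_bp` on
#' 0-based half-open coordinates.
#'
#' @param genes gene table.
#' @param chromosome_lengths named numeric vector; names are
#'   `species_id:chromosome` or plain chromosome names.
#' @param window_bp window size in bp (default 10000).
#' @return character vector of flagged gene ids.
#' @export
telomere_proximal_genes <- function(genes, chromosome_lengths,
                                    window_bp = 10000) {
  key <- paste(genes$species_id, genes$chromosome, sep = ":")
  len <- chromosome_lengths[key]
  plain <- is.na(len)
  len[plain] <- chromosome_lengths[genes$chromosome[plain]]
  if (anyNA(len))
    stop("chromosome length missing for: ",
         paste(utils::head(unique(genes$chromosome[is.na(len)]), 5), collapse = ", "))
  if (any(genes$end > len))
    stop("gene extends past chromosome end: ",
         genes$gene_id[which(genes$end > len)[1]])
  flagged <- pmin(genes$start, len - genes$end) < window_bp
  genes$gene_id[flagged]
}

#' Extract upstream promoter sequences
#'
#' For a plus-strand gene at half-open `[s, e)` the upstream window is
#' `[max(0, s - length_bp), s)`; for a minus-strand gene it is the reverse
#' complement of `[e, min(L, e + length_bp))`. Windows truncated at
#' chromosome ends are returned at their reduced length.
#'
#' @param genes gene table.
#' @param genome_sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences, names as in the gene table.
#' @param length_bp upstream window length (default 1000).
#' @return named character vector, one upstream sequence per gene.
#' @export
extract_upstream <- function(genes, genome_sequences, length_bp = 1000) {
  if (methods::is(genome_sequences, "DNAStringSet"))
    genome_sequences <- stats::setNames(as.character(genome_sequences),
                                        names(genome_sequences))
  key <- paste(genes$species_id, genes$chromosome, sep = ":")
  use_key <- ifelse(key %in% names(genome_sequences), key, genes$chromosome)
  miss <- setdiff(unique(use_key), names(genome_sequences))
  if (length(miss))
    stop("chromosome missing from genome_sequences: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chr <- genome_sequences[[use_key[i]]]
    L <- nchar(chr)
    if (genes$strand[i] == "+") {
      s <- genes$start[i]
      a <- max(0, s - length_bp)
      out[i] <- if (s > a) substr(chr, a + 1L, s) else ""
    } else {
      e <- genes$end[i]
      b <- min(L, e + length_bp)
      seq <- if (b > e) substr(chr, e + 1L, b) else ""
      out[i] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
  }
  stats::setNames(out, genes$gene_id)
}
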