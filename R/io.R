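## Plain-text readers and writers for the pipeline's input and output
## artifacts. Everything is TSV, FASTA, GFF3 or JSON so runs are diff-able
## and portable.

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_read <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", ...)
}

#' Read gene records from a GFF3 file
#'
#' Imports gene-type features (1-based inclusive coordinates, converted to
#' the package's 0-based half-open convention). The `ID` attribute becomes
#' `gene_id`; `species`, and `annotation` (or `product`/`description`)
#' attributes are used when present.
#'
#' @param path GFF3 file.
#' @param species_id species id to assign when the file carries no
#'   `species` attribute.
#' @return gene table as from [gene_table()].
#' @export
read_gene_gff <- function(path, species_id = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  md <- as.data.frame(gr)
  ann <- rep("", length(gr))
  for (cand in c("annotation", "product", "description"))
    if (cand %in% names(md)) {
      v <- as.character(md[[cand]])
      ann[!is.na(v) & nzchar(v)] <- v[!is.na(v) & nzchar(v)]
      break
    }
  sp <- if ("species" %in% names(md)) as.character(md$species) else
    rep(species_id, length(gr))
  gene_table(data.frame(
    gene_id = as.character(md$ID), species_id = sp,
    chromosome = as.character(md$seqnames),
    start = md$start, end = md$end, strand = as.character(md$strand),
    annotation = ann, stringsAsFactors = FALSE), from = "gff")
}

write_gene_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "famexpress"
  gr$ID <- genes$gene_id
  gr$species <- genes$species_id
  gr$annotation <- genes$annotation
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the exact formats the pipeline readers consume: per-species
#' protein FASTA, genes GFF3, BLAST-tabular similarity TSV (12 standard
#' columns plus `qlen`, `slen`), counts TSV, sample sheet TSV, gene-length
#' TSV, chromosome-length TSV, gene-to-term TSV, genome FASTA, and
#' `truth.json`.
#'
#' @param dataset a [generate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  write_gene_gff(dataset$genes, p("genes.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(dataset$proteins), p("proteins.faa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$genome_sequences), p("genome.fa"))
  tsv_write(data.frame(chromosome = names(dataset$chromosome_lengths),
                       length_bp = unname(dataset$chromosome_lengths)),
            p("chromosome_lengths.tsv"))

  ## BLAST outfmt 6 + qlen, slen; coverages re-derivable from aln_len
  e <- dataset$edges
  qlen_aa <- dataset$genes$length_bp[match(e$query_id,
                                           dataset$genes$gene_id)] %/% 3L
  slen_aa <- dataset$genes$length_bp[match(e$subject_id,
                                           dataset$genes$gene_id)] %/% 3L
  aln <- round(pmin(e$query_coverage_pct * qlen_aa,
                    e$subject_coverage_pct * slen_aa) / 100)
  blast <- data.frame(e$query_id, e$subject_id, e$identity_pct, aln,
                      0L, 0L, 1L, aln, 1L, aln, e$evalue, e$bitscore,
                      qlen_aa, slen_aa)
  utils::write.table(blast, p("similarity.blast6.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  cm <- dataset$counts
  cnt <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  tsv_write(cnt, p("counts.tsv"))
  tsv_write(cm$samples, p("samples.tsv"))
  tsv_write(data.frame(gene_id = names(cm$gene_length_bp),
                       length_bp = unname(cm$gene_length_bp)),
            p("gene_lengths.tsv"))
  tsv_write(dataset$term_map, p("terms.tsv"))

  truth <- dataset$truth
  jsonlite::write_json(
    list(families = truth$families,
         specific_families = truth$specific_families,
         single_copy_families = truth$single_copy_families,
         multicopy_families = truth$multicopy_families,
         archetype = as.list(truth$archetype),
         partners = as.list(truth$partners),
         planted_terms = truth$planted_terms),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a dataset directory back into memory
#'
#' Inverse of [write_dataset()]; re-derives similarity-edge coverages from
#' the alignment and sequence lengths.
#'
#' @param dir directory written by [write_dataset()] (or hand-assembled in
#'   the same layout).
#' @return list with `genes`, `edges`, `counts`, `term_map`,
#'   `genome_sequences`, `chromosome_lengths`, `truth` (when present).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  genes <- read_gene_gff(p("genes.gff3"))
  edges <- read_blast_tab(p("similarity.blast6.tsv"))
  cnt <- tsv_read(p("counts.tsv"), check.names = FALSE)
  m <- as.matrix(cnt[, -1L, drop = FALSE])
  rownames(m) <- cnt$gene_id
  samples <- tsv_read(p("samples.tsv"))
  lens <- tsv_read(p("gene_lengths.tsv"))
  cm <- count_matrix(m, samples,
                     stats::setNames(lens$length_bp, lens$gene_id))
  chl <- tsv_read(p("chromosome_lengths.tsv"))
  genome <- NULL
  if (file.exists(p("genome.fa"))) {
    gg <- Biostrings::readDNAStringSet(p("genome.fa"))
    genome <- stats::setNames(as.character(gg), names(gg))
  }
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(genes = genes, edges = edges, counts = cm,
       term_map = tsv_read(p("terms.tsv")),
       genome_sequences = genome,
       chromosome_lengths = stats::setNames(chl$length_bp, chl$chromosome),
       truth = truth)
}
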