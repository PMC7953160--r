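fam_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(family_id = r[[1]], species_id = r[[2]], gene_id = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("species-specific detection keeps single-species families only", {
  fams <- fam_df(list("f1", "spA", "a1"), list("f1", "spA", "a2"),
                 list("f2", "spA", "a3"), list("f2", "spB", "b1"))
  out <- find_species_specific_families(fams, "spA")
  expect_equal(unique(out$family_id), "f1")
  expect_error(find_species_specific_families(fams, "spZ"), "spZ")
  ## complement covers everything
  comp <- setdiff(unique(fams$family_id), unique(out$family_id))
  expect_setequal(c(unique(out$family_id), comp), unique(fams$family_id))
})

test_that("copy numbers count same-annotation genes within family and species", {
  fams <- fam_df(list("f1", "spA", "a1"), list("f1", "spA", "a2"),
                 list("f1", "spB", "b1"))
  genes <- make_genes(c("a1", "a2", "b1"), species = c("spA", "spA", "spB"),
                      annotation = "Kinase")
  ## annotation matching is case/whitespace-insensitive
  genes$annotation <- c("kinase", "  KINASE ", "kinase")
  cn <- copy_number_table(fams, genes)
  expect_equal(cn$copy_number[cn$species_id == "spA"], 2L)
  expect_equal(cn$copy_number[cn$species_id == "spB"], 1L)
  ## per-species totals equal family membership counts
  expect_equal(sum(cn$copy_number[cn$species_id == "spA"]),
               sum(fams$species_id == "spA"))
})

test_that("distinct annotations and empty annotations are never replicated", {
  fams <- fam_df(list("f1", "spA", "a1"), list("f1", "spA", "a2"),
                 list("f1", "spA", "a3"), list("f1", "spA", "a4"))
  genes <- make_genes(paste0("a", 1:4), species = "spA")
  genes$annotation <- c("kinase", "phosphatase", "", "")
  cn <- copy_number_table(fams, genes)
  expect_equal(nrow(cn), 4L)
  expect_true(all(cn$copy_number == 1L))
})

test_that("focal-species replicated families are reported across all species", {
  fams <- fam_df(list("f1", "spA", "a1"), list("f1", "spA", "a2"),
                 list("f1", "spB", "b1"),
                 list("f2", "spA", "a3"), list("f2", "spB", "b2"))
  genes <- make_genes(c("a1", "a2", "a3", "b1", "b2"),
                      species = c("spA", "spA", "spA", "spB", "spB"),
                      annotation = "flocculation protein")
  cn <- copy_number_table(fams, genes, target_species = "spA")
  expect_setequal(unique(cn$family_id), "f1")       # f2 has no replication in spA
  expect_setequal(unique(cn$species_id), c("spA", "spB"))
})

test_that("single-copy families require exactly one member in every genome", {
  fams <- fam_df(list("f1", "spA", "a1"), list("f1", "spB", "b1"),
                 list("f1", "spC", "c1"),
                 list("f2", "spA", "a2"), list("f2", "spB", "b2"),
                 list("f2", "spB", "b3"), list("f2", "spC", "c2"),
                 list("f3", "spA", "a3"), list("f3", "spB", "b4"))
  out <- single_copy_families(fams, c("spA", "spB", "spC"))
  expect_equal(unique(out$family_id), "f1")
  expect_error(single_copy_families(fams, character(0)), "non-empty")
})

test_that("supergene concatenation is canonical, length-checked and complete", {
  blocks <- list(
    f2 = c(spA = "MKL", spB = "MQL"),
    f1 = c(spA = "AAAA", spB = "AAC-"))
  out <- concatenate_supergene(blocks, c("spA", "spB"))
  expect_equal(nchar(out[["spA"]]), 7L)
  expect_equal(out[["spA"]], "AAAAMKL")  # f1 then f2: lexicographic order
  ## permuting block order changes nothing
  expect_equal(concatenate_supergene(rev(blocks), c("spA", "spB")), out)
  ## single species, single block is the identity
  expect_equal(unname(concatenate_supergene(list(f1 = c(spA = "WXYZ")), "spA")),
               "WXYZ")
  expect_error(concatenate_supergene(
    list(f1 = c(spA = "AG", spB = "AGG")), c("spA", "spB")), "f1")
  expect_error(concatenate_supergene(
    list(f1 = c(spA = "AG")), c("spA", "spB")), "spB")
})

test_that("telomere proximity uses the distance from either chromosome end", {
  genes <- make_genes(c("near_start", "middle", "near_end"),
                      start = c(3000, 500000, 1e6 - 11499), len = 1500)
  lens <- c(c1 = 1e6)
  flagged <- telomere_proximal_genes(genes, lens, 10000)
  expect_setequal(flagged, c("near_start", "near_end"))
  ## boundary: gene ending 9999 bp before the end is inside the window
  g2 <- make_genes("edge", start = 1e6 - 9999 - 1500, len = 1500)
  expect_equal(telomere_proximal_genes(g2, lens), "edge")
  ## exactly 10 kb away is outside (strict inequality)
  g3 <- make_genes("outside", start = 10000, len = 1500)
  g3$end <- 1e6 - 10000; g3$start <- g3$end - 1500
  expect_length(telomere_proximal_genes(g3, lens), 0L)
  ## invariant under strand flip
  g4 <- genes; g4$strand <- "-"
  expect_equal(telomere_proximal_genes(g4, lens), flagged)
  expect_error(telomere_proximal_genes(
    make_genes("toolong", start = 1e6 - 100, len = 1500), lens), "toolong")
})

test_that("upstream extraction follows strand and truncates at ends", {
  chr <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "")  # 10 kb
  genome <- c(c1 = chr)
  plus <- make_genes("gp", start = 5000, len = 1000)
  up <- extract_upstream(plus, genome, 1000)
  expect_equal(nchar(up[["gp"]]), 1000L)
  expect_equal(up[["gp"]], substr(chr, 4001, 5000))
  ## minus strand: reverse complement of the window downstream in coordinates
  minus <- make_genes("gm", start = 5000, len = 1000, strand = "-")
  um <- extract_upstream(minus, genome, 200)
  win <- substr(chr, 6001, 6200)
  expect_equal(um[["gm"]], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(win))))
  ## truncation at the chromosome start
  short <- make_genes("gs", start = 300, len = 600)
  expect_equal(nchar(extract_upstream(short, genome, 1000)[["gs"]]), 300L)
  expect_error(extract_upstream(plus, c(c9 = chr), 1000), "c1")
})

test_that("gene coordinate conventions round-trip (gff 1-based to 0-based)", {
  df <- data.frame(gene_id = "g", species_id = "spA", chromosome = "c1",
                   start = 101, end = 200, strand = "+")
  gt <- gene_table(df, from = "gff")
  expect_equal(gt$start, 100)
  expect_equal(gt$end, 200)
  expect_equal(gt$length_bp, 100)
})
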