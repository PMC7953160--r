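mk_cm <- function(counts, lib = rep(1e6, ncol(counts)), len = NULL,
                  species = "spA", tp = seq_len(ncol(counts)), rep_ = 1L) {
  if (is.null(len)) len <- setNames(rep(1000, nrow(counts)), rownames(counts))
  samples <- data.frame(sample = colnames(counts),
                        species_id = rep_len(species, ncol(counts)),
                        timepoint_h = tp, replicate = rep_len(rep_, ncol(counts)),
                        library_size = lib, stringsAsFactors = FALSE)
  count_matrix(counts, samples, len)
}

test_that("FPKM follows the closed form and its invariances", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  cm <- mk_cm(m)
  f <- compute_fpkm(cm)
  expect_equal(f["g1", "s1"], 10)      # 10 * 1e9 / (1000 * 1e6)
  expect_equal(f["g2", "s1"], 0)
  ## doubling count and library size leaves FPKM unchanged
  cm2 <- mk_cm(m * 2, lib = 2e6)
  expect_equal(compute_fpkm(cm2)["g1", "s1"], 10)
  ## gene length scales inversely
  cm3 <- mk_cm(m, len = c(g1 = 2000, g2 = 500))
  expect_equal(compute_fpkm(cm3)["g1", "s1"], 5)
  expect_error(mk_cm(m, len = c(g1 = 0, g2 = 10)), "length")
  expect_error(mk_cm(m, lib = 0), "library")
})

test_that("family aggregation sums member FPKM and conserves totals", {
  m <- matrix(c(20, 30, 7), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  cm <- mk_cm(m)
  fams <- data.frame(family_id = c("f1", "f1", "f2"), species_id = "spA",
                     gene_id = c("g1", "g2", "g3"))
  prof <- aggregate_family_expression(compute_fpkm(cm), cm, fams)
  expect_equal(prof$fpkm_sum[prof$family_id == "f1"], 50)
  expect_equal(prof$count_sum[prof$family_id == "f1"], 50)
  ## singleton family equals its gene
  expect_equal(prof$fpkm_sum[prof$family_id == "f2"], 7)
  ## conservation: family sums add up to the gene total
  expect_equal(sum(prof$fpkm_sum), sum(compute_fpkm(cm)))
})

test_that("replicates are averaged for FPKM and pooled for counts", {
  m <- matrix(c(10, 30), 1, 2, dimnames = list("g1", c("r1", "r2")))
  samples <- data.frame(sample = c("r1", "r2"), species_id = "spA",
                        timepoint_h = c(1, 1), replicate = c(1L, 2L),
                        library_size = 1e6)
  cm <- count_matrix(m, samples, c(g1 = 1000))
  fams <- data.frame(family_id = "f1", species_id = "spA", gene_id = "g1")
  prof <- suppressMessages(
    aggregate_family_expression(compute_fpkm(cm), cm, fams))
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$fpkm_sum, 20)          # mean of 10 and 30 FPKM
  expect_equal(prof$count_sum, 40)         # pooled counts
  expect_equal(prof$library_size, 2e6)     # pooled library
})

test_that("family members missing from the count matrix contribute zero", {
  m <- matrix(5, 1, 1, dimnames = list("g1", "s1"))
  cm <- mk_cm(m)
  fams <- data.frame(family_id = c("f1", "f1"), species_id = "spA",
                     gene_id = c("g1", "g_unmeasured"))
  prof <- suppressMessages(
    aggregate_family_expression(compute_fpkm(cm), cm, fams))
  expect_equal(prof$fpkm_sum, 5)
  expect_equal(prof$count_sum, 5)
})
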