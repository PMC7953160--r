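mk_map <- function(genes, terms) {
  data.frame(gene_id = genes, term_id = terms,
             term_label = paste("label", terms), stringsAsFactors = FALSE)
}

test_that("the exact combinatorial example and trivial cases hold", {
  bg <- paste0("g", 1:10)
  tm <- mk_map(paste0("g", 1:5), "T1")         # K = 5 of N = 10
  out <- hypergeometric_enrichment(paste0("g", 1:4), tm, bg)  # k = 4 of n = 4
  expect_equal(out$p_value, choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-14)

  ## a term annotating the whole background has p = 1 for any set
  tm_all <- mk_map(bg, "Tall")
  out_all <- hypergeometric_enrichment(c("g2", "g7"), tm_all, bg)
  expect_equal(out_all$p_value, 1)

  ## terms with no hit in the set are omitted
  tm2 <- rbind(tm, mk_map(paste0("g", 8:10), "Tmiss"))
  out2 <- hypergeometric_enrichment(paste0("g", 1:3), tm2, bg)
  expect_false("Tmiss" %in% out2$term_id)

  expect_error(hypergeometric_enrichment("gX", tm, bg), "gX")
})

test_that("p-values match brute-force enumeration for all small configurations", {
  for (N in c(8, 15, 30)) {
    bg <- paste0("g", seq_len(N))
    for (K in c(2, floor(N / 2))) {
      tm <- mk_map(bg[seq_len(K)], "T")
      for (n in c(3, floor(N / 2))) {
        for (k in 1:min(n, K)) {
          gs <- c(bg[seq_len(k)],
                  if (n > k) bg[(K + 1):(K + n - k)] else character(0))
          out <- hypergeometric_enrichment(gs, tm, bg)
          expect_equal(out$p_value, hyper_oracle(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("p decreases in the hit count with everything else fixed", {
  N <- 40; bg <- paste0("g", 1:N)
  tm <- mk_map(bg[1:12], "T")
  ps <- sapply(1:8, function(k) {
    gs <- c(bg[seq_len(k)], bg[13:(13 + 8 - k - 1)])
    hypergeometric_enrichment(gs, tm, bg)$p_value
  })
  expect_true(all(diff(ps) < 0))
})

test_that("stratifying the background does not change a preserved-count p", {
  bg <- paste0("g", 1:20)
  tm <- mk_map(bg[1:6], "T")
  gs <- c(bg[1:3], bg[7:10])
  p_whole <- hypergeometric_enrichment(gs, tm, bg)$p_value
  expect_equal(p_whole, hyper_oracle(3, 6, 7, 20), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment is available by flag", {
  bg <- paste0("g", 1:30)
  tm <- rbind(mk_map(bg[1:5], "T1"), mk_map(bg[6:20], "T2"))
  out <- hypergeometric_enrichment(bg[1:6], tm, bg, bh = TRUE)
  expect_true("p_adjusted" %in% names(out))
  expect_equal(out$p_adjusted,
               p.adjust(out$p_value, method = "BH"))
})

test_that("cluster summaries find a planted term and lose it under permutation", {
  set.seed(23)
  n_fam <- 40
  fams <- data.frame(family_id = rep(sprintf("f%02d", 1:n_fam), each = 2),
                     species_id = "spA",
                     gene_id = sprintf("g%03d", 1:(2 * n_fam)))
  assign <- setNames(rep(2L, n_fam), sprintf("f%02d", 1:n_fam))
  assign[1:10] <- 1L
  ## planted term on exactly cluster 1's genes
  planted_genes <- fams$gene_id[fams$family_id %in% names(assign)[1:10]]
  tm <- rbind(mk_map(planted_genes, "Tplant"),
              mk_map(sample(fams$gene_id, 30), "Tbg"))
  out <- summarize_cluster_terms(assign, fams, tm)
  hit <- out[out$cluster == 1 & out$term_id == "Tplant", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$p_value, 0.05)

  ## permuting family labels destroys the signal almost always
  destroyed <- 0L
  for (perm in 1:100) {
    pa <- setNames(sample(assign), names(assign))
    pout <- summarize_cluster_terms(pa, fams, tm)
    p <- pout$p_value[pout$cluster == 1 & pout$term_id == "Tplant"]
    if (!length(p) || p >= 0.05) destroyed <- destroyed + 1L
  }
  expect_gte(destroyed, 95L)
})

test_that("empty gene sets produce empty result tables", {
  bg <- paste0("g", 1:5)
  tm <- mk_map(bg, "T")
  out <- summarize_cluster_terms(setNames(integer(0), character(0)),
                                 data.frame(family_id = character(0),
                                            species_id = character(0),
                                            gene_id = character(0)),
                                 tm, background = bg)
  expect_equal(nrow(out), 0L)
})
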