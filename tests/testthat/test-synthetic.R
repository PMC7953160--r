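test_that("the generator is deterministic and matches its truth set", {
  d1 <- generate_dataset(synthetic_spec(), seed = 17)
  d2 <- generate_dataset(synthetic_spec(), seed = 17)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$edges, d2$edges)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$truth, d2$truth)

  tr <- d1$truth
  expect_length(tr$specific_families, 15L)
  expect_length(tr$single_copy_families, 40L)
  expect_equal(length(unique(tr$families$true_family)), 200L)
  ## the truth partition covers every emitted gene exactly once
  expect_setequal(tr$families$gene_id, d1$genes$gene_id)
  expect_equal(anyDuplicated(tr$families$gene_id), 0L)
})

test_that("within-family edges pass the filters and decoys fail them", {
  d <- generate_dataset(synthetic_spec(), seed = 3)
  fam_of <- d$truth$families$true_family[
    match(d$edges$query_id, d$truth$families$gene_id)]
  fam_of_s <- d$truth$families$true_family[
    match(d$edges$subject_id, d$truth$families$gene_id)]
  within <- fam_of == fam_of_s
  kept <- filter_similarity_edges(d$edges)
  kept_key <- paste(pmin(kept$query_id, kept$subject_id),
                    pmax(kept$query_id, kept$subject_id))
  all_key <- paste(pmin(d$edges$query_id, d$edges$subject_id),
                   pmax(d$edges$query_id, d$edges$subject_id))
  expect_setequal(kept_key, unique(all_key[within]))
})

test_that("archetype counts have the planted means (law of large numbers)", {
  tg <- c(1, 4, 6, 12, 24, 48, 72)
  mu <- archetype_mean("late_up", tg, 200, 3)
  draws <- t(sapply(1:200, function(i)
    generate_archetype_counts("late_up", tg, 200, 3, dispersion = 10,
                              seed = 1000 + i)))
  expect_equal(colMeans(draws) / mu, rep(1, 7), tolerance = 0.05)
})

test_that("large dispersion approaches the Poisson variance-to-mean ratio", {
  x <- generate_archetype_counts("flat", rep(1, 1e4), 100, 0,
                                 dispersion = 1e6, seed = 5)
  expect_gte(var(x) / mean(x), 0.9)
  expect_lte(var(x) / mean(x), 1.2)
  expect_error(generate_archetype_counts("flat", 1, 100, 0, 0, seed = 1),
               "dispersion")
})

test_that("amplitude zero is flat for every archetype", {
  tg <- c(1, 4, 6, 12, 24, 48, 72)
  for (a in c("flat", "late_up", "late_down", "transient"))
    expect_equal(archetype_mean(a, tg, 150, 0), rep(150, 7))
})

test_that("a strong late up-shift is differential from 12 h under deep libraries", {
  tg <- c(1, 4, 6, 12, 24, 48, 72)
  mu <- round(archetype_mean("late_up", tg, 500, 3))
  for (i in 4:7) {
    g <- gfold_statistic(mu[i], 1e7, mu[1], 1e7, seed = i)$gfold
    expect_gte(g, 1)
  }
})

test_that("emitted files round-trip through the package readers", {
  d <- generate_dataset(synthetic_spec(), seed = 7)
  dir <- tempfile("ds_")
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_equal(back$genes[, names(back$genes)], d$genes[, names(back$genes)])
  expect_identical(back$counts$counts, d$counts$counts)
  expect_equal(back$counts$samples, d$counts$samples)
  expect_setequal(back$term_map$gene_id, d$term_map$gene_id)
  expect_equal(back$chromosome_lengths, d$chromosome_lengths)
  expect_length(back$truth$specific_families, 15L)
  ## filtering the re-read edges still recovers the exact family partition
  fams <- build_families(back$genes, filter_similarity_edges(back$edges))
  expect_equal(ari(partition_of(fams, d$genes$gene_id),
                   d$truth$families$true_family[
                     match(d$genes$gene_id, d$truth$families$gene_id)]), 1.0)
})

test_that("specs without focal-only annotated genes are rejected", {
  expect_error(generate_dataset(synthetic_spec(n_shared = 0L), seed = 1),
               "spec too small")
})
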