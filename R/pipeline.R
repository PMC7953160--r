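#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' tunable at its default. Pass overrides as named arguments, or a nested
#' list to merge.
#'
#' @param ... named overrides (e.g. `k = 6`, `thresholds = list(alpha = 0.01)`).
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(synthetic = TRUE, dir = NULL),
    outdir = NULL,
    seed = 17L,
    focal_species = "spA",
    partner_species = "spB",
    reference_h = 1,
    phase_a = c(6, 12),     # focal-species fast-growing window (from, to)
    phase_b = c(12, 24),    # partner-species window
    thresholds = list(
      max_evalue = 1e-5, min_coverage = 75, min_identity = 50,
      inflation = 2, credibility = 0.01, draws = 10000L,
      r_threshold = 0.8, alpha = 0.05, k = 12L, restarts = 25L,
      window_bp = 10000L, upstream_bp = 1000L))
  overrides <- list(...)
  modify <- function(base, upd) {
    for (nm in names(upd))
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], upd[[nm]]) else upd[[nm]]
    base
  }
  modify(cfg, overrides)
}

#' Validate a pipeline configuration
#'
#' Checks structure, threshold ranges, phase windows and the mandatory
#' seed before any stage runs; errors carry condition class
#' `famexpress_validation`.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @return the normalized configuration, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  fail <- function(...) stop(errorCondition(sprintf(...),
                                            class = "famexpress_validation"))
  if (!is.list(config)) fail("config must be a list or a YAML path")
  ## merge over defaults so partial configs are completed
  config <- utils::modifyList(default_config(), config)
  if (is.null(config$seed) || !is.finite(config$seed))
    fail("config$seed is mandatory")
  th <- config$thresholds
  if (th$credibility <= 0 || th$credibility >= 0.5)
    fail("credibility must be in (0, 0.5)")
  if (th$k < 1L) fail("k must be >= 1")
  for (w in c("phase_a", "phase_b"))
    if (length(config[[w]]) != 2L || config[[w]][1L] >= config[[w]][2L])
      fail("%s must be an increasing (from, to) pair", w)
  if (!isTRUE(config$input$synthetic)) {
    if (is.null(config$input$dir) || !dir.exists(config$input$dir))
      fail("input$dir does not exist")
  }
  config
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Executes the stages in dependency order: family construction from
#' filtered similarity evidence, species-specific family and copy-number
#' detection, FPKM quantification and family aggregation, fold-change
#' trajectories against the reference time point, cross-species trajectory
#' clustering, co-expression function transfer for the focal species'
#' specific families, phase-matched trend tabulation, and per-cluster term
#' enrichment. All artifacts are plain TSV/JSON under `config$outdir`; a
#' machine-readable run report (parameter echo, artifact checksums, stage
#' wall times, summary counts) is returned and written as `report.json`.
#'
#' @param config configuration list or YAML path (see [default_config()],
#'   [validate_config()]).
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  outdir <- config$outdir
  if (is.null(outdir)) outdir <- tempfile("famexpress_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  artifacts <- character(0)
  timings <- list()
  counts <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e)
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = "famexpress_stage_error")))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    tsv_write(df, path)
    artifacts <<- c(artifacts, path)
    path
  }

  ## -- inputs ---------------------------------------------------------
  ds <- stage("input", {
    if (isTRUE(config$input$synthetic))
      generate_dataset(synthetic_spec(), seed = derive_seed(config$seed, 1L))
    else read_dataset(config$input$dir)
  })
  genes <- ds$genes

  ## -- family layer ---------------------------------------------------
  fams <- stage("families", {
    fe <- filter_similarity_edges(ds$edges, th$max_evalue, th$min_coverage,
                                  th$min_identity)
    build_families(genes, fe, inflation = th$inflation)
  })
  emit(fams, "families.tsv")
  counts$families <- length(unique(fams$family_id))

  specific <- stage("specific", {
    find_species_specific_families(fams, config$focal_species)
  })
  emit(specific, "specific_families.tsv")
  counts$specific_families <- length(unique(specific$family_id))

  cn <- stage("copy_number",
              copy_number_table(fams, genes, config$focal_species))
  emit(cn, "copy_number.tsv")
  tel <- stage("telomere",
               telomere_proximal_genes(genes, ds$chromosome_lengths,
                                       th$window_bp))
  emit(data.frame(gene_id = tel), "telomere_genes.tsv")
  counts$telomere_genes <- length(tel)
  if (!is.null(ds$genome_sequences)) {
    up <- stage("upstream",
                extract_upstream(genes[genes$species_id == config$focal_species, ],
                                 ds$genome_sequences, th$upstream_bp))
    path <- file.path(outdir, "upstream.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(up), path)
    artifacts <- c(artifacts, path)
  }

  ## -- expression layer -----------------------------------------------
  prof <- stage("expression", {
    fpkm <- compute_fpkm(ds$counts)
    aggregate_family_expression(fpkm, ds$counts, fams)
  })
  emit(prof, "family_profiles.tsv")

  traj <- stage("trajectories", {
    build_trajectories(prof, reference_h = config$reference_h,
                       credibility = th$credibility, n_draws = th$draws,
                       seed = derive_seed(config$seed, 2L))
  })
  emit(traj, "trajectories.tsv")
  counts$differential_families <- length(differential_families(traj))

  ## -- cross-species layer ---------------------------------------------
  clust <- stage("clustering", {
    feats <- trajectory_features(traj, config$focal_species,
                                 config$partner_species)
    k <- min(th$k, nrow(feats))
    cluster_trajectories(feats, k = k,
                         seed = derive_seed(config$seed, 3L),
                         restarts = th$restarts)
  })
  emit(data.frame(family_id = names(clust$assignments),
                  cluster = unname(clust$assignments)), "clusters.tsv")
  emit(data.frame(cluster = seq_len(clust$k), clust$centroids,
                  check.names = FALSE), "cluster_centroids.tsv")
  counts$clusters <- clust$k

  preds <- stage("prediction", {
    fpkm <- compute_fpkm(ds$counts)
    focal_samples <- ds$counts$samples[
      ds$counts$samples$species_id == config$focal_species, ]
    focal_samples <- focal_samples[order(focal_samples$timepoint_h), ]
    tg <- as.character(focal_samples$timepoint_h)
    spec_ids <- unique(specific$family_id)
    kp <- prof[prof$family_id %in% spec_ids &
                 prof$species_id == config$focal_species, ]
    kmat <- matrix(0, length(tg), length(spec_ids),
                   dimnames = list(tg, sort(spec_ids)))
    for (i in seq_len(nrow(kp)))
      kmat[as.character(kp$timepoint_h[i]), kp$family_id[i]] <- kp$fpkm_sum[i]
    ann_genes <- genes$gene_id[genes$species_id == config$focal_species &
                                 nzchar(genes$annotation) &
                                 !(genes$gene_id %in%
                                     specific$gene_id) &
                                 genes$gene_id %in% rownames(fpkm)]
    gmat <- t(fpkm[ann_genes, focal_samples$sample, drop = FALSE])
    rownames(gmat) <- tg
    predict_function(kmat, gmat,
                     stats::setNames(genes$annotation, genes$gene_id),
                     r_threshold = th$r_threshold)
  })
  emit(preds, "function_predictions.tsv")
  counts$predictions <- sum(!is.na(preds$predicted_gene_id))

  trends <- stage("trends", {
    pa <- phase_gfold(prof, config$focal_species, config$phase_a,
                      th, derive_seed(config$seed, 4L))
    pb <- phase_gfold(prof, config$partner_species, config$phase_b,
                      th, derive_seed(config$seed, 5L))
    shared <- intersect(names(pa), names(pb))
    tab <- trend_table(pa[shared], pb[shared])
    fc <- rbind(
      data.frame(family_id = shared, species_id = config$focal_species,
                 gfold = unname(pa[shared])),
      data.frame(family_id = shared, species_id = config$partner_species,
                 gfold = unname(pb[shared])))
    list(table = tab,
         detail = data.frame(
           family_id = shared, gfold_a = unname(pa[shared]),
           gfold_b = unname(pb[shared]),
           category = phase_matched_trend(pa[shared], pb[shared])),
         ranked = rank_families_by_gfold(fc, config$focal_species))
  })
  emit(trends$detail, "trends.tsv")
  emit(trends$ranked, "ranked_families.tsv")
  jsonlite::write_json(as.data.frame(trends$table),
                       file.path(outdir, "trend_table.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, file.path(outdir, "trend_table.json"))

  enr <- stage("enrichment", {
    summarize_cluster_terms(clust, fams, ds$term_map, alpha = th$alpha)
  })
  emit(enr, "cluster_enrichment.tsv")
  counts$significant_terms <- sum(enr$significant)

  report <- list(
    parameters = config[setdiff(names(config), "input")],
    counts = counts,
    stage_seconds = timings,
    checksums = as.list(tools::md5sum(sort(artifacts))))
  names(report$checksums) <- basename(names(report$checksums))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$outdir <- outdir
  if (!is.null(ds$truth)) report$truth <- ds$truth
  invisible(report)
}

## GFOLD of `window[2]` h versus `window[1]` h per family for one species.
phase_gfold <- function(prof, species, window, th, seed) {
  a <- prof[prof$species_id == species & prof$timepoint_h == window[2L], ]
  b <- prof[prof$species_id == species & prof$timepoint_h == window[1L], ]
  shared <- intersect(a$family_id, b$family_id)
  shared <- sort(shared)
  a <- a[match(shared, a$family_id), ]
  b <- b[match(shared, b$family_id), ]
  out <- numeric(length(shared))
  for (i in seq_along(shared))
    out[i] <- gfold_statistic(a$count_sum[i], a$library_size[i],
                              b$count_sum[i], b$library_size[i],
                              credibility = th$credibility,
                              n_draws = th$draws,
                              seed = derive_seed(seed, i))$gfold
  stats::setNames(out, shared)
}
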