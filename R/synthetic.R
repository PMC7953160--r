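#' Specification of a synthetic comparative-transcriptomics dataset
#'
#' Describes the statistical structure of a planted-truth dataset: a
#' multi-species family layer (universal single-copy families, multi-copy
#' families, species-specific families, shared families), a two-species
#' time-course expression layer with archetypal trajectory shapes under
#' negative-binomial noise, planted co-expression partners for the focal
#' species' specific families, and planted enriched terms per archetype.
#' The defaults mirror the study design the package targets: a focal
#' Crabtree-negative yeast compared against a reference yeast over a
#' 7-point growth time course, inside a larger set of genomes used only
#' for family construction.
#'
#' @param n_species number of species in the family layer (default 4;
#'   ids "spA", "spB", ...). The first two are the expression species.
#' @param n_single_copy universal single-copy families (default 40).
#' @param n_specific specific families for the focal (first) species
#'   (default 15); `specific_multi` of them carry 2 genes, the rest 1.
#' @param specific_multi multi-gene specific families (default 5).
#' @param n_multicopy families with replicated (same-annotation) genes,
#'   copy numbers 2-4 in the focal species (default 20).
#' @param n_shared additional shared families, one gene in each of a
#'   random subset (>= 2) of species; total families =
#'   `n_single_copy + n_specific + n_multicopy + n_shared` (default 125,
#'   giving 200 families).
#' @param time_grid sampling times in hours (default 1, 4, 6, 12, 24, 48, 72).
#' @param library_size total mapped reads per sample (default 2e6).
#' @param base_mean_range range of per-family baseline mean counts
#'   (default c(100, 400)).
#' @param amplitude_log2 archetype amplitude in log2 units (default 3,
#'   i.e. an 8-fold shift).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param archetype_probs probabilities of the flat / late_up / late_down /
#'   transient archetypes for expressed families (default
#'   c(0.4, 0.25, 0.2, 0.15)).
#' @param telomere_fraction fraction of genes placed within 10 kb of a
#'   chromosome end (default 0.1).
#' @param decoy_fraction decoy cross-family similarity edges as a fraction
#'   of true within-family edges (default 0.05).
#' @param n_chromosomes chromosomes per species (default 2).
#' @param n_background_terms random unplanted GO-like terms (default 20).
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 4L, n_single_copy = 40L,
                           n_specific = 15L, specific_multi = 5L,
                           n_multicopy = 20L, n_shared = 125L,
                           time_grid = c(1, 4, 6, 12, 24, 48, 72),
                           library_size = 2e6,
                           base_mean_range = c(100, 400),
                           amplitude_log2 = 3, dispersion = 10,
                           archetype_probs = c(flat = 0.4, late_up = 0.25,
                                               late_down = 0.2,
                                               transient = 0.15),
                           telomere_fraction = 0.1, decoy_fraction = 0.05,
                           n_chromosomes = 2L, n_background_terms = 20L) {
  stopifnot(n_species >= 2L, specific_multi <= n_specific,
            dispersion > 0, all(archetype_probs >= 0))
  structure(list(
    species = paste0("sp", LETTERS[seq_len(n_species)]),
    n_single_copy = n_single_copy, n_specific = n_specific,
    specific_multi = specific_multi, n_multicopy = n_multicopy,
    n_shared = n_shared, time_grid = time_grid,
    library_size = library_size, base_mean_range = base_mean_range,
    amplitude_log2 = amplitude_log2, dispersion = dispersion,
    archetype_probs = archetype_probs / sum(archetype_probs),
    telomere_fraction = telomere_fraction,
    decoy_fraction = decoy_fraction, n_chromosomes = n_chromosomes,
    n_background_terms = n_background_terms), class = "synthetic_spec")
}

## Archetype shape on a time grid: multiplicative log2 offset per time.
## late_up: +amplitude from 12 h onward; late_down: -amplitude from 12 h;
## transient: +amplitude at 4-6 h only; flat: zero.
archetype_shape <- function(archetype, time_grid, amplitude_log2) {
  shape <- switch(archetype,
    flat = rep(0, length(time_grid)),
    late_up = ifelse(time_grid >= 12, amplitude_log2, 0),
    late_down = ifelse(time_grid >= 12, -amplitude_log2, 0),
    transient = ifelse(time_grid >= 4 & time_grid <= 6, amplitude_log2, 0),
    stop("unknown archetype: ", archetype))
  shape
}

#' Expected counts of a trajectory archetype
#'
#' @param archetype one of `"flat"`, `"late_up"`, `"late_down"`,
#'   `"transient"`.
#' @param time_grid time points in hours.
#' @param base_mean baseline mean count (> 0).
#' @param amplitude_log2 shift amplitude in log2 units.
#' @return numeric vector of expected counts per time point.
#' @export
archetype_mean <- function(archetype, time_grid, base_mean, amplitude_log2) {
  if (base_mean <= 0) stop("base_mean must be positive")
  base_mean * 2 ^ archetype_shape(archetype, time_grid, amplitude_log2)
}

#' Sample a count trajectory from an archetype
#'
#' Negative-binomial draws around the archetype's expected counts;
#' `dispersion` is the NB size parameter, with the Poisson limit as
#' dispersion grows.
#'
#' @inheritParams archetype_mean
#' @param dispersion NB size (> 0).
#' @param seed RNG seed.
#' @return integer vector of counts, one per time point.
#' @export
generate_archetype_counts <- function(archetype, time_grid, base_mean,
                                      amplitude_log2, dispersion, seed) {
  if (dispersion <= 0) stop("dispersion must be positive")
  mu <- archetype_mean(archetype, time_grid, base_mean, amplitude_log2)
  with_seed(seed, stats::rnbinom(length(mu), mu = mu, size = dispersion))
}

#' Simulated cross-species fold-change feature vectors
#'
#' Generates the feature matrix the trajectory-clustering step consumes:
#' per family, the archetype's fold-change pattern in both species (the
#' non-reference time points of each, concatenated) plus i.i.d. Gaussian
#' noise. Used to study clustering recovery at a controlled noise level.
#'
#' @param n_per_archetype families per archetype.
#' @param archetypes archetype names (default the four standard shapes).
#' @param noise_sd Gaussian noise standard deviation (default 0.25).
#' @param amplitude_log2 pattern amplitude (default 2).
#' @param time_grid time grid including the reference point (default
#'   the 7-point grid; the reference 1 h is dropped from features).
#' @param seed RNG seed.
#' @return list with `features` (matrix) and `truth` (archetype label per
#'   row).
#' @export
simulate_trajectory_features <- function(n_per_archetype,
                                         archetypes = c("flat", "late_up",
                                                        "late_down",
                                                        "transient"),
                                         noise_sd = 0.25,
                                         amplitude_log2 = 2,
                                         time_grid = c(1, 4, 6, 12, 24, 48, 72),
                                         seed = 17L) {
  tps <- time_grid[-1L]
  centers <- t(vapply(archetypes, function(a)
    rep(archetype_shape(a, tps, amplitude_log2), 2L),
    numeric(2L * length(tps))))
  n <- n_per_archetype * length(archetypes)
  truth <- rep(archetypes, each = n_per_archetype)
  feats <- with_seed(seed,
    centers[rep(seq_along(archetypes), each = n_per_archetype), ] +
      matrix(stats::rnorm(n * ncol(centers), sd = noise_sd), n))
  rownames(feats) <- sprintf("fam%04d", seq_len(n))
  colnames(feats) <- c(paste0("spA_", tps, "h"), paste0("spB_", tps, "h"))
  list(features = feats, truth = stats::setNames(truth, rownames(feats)))
}

#' Simulated co-expression profiles for function-transfer evaluation
#'
#' Builds FPKM-scale time profiles for `n_pairs` unannotated
#' species-specific families, each constructed to correlate with a
#' designated annotated gene at population correlation `rho`, plus
#' independent decoy annotated genes.
#'
#' @param n_pairs planted family/partner pairs (default 20).
#' @param n_decoys additional annotated genes uncorrelated with any family
#'   (default 50).
#' @param rho target correlation (default 0.95).
#' @param time_grid time points (default the 7-point grid).
#' @param seed RNG seed.
#' @return list: `kms_profiles` (time x family matrix), `gene_profiles`
#'   (time x gene matrix), `annotations` (named vector), `partners`
#'   (named character vector family -> designated gene).
#' @export
simulate_coexpression_profiles <- function(n_pairs = 20L, n_decoys = 50L,
                                           rho = 0.95,
                                           time_grid = c(1, 4, 6, 12, 24, 48, 72),
                                           seed = 17L) {
  tn <- length(time_grid)
  with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_pairs + n_decoys))
    gmat <- matrix(stats::rnorm(tn * length(genes)), tn,
                   dimnames = list(time_grid, genes))
    fams <- sprintf("KMS%02d", seq_len(n_pairs))
    partners <- stats::setNames(genes[seq_len(n_pairs)], fams)
    kmat <- matrix(NA_real_, tn, n_pairs, dimnames = list(time_grid, fams))
    for (i in seq_len(n_pairs)) {
      z <- gmat[, i]
      kmat[, i] <- rho * scale(z)[, 1] +
        sqrt(1 - rho^2) * stats::rnorm(tn)
    }
    ## shift/scale to a non-negative FPKM-like range (Pearson r unchanged)
    gmat <- 50 * (gmat - min(gmat) + 0.1)
    kmat <- 50 * (kmat - min(kmat) + 0.1)
    annotations <- stats::setNames(paste("function of", genes), genes)
    list(kms_profiles = kmat, gene_profiles = gmat,
         annotations = annotations, partners = partners)
  })
}

#' Generate a full synthetic dataset with planted truth
#'
#' Emits everything the pipeline consumes — gene records, similarity
#' edges, a two-species time-course count matrix, a gene-to-term map and
#' genome sequences — together with the `truth` ground-truth record.
#' Within-family similarity edges are drawn to pass the homology filters
#' (identity 55-95, coverage 85-100, E-value <= 1e-10); decoy cross-family
#' edges each fail at least one filter. Byte-identical output for a given
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (mandatory).
#' @return list of class `synthetic_dataset` with elements `genes`,
#'   `edges`, `counts` (a [count_matrix()]), `term_map`,
#'   `genome_sequences`, `chromosome_lengths`, `proteins`, and `truth`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 17L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  sps <- spec$species
  expr_sps <- sps[1:2]
  focal <- sps[1L]

  ## ---- family layer ------------------------------------------------
  fam <- list(); fid <- 0L
  new_fam <- function() { fid <<- fid + 1L; sprintf("T%04d", fid) }
  add <- function(id, species_counts, kind) {
    fam[[id]] <<- list(id = id, copies = species_counts, kind = kind)
  }
  for (i in seq_len(spec$n_single_copy))
    add(new_fam(), stats::setNames(rep(1L, length(sps)), sps), "single_copy")
  for (i in seq_len(spec$n_specific)) {
    ng <- if (i <= spec$specific_multi) 2L else 1L
    add(new_fam(), stats::setNames(ng, focal), "specific")
  }
  for (i in seq_len(spec$n_multicopy)) {
    cp <- stats::setNames(sample(1:2, length(sps), replace = TRUE), sps)
    cp[focal] <- sample(2:4, 1L)
    add(new_fam(), cp, "multicopy")
  }
  ## shared families span a proper subset of species (>= 2), so the
  ## universal single-copy families are exactly the planted ones
  for (i in seq_len(spec$n_shared)) {
    k <- sample(2:(length(sps) - 1L), 1L)
    chosen <- sort(sample(sps, k))
    add(new_fam(), stats::setNames(rep(1L, k), chosen), "shared")
  }

  ## expand to gene records
  rows <- list()
  gnum <- stats::setNames(rep(0L, length(sps)), sps)
  for (f in fam) {
    for (sp in names(f$copies)) {
      for (j in seq_len(f$copies[[sp]])) {
        gnum[sp] <- gnum[sp] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("%s_g%04d", sp, gnum[sp]),
          species_id = sp, true_family = f$id, kind = f$kind,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, rows)

  ## annotations: multicopy families share one label (replicated genes);
  ## single-copy/shared get unique labels; specific families unannotated
  genes$annotation <- ""
  for (f in fam) {
    sel <- genes$true_family == f$id
    if (f$kind == "multicopy") {
      genes$annotation[sel] <- paste("replicated protein", f$id)
    } else if (f$kind != "specific") {
      genes$annotation[sel] <- paste("conserved protein", f$id)
    }
  }

  ## ---- placement on chromosomes ------------------------------------
  genes$chromosome <- NA_character_
  genes$start <- NA_real_; genes$end <- NA_real_; genes$strand <- NA_character_
  ## homologs have near-equal lengths (members within ~3% of the family
  ## base), so coverages survive the alignment-length round trip
  fam_base_len <- stats::setNames(
    sample(seq(900, 3000, by = 3), length(fam), replace = TRUE),
    vapply(fam, `[[`, character(1L), "id"))
  genes$length_bp <- as.integer(3L * round(
    fam_base_len[genes$true_family] *
      stats::runif(nrow(genes), 0.97, 1.03) / 3))
  chrom_len <- c()
  stride <- 4000; margin <- 30000
  for (sp in sps) {
    gi <- which(genes$species_id == sp)
    gi <- gi[sample.int(length(gi))]  # random order across chromosomes
    per_chr <- split(gi, rep(seq_len(spec$n_chromosomes), length.out = length(gi)))
    for (ci in seq_along(per_chr)) {
      idx <- per_chr[[ci]]
      chrom <- sprintf("%s_chr%d", sp, ci)
      n_tel <- round(spec$telomere_fraction * length(idx))
      tel <- idx[seq_len(n_tel)]
      interior <- setdiff(idx, tel)
      L <- 2 * margin + stride * (length(interior) + 2L)
      if (any(genes$length_bp[idx] >= L))
        stop("infeasible placement: gene exceeds chromosome length")
      ## interior genes on a fixed stride
      for (k in seq_along(interior)) {
        s <- margin + (k - 1L) * stride
        genes$start[interior[k]] <- s
        genes$end[interior[k]] <- s + genes$length_bp[interior[k]]
      }
      ## telomeric genes: alternate chromosome start / end, span within 10 kb
      for (k in seq_along(tel)) {
        w <- genes$length_bp[tel[k]]
        if (k %% 2L == 1L) {
          s <- sample.int(max(1L, 9000L - w), 1L) - 1L
        } else {
          e <- L - (sample.int(max(1L, 9000L - w), 1L) - 1L)
          s <- e - w
        }
        genes$start[tel[k]] <- s
        genes$end[tel[k]] <- s + w
      }
      genes$chromosome[idx] <- chrom
      chrom_len[chrom] <- L
    }
  }
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  gt <- gene_table(genes[, c("gene_id", "species_id", "chromosome", "start",
                             "end", "strand", "length_bp", "annotation")])

  ## ---- genome + protein sequences ----------------------------------
  genome <- vapply(names(chrom_len), function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_len[[ch]], replace = TRUE),
          collapse = ""), character(1L))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  proteins <- vapply(genes$length_bp %/% 3L, function(n)
    paste(sample(aa, n, replace = TRUE), collapse = ""), character(1L))
  names(proteins) <- genes$gene_id

  ## ---- similarity edges --------------------------------------------
  true_edges <- list()
  for (f in fam) {
    mem <- genes$gene_id[genes$true_family == f$id]
    if (length(mem) < 2L) next
    pr <- utils::combn(mem, 2L)
    for (j in seq_len(ncol(pr))) {
      true_edges[[length(true_edges) + 1L]] <- data.frame(
        query_id = pr[1L, j], subject_id = pr[2L, j],
        identity_pct = stats::runif(1L, 55, 95),
        evalue = 10 ^ stats::runif(1L, -50, -10),
        bitscore = stats::runif(1L, 200, 900),
        query_coverage_pct = stats::runif(1L, 85, 100),
        subject_coverage_pct = stats::runif(1L, 85, 100),
        stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, true_edges)
  n_decoy <- ceiling(spec$decoy_fraction * nrow(edges))
  decoys <- list()
  while (length(decoys) < n_decoy) {
    pick <- sample(genes$gene_id, 2L)
    if (genes$true_family[match(pick[1L], genes$gene_id)] ==
        genes$true_family[match(pick[2L], genes$gene_id)]) next
    mode <- sample(c("evalue", "coverage", "identity"), 1L)
    decoys[[length(decoys) + 1L]] <- data.frame(
      query_id = pick[1L], subject_id = pick[2L],
      identity_pct = if (mode == "identity") stats::runif(1L, 10, 45)
                     else stats::runif(1L, 55, 95),
      evalue = if (mode == "evalue") 10 ^ stats::runif(1L, -4, -1)
               else 10 ^ stats::runif(1L, -50, -10),
      bitscore = stats::runif(1L, 40, 120),
      query_coverage_pct = if (mode == "coverage") stats::runif(1L, 10, 60)
                           else stats::runif(1L, 80, 100),
      subject_coverage_pct = if (mode == "coverage") stats::runif(1L, 10, 60)
                             else stats::runif(1L, 80, 100),
      stringsAsFactors = FALSE)
  }
  edges <- rbind(edges, do.call(rbind, decoys))
  edges <- edges[sample.int(nrow(edges)), ]
  rownames(edges) <- NULL

  ## ---- expression layer --------------------------------------------
  tg <- spec$time_grid
  archetypes <- names(spec$archetype_probs)
  fam_ids <- vapply(fam, `[[`, character(1L), "id")
  expressed <- fam_ids[vapply(fam, function(f)
    any(names(f$copies) %in% expr_sps), logical(1L))]
  arch_by_fam <- stats::setNames(
    sample(archetypes, length(expressed), replace = TRUE,
           prob = spec$archetype_probs), expressed)
  ## specific-family co-expression partners: latent log2 trajectories
  ## shared with a designated annotated focal-species gene
  spec_fams <- fam_ids[vapply(fam, function(f) f$kind == "specific", logical(1L))]
  ## partners live in annotated families measured only in the focal
  ## species, so the planted latent profiles never enter the
  ## cross-species clustering layer
  fams_with_b <- fam_ids[vapply(fam, function(f)
    expr_sps[2L] %in% names(f$copies), logical(1L))]
  partner_pool <- genes$gene_id[genes$species_id == focal &
                                  genes$kind == "shared" &
                                  !(genes$true_family %in% fams_with_b)]
  if (length(partner_pool) < length(spec_fams))
    stop("spec too small: not enough focal-only annotated genes for ",
         "co-expression partners")
  partners <- stats::setNames(sample(partner_pool, length(spec_fams)),
                              spec_fams)

  expr_genes <- genes[genes$species_id %in% expr_sps, , drop = FALSE]
  samples <- data.frame(
    sample = as.vector(outer(expr_sps, tg, function(s, t)
      sprintf("%s_t%gh", s, t))),
    species_id = rep(expr_sps, length(tg)),
    timepoint_h = rep(tg, each = length(expr_sps)),
    replicate = 1L,
    library_size = spec$library_size,
    stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(expr_genes), nrow(samples),
                   dimnames = list(expr_genes$gene_id, samples$sample))

  base_by_fam <- stats::setNames(
    stats::runif(length(fam_ids), spec$base_mean_range[1L],
                 spec$base_mean_range[2L]), fam_ids)
  ## latent smooth log2 profile per planted partner gene, reused by the
  ## specific family that tracks it
  latent <- list()
  latent_profile <- function() stats::rnorm(length(tg), sd = 1.2)
  for (g in unique(partners)) latent[[g]] <- latent_profile()

  for (i in seq_len(nrow(expr_genes))) {
    g <- expr_genes$gene_id[i]
    sp <- expr_genes$species_id[i]
    f <- expr_genes$true_family[i]
    nmem <- sum(expr_genes$true_family == f & expr_genes$species_id == sp)
    base <- base_by_fam[[f]] / nmem
    if (g %in% names(latent)) {
      mu <- base * 2 ^ latent[[g]]
    } else if (f %in% spec_fams) {
      mu <- base * 2 ^ latent[[partners[[f]]]]
    } else {
      mu <- archetype_mean(arch_by_fam[[f]], tg, base, spec$amplitude_log2)
    }
    for (ti in seq_along(tg)) {
      col <- sprintf("%s_t%gh", sp, tg[ti])
      counts[g, col] <- stats::rnbinom(1L, mu = mu[ti], size = spec$dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  cm <- count_matrix(counts, samples,
                     stats::setNames(expr_genes$length_bp, expr_genes$gene_id))

  ## ---- term map -----------------------------------------------------
  ## planted archetype terms on every member gene of non-flat archetype
  ## families; background terms sprinkled at random
  tm <- list()
  planted_terms <- c(late_up = "GO:9000001", late_down = "GO:9000002",
                     transient = "GO:9000003")
  for (f in expressed) {
    a <- arch_by_fam[[f]]
    if (a == "flat") next
    for (g in genes$gene_id[genes$true_family == f &
                              genes$species_id %in% expr_sps])
      tm[[length(tm) + 1L]] <- data.frame(
        gene_id = g, term_id = planted_terms[[a]],
        term_label = paste("planted", a, "process"),
        stringsAsFactors = FALSE)
  }
  bg_terms <- sprintf("GO:%07d", seq_len(spec$n_background_terms))
  expr_ids <- expr_genes$gene_id
  for (t in bg_terms) {
    hit <- sample(expr_ids, max(3L, round(0.05 * length(expr_ids))))
    for (g in hit)
      tm[[length(tm) + 1L]] <- data.frame(
        gene_id = g, term_id = t,
        term_label = paste("background process", t),
        stringsAsFactors = FALSE)
  }
  term_map <- do.call(rbind, tm)

  truth <- list(
    families = genes[, c("true_family", "species_id", "gene_id")],
    specific_families = sort(spec_fams),
    single_copy_families = sort(fam_ids[vapply(fam, function(f)
      f$kind == "single_copy", logical(1L))]),
    multicopy_families = sort(fam_ids[vapply(fam, function(f)
      f$kind == "multicopy", logical(1L))]),
    archetype = arch_by_fam,
    partners = partners,
    planted_terms = data.frame(archetype = names(planted_terms),
                               term_id = unname(planted_terms),
                               stringsAsFactors = FALSE))
  structure(list(genes = gt, edges = edges, counts = cm,
                 term_map = term_map, genome_sequences = genome,
                 chromosome_lengths = chrom_len, proteins = proteins,
                 truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes / %d species, ",
                     "%d true families, %d similarity edges\n"),
              nrow(x$genes), length(unique(x$genes$species_id)),
              length(unique(x$truth$families$true_family)), nrow(x$edges)))
  invisible(x)
}
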