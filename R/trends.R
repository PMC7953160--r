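#' Phase-matched trend category for a family
#'
#' Each species' growth-phase fold change (e.g. 12 h vs 6 h for one
#' species, 24 h vs 12 h for the other) is reduced to an up/down/unchanged
#' trend with [call_de()]; the category is the ordered pair, one of nine.
#'
#' @param gfold_a,gfold_b numeric vectors of fold-change statistics for the
#'   two species' phase comparisons (recycled to common length).
#' @return factor with levels `"up/up"`, `"up/flat"`, `"up/down"`,
#'   `"flat/up"`, ..., `"down/down"` (species A first).
#' @export
phase_matched_trend <- function(gfold_a, gfold_b) {
  ta <- call_de(gfold_a)
  tb <- call_de(gfold_b)
  lab <- c(`-1` = "down", `0` = "flat", `1` = "up")
  lev <- as.vector(t(outer(c("up", "flat", "down"), c("up", "flat", "down"),
                           paste, sep = "/")))
  factor(paste(lab[as.character(ta)], lab[as.character(tb)], sep = "/"),
         levels = lev)
}

#' 3 x 3 cross-species trend table
#'
#' Cross-tabulates per-family trends of the two species' phase-matched
#' fold changes. Cell counts sum to the number of compared families.
#'
#' @param gfold_a,gfold_b per-family fold-change statistics, equal length,
#'   aligned by family.
#' @return 3 x 3 integer table, rows = species A trend (up/flat/down),
#'   columns = species B trend.
#' @export
trend_table <- function(gfold_a, gfold_b) {
  stopifnot(length(gfold_a) == length(gfold_b))
  lab <- factor(c("up", "flat", "down"), levels = c("up", "flat", "down"))
  ta <- lab[match(call_de(gfold_a), c(1L, 0L, -1L))]
  tb <- lab[match(call_de(gfold_b), c(1L, 0L, -1L))]
  table(A = ta, B = tb)
}

#' Rank shared families by one species' fold change
#'
#' Orders families descending by the ordering species' fold-change
#' statistic (ties broken by family id) and carries the partner species'
#' value alongside — the family-level analogue of an ordered two-species
#' fold-change heatmap.
#'
#' @param fold_changes data.frame with columns `family_id`, `species_id`,
#'   `gfold` (one row per family per species; exactly two species).
#' @param order_species the species whose `gfold` defines the order.
#' @return data.frame `family_id`, `gfold_<order species>`,
#'   `gfold_<partner>`, sorted descending by the ordering column.
#' @export
rank_families_by_gfold <- function(fold_changes, order_species) {
  sps <- unique(fold_changes$species_id)
  if (!order_species %in% sps) stop("unknown species_id: ", order_species)
  partner <- setdiff(sps, order_species)
  if (length(partner) != 1L)
    stop("expected exactly two species, got: ", paste(sps, collapse = ", "))
  a <- fold_changes[fold_changes$species_id == order_species, ]
  b <- fold_changes[fold_changes$species_id == partner, ]
  shared <- intersect(a$family_id, b$family_id)
  a <- a[match(shared, a$family_id), ]
  b <- b[match(shared, b$family_id), ]
  out <- data.frame(family_id = shared, stringsAsFactors = FALSE)
  out[[paste0("gfold_", order_species)]] <- a$gfold
  out[[paste0("gfold_", partner)]] <- b$gfold
  out <- out[order(-a$gfold, a$family_id), ]
  rownames(out) <- NULL
  out
}
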