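#' Map metagenomic species onto a reconstruction catalog
#'
#' Species names in the abundance table and the catalog are compared after
#' a documented normalization (case-fold; spaces and periods to
#' underscores, see [normalize_taxon_name()]). Matched rows are kept under
#' the catalog's canonical species IDs; unmapped species are reported with
#' the relative-abundance mass they carried.
#'
#' @param table Species x samples matrix of relative abundances.
#' @param catalog_species Character vector of catalog species IDs.
#' @return List with `table` (mapped rows, original abundances, not
#'   renormalized), `unmapped` (named vector: mean pre-mapping abundance of
#'   each unmapped species) and `unmapped_mass` (per-sample unmapped
#'   abundance mass).
#' @export
map_taxa <- function(table, catalog_species) {
  stopifnot(is.matrix(table), length(catalog_species) >= 1)
  key_tab <- normalize_taxon_name(rownames(table))
  key_cat <- normalize_taxon_name(catalog_species)
  hit <- match(key_tab, key_cat)
  mapped <- !is.na(hit)
  if (!any(mapped)) stopf("no species mapped onto the catalog in any sample")
  out <- table[mapped, , drop = FALSE]
  rownames(out) <- catalog_species[hit[mapped]]
  zero_samples <- colnames(table)[colSums(out) <= 0]
  if (length(zero_samples)) {
    stopf("no mapped species with nonzero abundance in sample(s): %s",
          paste(zero_samples, collapse = ", "))
  }
  unmapped <- table[!mapped, , drop = FALSE]
  list(table = out,
       unmapped = stats::setNames(rowMeans(unmapped), rownames(unmapped)),
       unmapped_mass = colSums(unmapped))
}

#' Renormalize relative abundances to compositional closure
#'
#' @param table Species x samples matrix; every column must have positive
#'   sum.
#' @return Matrix whose columns sum to 1, proportions preserved.
#' @export
renormalize <- function(table) {
  cs <- colSums(table)
  if (any(cs <= 0)) {
    stopf("column(s) with non-positive sum: %s",
          paste(colnames(table)[cs <= 0], collapse = ", "))
  }
  sweep(table, 2, cs, "/")
}

#' Remove sub-threshold relative abundances
#'
#' Entries strictly below `threshold_fraction` are zeroed (an entry exactly
#' at the threshold is retained), columns are renormalized, and species
#' left with all-zero rows are dropped.
#'
#' @param table Species x samples matrix of relative abundances.
#' @param threshold_fraction Removal threshold as a fraction (default 1e-7,
#'   i.e. 0.00001%).
#' @return Filtered, renormalized matrix.
#' @export
apply_abundance_threshold <- function(table, threshold_fraction = 1e-7) {
  stopifnot(threshold_fraction >= 0)
  out <- table
  out[out < threshold_fraction] <- 0
  dead <- colSums(out) <= 0
  if (any(dead)) {
    stopf("threshold %g removes all species in sample(s): %s",
          threshold_fraction, paste(colnames(table)[dead], collapse = ", "))
  }
  out <- renormalize(out)
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Mapping coverage report
#'
#' Per-sample mapped-read fraction (sum of the pre-mapping abundances of
#' the species retained in the post table) and pre/post species richness.
#'
#' @param pre_table Abundance matrix before mapping/filtering.
#' @param post_table Abundance matrix after mapping/filtering (same
#'   samples).
#' @return List with `per_sample` (data frame: sample, mapped_fraction,
#'   richness_pre, richness_post) and `summary` (global mapped species
#'   count, mean/SD richness before and after, mean mapped fraction).
#' @export
coverage_stats <- function(pre_table, post_table) {
  if (!identical(sort(colnames(pre_table)), sort(colnames(post_table)))) {
    stopf("pre and post tables cover different samples")
  }
  post_table <- post_table[, colnames(pre_table), drop = FALSE]
  frac <- vapply(colnames(pre_table), function(s) {
    keep <- rownames(post_table)[post_table[, s] > 0]
    keep <- intersect(keep, rownames(pre_table))
    sum(pre_table[keep, s])
  }, numeric(1))
  rich_pre <- colSums(pre_table > 0)
  rich_post <- colSums(post_table > 0)
  per_sample <- data.frame(sample = colnames(pre_table),
                           mapped_fraction = unname(frac),
                           richness_pre = unname(rich_pre),
                           richness_post = unname(rich_post),
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       summary = list(
         n_species_pre = sum(rowSums(pre_table > 0) > 0),
         n_species_post = sum(rowSums(post_table > 0) > 0),
         mean_richness_pre = mean(rich_pre), sd_richness_pre = stats::sd(rich_pre),
         mean_richness_post = mean(rich_post), sd_richness_post = stats::sd(rich_post),
         mean_mapped_fraction = mean(frac)))
}
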