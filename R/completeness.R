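#' Derive the core gene-family set from a reference presence matrix
#'
#' A family is core when it is present in at least
#' `prevalence_threshold` of the reference taxa (inclusive threshold, so a
#' family present in exactly 95% of references qualifies at the default).
#'
#' @param presence 0/1 or logical matrix, reference taxa x gene families.
#' @param prevalence_threshold inclusive prevalence cutoff, default 0.95.
#' @return object of class `core_set` with the member family ids, the
#'   threshold, and the reference taxon count.
#' @export
derive_core_set <- function(presence, prevalence_threshold = 0.95) {
  if (is.null(dim(presence)) || nrow(presence) < 1 || ncol(presence) < 1)
    stop("presence matrix must have at least one reference taxon and one family")
  if (prevalence_threshold < 0 || prevalence_threshold > 1)
    stop("prevalence_threshold must be in [0, 1]")
  prev <- colMeans(presence > 0)
  structure(list(gene_family_ids = colnames(presence)[prev >= prevalence_threshold],
                 prevalence_threshold = prevalence_threshold,
                 n_reference_taxa = nrow(presence)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set: %d families at prevalence >= %.2f over %d reference taxa\n",
              length(x$gene_family_ids), x$prevalence_threshold,
              x$n_reference_taxa))
  invisible(x)
}

#' Score one bin's completeness against the core set
#'
#' `core_percent = 100 * |bin families  core| / |core|`; e.g. a bin with
#' 170 of 316 core families scores 53.8%.
#'
#' @param families character vector of gene families detected in the bin.
#' @param core_set a [derive_core_set()] result.
#' @param min_families strict detection cutoff for `passes_filter`
#'   (retained iff `n_families_detected > min_families`).
#' @param taxon_id optional bin label.
#' @return one-row data.table: taxon_id, n_families_detected,
#'   core_detected, core_percent, passes_filter.
#' @export
score_bin <- function(families, core_set, min_families = 900L,
                      taxon_id = NA_character_) {
  if (!length(core_set$gene_family_ids)) stop("core set is empty")
  families <- unique(families)
  core_detected <- sum(families %in% core_set$gene_family_ids)
  data.table(taxon_id = taxon_id,
             n_families_detected = length(families),
             core_detected = core_detected,
             core_percent = 100 * core_detected / length(core_set$gene_family_ids),
             passes_filter = length(families) > min_families)
}

#' Score every bin of a bin abundance
#'
#' A family counts as detected in a bin when it carries positive abundance
#' in at least one sample.
#'
#' @param ba a `bin_abundance`.
#' @inheritParams score_bin
#' @return data.table, one row per bin.
#' @export
score_bins <- function(ba, core_set, min_families = 900L) {
  detected <- rowSums(ba$values) > 0
  dt <- ba$keys[detected]
  fam_by_bin <- split(dt$gene_family_id, dt$taxon_id)
  rbindlist(lapply(names(fam_by_bin), function(tx)
    score_bin(fam_by_bin[[tx]], core_set, min_families, tx)))
}

#' Apply the bin-inclusion filter
#'
#' Retains bins with strictly more than `min_families` detected families
#' (a bin at exactly the cutoff is dropped).
#'
#' @param completeness output of [score_bins()].
#' @param min_families strict cutoff, default 900.
#' @return character vector of retained bin taxon ids.
#' @export
filter_bins <- function(completeness, min_families = 900L) {
  completeness[n_families_detected > min_families, taxon_id]
}
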