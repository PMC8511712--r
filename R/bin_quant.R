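#' Build a taxonomy tree from a node table
#'
#' @param tab data.frame with columns `taxon_id`, `parent_id` (NA for the
#'   root), `rank`, `name`. Ranks must come from the fixed vocabulary
#'   root/lineage/class/order/genus/species.
#' @return object of class `taxonomy_tree`.
#' @export
build_taxonomy <- function(tab) {
  tab <- as.data.table(tab)
  stopifnot(all(c("taxon_id", "parent_id", "rank") %in% names(tab)))
  if (anyDuplicated(tab$taxon_id)) stop("duplicated taxonomy nodes")
  bad <- setdiff(unique(tab$rank), RANK_LEVELS)
  if (length(bad)) stop("unknown rank label(s): ", paste(bad, collapse = ", "))
  roots <- tab[is.na(parent_id) | parent_id == taxon_id, taxon_id]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root")
  missing <- setdiff(tab[!is.na(parent_id), parent_id], tab$taxon_id)
  if (length(missing))
    stop("parent node(s) absent from taxonomy: ", paste(missing, collapse = ", "))
  parent <- tab$parent_id
  names(parent) <- tab$taxon_id
  rank <- tab$rank
  names(rank) <- tab$taxon_id
  # cycle check: every node must reach the root in < n steps
  n <- nrow(tab)
  for (id in tab$taxon_id) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      if (cur == roots || is.na(parent[[cur]])) break
      cur <- parent[[cur]]
      if (step > n) stop("taxonomy contains a cycle involving node ", id)
    }
  }
  structure(list(nodes = tab[], parent = parent, rank = rank, root = roots),
            class = "taxonomy_tree")
}

# for each taxon id, walk up to its ancestor (or self) at `target_rank`;
# NA when the lineage has no node at that rank
.ancestor_at_rank <- function(taxonomy, taxon_ids, target_rank) {
  uniq <- unique(taxon_ids)
  anc <- vapply(uniq, function(id) {
    if (!id %in% names(taxonomy$parent)) return(NA_character_)
    cur <- id
    repeat {
      if (taxonomy$rank[[cur]] == target_rank) return(cur)
      p <- taxonomy$parent[[cur]]
      if (is.na(p) || p == cur) return(NA_character_)
      cur <- p
    }
  }, character(1))
  anc[match(taxon_ids, uniq)]
}

#' Build environmental taxon bins at a target rank
#'
#' A contig belongs to bin `B` iff its annotated taxon equals `B` or is a
#' descendant of `B`; one bin is materialized for every node at
#' `target_rank` with at least one member contig. Contigs annotated above
#' the target rank (e.g. at class level when binning genera) fall in no
#' bin; contigs whose taxon is absent from the taxonomy are skipped with a
#' warning.
#'
#' @param contig_table a [contig_table()].
#' @param taxonomy a [build_taxonomy()] tree (or its node table).
#' @param target_rank rank to bin at, usually `"genus"` or `"order"`.
#' @return named list mapping bin taxon id to a character vector of member
#'   contig ids, with attributes `rank`, `n_unknown_taxon` (skipped) and
#'   `n_above_rank` (annotated above the target rank).
#' @export
build_bins <- function(contig_table, taxonomy, target_rank = "genus") {
  if (!inherits(taxonomy, "taxonomy_tree")) taxonomy <- build_taxonomy(taxonomy)
  if (!target_rank %in% RANK_LEVELS)
    stop("target_rank must be one of: ", paste(RANK_LEVELS, collapse = ", "))
  info <- contig_table$info[!is.na(taxon_id)]
  known <- info$taxon_id %in% names(taxonomy$parent)
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    warning(sprintf("%d contig(s) reference taxa absent from the taxonomy; skipped",
                    n_unknown))
  info <- info[known]
  anc <- .ancestor_at_rank(taxonomy, info$taxon_id, target_rank)
  bins <- split(info$contig_id, anc)
  structure(bins, rank = target_rank, n_unknown_taxon = n_unknown,
            n_above_rank = sum(is.na(anc)))
}

#' Bin-denominated FPKM at contig level
#'
#' FPKM(contig c, sample s) =
#' `(fragments_cs / (length_c/1000)) / (M_bin(c),s / 1e6)`, where
#' `M_bin` is the total number of fragments mapped to the contig's taxon
#' bin in that sample -- the bin, not the whole library, is the
#' denominator. When a bin received no fragments at all in a sample its
#' FPKM values are set to 0 and the (bin, sample) is flagged.
#'
#' @param contig_table a [contig_table()].
#' @param bins bin membership from [build_bins()].
#' @return object of class `contig_fpkm`: the contig x sample FPKM matrix
#'   restricted to binned contigs, the contig->bin map, a `totals` table of
#'   `m_bin`, and the flagged zero-total (bin, sample) pairs.
#' @export
compute_fpkm <- function(contig_table, bins) {
  counts <- contig_table$counts
  if (any(counts < 0)) stop("negative fragment counts")
  members <- unlist(bins, use.names = FALSE)
  bin_of <- rep(names(bins), lengths(bins))
  names(bin_of) <- members
  cm <- counts[members, , drop = FALSE]
  M <- rowsum(cm, group = bin_of[members])          # bin x sample totals
  lens <- contig_table$info$length_bp[match(members, contig_table$info$contig_id)]
  denom <- M[bin_of[members], , drop = FALSE] / 1e6
  fpkm <- (cm / (lens / 1000)) / denom
  fpkm[denom == 0] <- 0
  zero <- which(M == 0, arr.ind = TRUE)
  flagged <- if (nrow(zero)) data.table(taxon_id = rownames(M)[zero[, 1]],
                                        sample_id = colnames(M)[zero[, 2]])
             else data.table(taxon_id = character(), sample_id = character())
  totals <- data.table(taxon_id = rep(rownames(M), ncol(M)),
                       sample_id = rep(colnames(M), each = nrow(M)),
                       m_bin = as.vector(M))
  structure(list(fpkm = fpkm, bin = bin_of, totals = totals,
                 flagged = flagged, rank = attr(bins, "rank")),
            class = "contig_fpkm")
}

#' Aggregate contig FPKM to the (bin, gene family) level
#'
#' Sums FPKM over a bin's contigs sharing the same gene-family annotation.
#' Contigs without a gene-family annotation are dropped from the family
#' tensor but their FPKM is accumulated in a reported per-(bin, sample)
#' unannotated total (they already contributed to the `M_bin` denominator).
#'
#' @param contig_fpkm a [compute_fpkm()] result.
#' @param contig_table the matching [contig_table()].
#' @return object of class `bin_abundance`: `keys` (taxon_id,
#'   gene_family_id per row), `values` (row x sample FPKM matrix),
#'   `totals`, `unannotated`, `rank`, `flagged`.
#' @export
aggregate_by_function <- function(contig_fpkm, contig_table) {
  ids <- rownames(contig_fpkm$fpkm)
  fam <- contig_table$info$gene_family_id[match(ids, contig_table$info$contig_id)]
  bin <- contig_fpkm$bin[ids]
  has_fam <- !is.na(fam)
  key <- paste(bin[has_fam], fam[has_fam], sep = "\r")
  vals <- rowsum(contig_fpkm$fpkm[has_fam, , drop = FALSE], group = key)
  ord <- order(rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  parts <- tstrsplit(rownames(vals), "\r", fixed = TRUE)
  keys <- data.table(taxon_id = parts[[1]], gene_family_id = parts[[2]])
  rownames(vals) <- NULL
  un <- if (any(!has_fam)) {
    u <- rowsum(contig_fpkm$fpkm[!has_fam, , drop = FALSE],
                group = bin[!has_fam])
    data.table(taxon_id = rep(rownames(u), ncol(u)),
               sample_id = rep(colnames(u), each = nrow(u)),
               fpkm_unannotated = as.vector(u))
  } else data.table(taxon_id = character(), sample_id = character(),
                    fpkm_unannotated = numeric())
  structure(list(keys = keys, values = vals, totals = contig_fpkm$totals,
                 unannotated = un, rank = contig_fpkm$rank,
                 flagged = contig_fpkm$flagged),
            class = "bin_abundance")
}

#' @export
print.bin_abundance <- function(x, ...) {
  cat(sprintf("bin abundance (%s rank): %d bins, %d (bin, family) rows x %d samples\n",
              x$rank %||% "?", length(unique(x$keys$taxon_id)),
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Roll a bin abundance up to an ancestor rank
#'
#' Integrates abundances down taxonomic levels: the value of an ancestor
#' bin is its own directly assigned value plus the sum of its descendant
#' bins' values, per (gene family, sample). Bins already at `to_rank` map
#' to themselves; `to_rank` equal to the abundance's rank is the identity.
#'
#' @param ba a [aggregate_by_function()] result.
#' @param taxonomy the taxonomy tree.
#' @param to_rank ancestor rank to roll up to.
#' @return a new `bin_abundance` at `to_rank`.
#' @export
rollup <- function(ba, taxonomy, to_rank) {
  if (!inherits(taxonomy, "taxonomy_tree")) taxonomy <- build_taxonomy(taxonomy)
  if (!to_rank %in% RANK_LEVELS) stop("unknown rank: ", to_rank)
  bins <- unique(ba$keys$taxon_id)
  to_i <- match(to_rank, RANK_LEVELS)
  from_i <- match(taxonomy$rank[bins], RANK_LEVELS)
  if (any(from_i < to_i, na.rm = TRUE))
    stop(sprintf("cannot roll up to '%s': bin(s) at a more inclusive rank present",
                 to_rank))
  anc <- .ancestor_at_rank(taxonomy, ba$keys$taxon_id, to_rank)
  if (anyNA(anc))
    stop("some bins have no ancestor at rank ", to_rank)
  key <- paste(anc, ba$keys$gene_family_id, sep = "\r")
  vals <- rowsum(ba$values, group = key)
  ord <- order(rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  parts <- tstrsplit(rownames(vals), "\r", fixed = TRUE)
  keys <- data.table(taxon_id = parts[[1]], gene_family_id = parts[[2]])
  rownames(vals) <- NULL
  tot <- copy(ba$totals)
  tot[, taxon_id := .ancestor_at_rank(taxonomy, taxon_id, to_rank)]
  tot <- tot[, .(m_bin = sum(m_bin)), by = .(taxon_id, sample_id)]
  structure(list(keys = keys, values = vals, totals = tot,
                 unannotated = ba$unannotated, rank = to_rank,
                 flagged = ba$flagged),
            class = "bin_abundance")
}

#' Quantify a contig table end to end
#'
#' Convenience wrapper: [build_bins()] then [compute_fpkm()] then
#' [aggregate_by_function()].
#'
#' @inheritParams build_bins
#' @return a `bin_abundance`.
#' @export
quantify_bins <- function(contig_table, taxonomy, target_rank = "genus") {
  bins <- build_bins(contig_table, taxonomy, target_rank)
  aggregate_by_function(compute_fpkm(contig_table, bins), contig_table)
}

#' Write / read a bin abundance as flat tables
#'
#' `bin_fpkm.tsv` holds taxon_id, gene_family_id and one FPKM column per
#' sample; `bin_totals.tsv` holds the per (bin, sample) denominators.
#'
#' @param ba a `bin_abundance`.
#' @param dir output directory.
#' @export
write_bin_abundance <- function(ba, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(cbind(ba$keys, as.data.table(ba$values)),
             file.path(dir, "bin_fpkm.tsv"))
  .write_tsv(ba$totals, file.path(dir, "bin_totals.tsv"))
  invisible(dir)
}

#' @rdname write_bin_abundance
#' @param rank rank label to attach on read.
#' @export
read_bin_abundance <- function(dir, rank = "genus") {
  wide <- .read_tsv(file.path(dir, "bin_fpkm.tsv"),
                    c("taxon_id", "gene_family_id"))
  totals <- .read_tsv(file.path(dir, "bin_totals.tsv"),
                      c("taxon_id", "sample_id", "m_bin"))
  keys <- wide[, .(taxon_id, gene_family_id)]
  vals <- as.matrix(wide[, setdiff(names(wide),
                                   c("taxon_id", "gene_family_id")),
                         with = FALSE])
  structure(list(keys = keys, values = vals, totals = totals,
                 unannotated = NULL, rank = rank,
                 flagged = data.table(taxon_id = character(),
                                      sample_id = character())),
            class = "bin_abundance")
}
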