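test_that("bin membership follows the daughter-node rule", {
  ct <- toy_contigs()
  tax <- toy_taxonomy()
  expect_warning(bins <- build_bins(ct, tax, "genus"), NA)
  # species-level contig joins its genus bin; genus-level contig likewise
  expect_setequal(bins$gA, c("c1", "c2", "c5"))
  expect_setequal(bins$gB, "c4")
  # class-only contig is in no genus bin ...
  expect_false("c3" %in% unlist(bins))
  expect_equal(attr(bins, "n_above_rank"), 1L)
  # ... but appears in the class-rank bin
  bins_cls <- build_bins(ct, tax, "class")
  expect_setequal(bins_cls$cls1, c("c1", "c2", "c3", "c4", "c5"))
  # bins at a fixed rank partition the binned contigs
  expect_false(anyDuplicated(unlist(bins)) > 0)
})

test_that("contigs referencing unknown taxa are skipped with a warning", {
  ct <- toy_contigs()
  ct$info$taxon_id[4] <- "ghost"
  expect_warning(bins <- build_bins(ct, toy_taxonomy(), "genus"), "1 contig")
  expect_equal(attr(bins, "n_unknown_taxon"), 1L)
  expect_false("c4" %in% unlist(bins))
})

test_that("taxonomy validation rejects broken trees", {
  tax <- toy_taxonomy()
  expect_s3_class(build_taxonomy(tax), "taxonomy_tree")
  bad <- data.table::copy(tax); bad$parent_id[5] <- "nowhere"
  expect_error(build_taxonomy(bad), "absent")
  cyc <- data.table::copy(tax); cyc$parent_id[2] <- "gA"; cyc$parent_id[5] <- "lin1"
  expect_error(build_taxonomy(cyc), "cycle")
  badrank <- data.table::copy(tax); badrank$rank[3] <- "phylum"
  expect_error(build_taxonomy(badrank), "rank")
})

test_that("FPKM uses the bin total as denominator", {
  # bin with two contigs; M_bin per sample = column totals of the bin
  info <- data.table::data.table(
    contig_id = c("a", "b", "c"),
    length_bp = c(1000L, 500L, 2000L),
    taxon_id = c("gA", "gA", "gA"),
    gene_family_id = c("K1", "K2", NA))
  counts <- matrix(c(10, 3,
                     0, 3,
                     1e6 - 10, 2e6 - 6), ncol = 2, byrow = TRUE,
                   dimnames = list(info$contig_id, c("s1", "s2")))
  ct <- contig_table(info, counts)
  bins <- build_bins(ct, toy_taxonomy(), "genus")
  cf <- compute_fpkm(ct, bins)
  # length 1000 bp, 10 fragments, M = 1e6 -> FPKM 10
  expect_equal(cf$fpkm["a", "s1"], 10)
  # length 500 bp, 3 fragments, M = 2e6 -> FPKM 3
  expect_equal(cf$fpkm["b", "s2"], 3)
  # zero fragments -> zero FPKM
  expect_equal(cf$fpkm["b", "s1"], 0)
  # conservation: member fragments sum to M_bin
  expect_equal(cf$totals[sample_id == "s1", m_bin], 1e6)
  expect_equal(cf$totals[sample_id == "s2", m_bin], 2e6)
})

test_that("FPKM is invariant to rescaling all counts within a (bin, sample)", {
  ct <- toy_contigs()
  bins <- build_bins(ct, toy_taxonomy(), "genus")
  f1 <- compute_fpkm(ct, bins)$fpkm
  ct2 <- ct
  ct2$counts[bins$gA, "s1"] <- ct$counts[bins$gA, "s1"] * 7L
  f2 <- compute_fpkm(ct2, bins)$fpkm
  expect_equal(f2[bins$gA, "s1"], f1[bins$gA, "s1"])
})

test_that("zero-total (bin, sample) pairs yield zero FPKM and a flag", {
  info <- data.table::data.table(contig_id = "a", length_bp = 100L,
                                 taxon_id = "gA", gene_family_id = "K1")
  ct <- contig_table(info, matrix(c(0L, 5L), 1, 2,
                                  dimnames = list("a", c("s1", "s2"))))
  cf <- compute_fpkm(ct, build_bins(ct, toy_taxonomy(), "genus"))
  expect_equal(cf$fpkm["a", "s1"], 0)
  expect_false(is.nan(cf$fpkm["a", "s1"]))
  expect_equal(cf$flagged, data.table::data.table(taxon_id = "gA",
                                                  sample_id = "s1"))
})

test_that("family aggregation is additive and matches a brute-force oracle", {
  ct <- toy_contigs()
  bins <- build_bins(ct, toy_taxonomy(), "genus")
  cf <- compute_fpkm(ct, bins)
  ba <- aggregate_by_function(cf, ct)
  # brute force: tapply-style resummation per (bin, family, sample)
  for (s in c("s1", "s2")) for (i in seq_len(nrow(ba$keys))) {
    tx <- ba$keys$taxon_id[i]; fam <- ba$keys$gene_family_id[i]
    ids <- intersect(bins[[tx]],
                     ct$info[gene_family_id %in% fam, contig_id])
    expect_equal(unname(ba$values[i, s]), sum(cf$fpkm[ids, s]))
  }
  # family-less contig c5 is absent from the tensor but in the
  # unannotated totals (and contributed to M)
  expect_false(any(is.na(ba$keys$gene_family_id)))
  expect_equal(ba$unannotated[taxon_id == "gA" & sample_id == "s2",
                              fpkm_unannotated],
               unname(cf$fpkm["c5", "s2"]))
})

test_that("rollup sums descendant bins into ancestors", {
  # mixed-rank abundance: genus gA holds direct mass plus two species bins
  tax <- data.table::data.table(
    taxon_id  = c("root", "lin1", "cls1", "ord1", "gA", "gA_s1", "gA_s2", "gB"),
    parent_id = c(NA, "root", "lin1", "cls1", "ord1", "gA", "gA", "ord1"),
    rank = c("root", "lineage", "class", "order", "genus", "species",
             "species", "genus"),
    name = "")
  ba <- structure(list(
    keys = data.table::data.table(
      taxon_id = c("gA", "gA_s1", "gA_s2", "gB"),
      gene_family_id = "K1"),
    values = matrix(c(5, 3, 2, 4), 4, 1,
                    dimnames = list(NULL, "s1")),
    totals = data.table::data.table(
      taxon_id = c("gA", "gA_s1", "gA_s2", "gB"), sample_id = "s1",
      m_bin = c(50, 30, 20, 40)),
    unannotated = NULL, rank = "species",
    flagged = data.table::data.table(taxon_id = character(),
                                     sample_id = character())),
    class = "bin_abundance")
  up <- rollup(ba, tax, "genus")
  expect_equal(up$values[up$keys$taxon_id == "gA", 1], 10, ignore_attr = TRUE)
  expect_equal(up$values[up$keys$taxon_id == "gB", 1], 4, ignore_attr = TRUE)
  expect_equal(up$totals[taxon_id == "gA", m_bin], 100)
  # identity at the same rank set
  same <- rollup(up, tax, "genus")
  expect_equal(same$values, up$values)
  # rank order violation
  expect_error(rollup(up, tax, "species"), "rank")
})

test_that("rollup equals brute-force subtree summation on a generated tree", {
  cm <- small_community(seed = 8, n_genera = 4, n_fam = 30)
  ba <- quantify_bins(cm$contigs, cm$taxonomy, "genus")
  up <- rollup(ba, cm$taxonomy, "order")
  tree <- build_taxonomy(cm$taxonomy)
  # oracle: ancestor mapping recomputed by climbing parents in the test
  climb <- function(id) {
    while (tree$rank[[id]] != "order") id <- tree$parent[[id]]
    id
  }
  man <- tapply(ba$values[, 3],
                paste(vapply(ba$keys$taxon_id, climb, ""),
                      ba$keys$gene_family_id),
                sum)
  got <- structure(up$values[, 3],
                   names = paste(up$keys$taxon_id, up$keys$gene_family_id))
  expect_equal(unname(got[names(man)]), as.numeric(man[names(man)]))
  # mass conservation: everything was annotated at or below genus
  expect_equal(sum(up$values), sum(ba$values))
})
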