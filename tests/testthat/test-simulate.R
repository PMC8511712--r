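test_that("the generator is deterministic in (seed, parameters)", {
  a <- small_community(seed = 42)
  b <- small_community(seed = 42)
  expect_identical(a$contigs$counts, b$contigs$counts)
  expect_identical(a$contigs$info, b$contigs$info)
  expect_identical(a$truth$families, b$truth$families)
  c2 <- small_community(seed = 43)
  expect_false(identical(a$contigs$counts, c2$contigs$counts))
})

test_that("diel flags in the truth ledger follow the requested fraction", {
  d <- default_design()
  cm0 <- generate_community(d, genus_spec("g", 50L, diel_fraction = 0), seed = 1)
  expect_equal(sum(cm0$truth$families$is_diel), 0L)
  cm <- generate_community(d, genus_spec("g", 200L, diel_fraction = 0.2), seed = 1)
  expect_equal(sum(cm$truth$families$is_diel), 40L)
  # every diel family carries exactly one peak on the sampling grid
  diel <- cm$truth$families[is_diel == TRUE]
  expect_true(all(diel$peak_hour %in% d$times_of_day))
  expect_true(all(is.na(cm$truth$families[is_diel == FALSE, peak_hour])))
})

test_that("ledger covers every annotated (taxon, family) pair exactly once", {
  cm <- small_community(seed = 5, n_genera = 3, n_fam = 40)
  info <- cm$contigs$info[!is.na(gene_family_id)]
  genus <- sub("_sp[12]$", "", info$taxon_id)
  observed <- unique(paste(genus, info$gene_family_id))
  ledger <- paste(cm$truth$families$taxon_id, cm$truth$families$gene_family_id)
  expect_false(anyDuplicated(ledger) > 0)
  expect_setequal(observed, ledger)
})

test_that("non-diel counts match the stated negative-binomial moments", {
  # one genus, single-contig families, no rhythm: counts are iid NB draws
  d <- default_design()
  mu <- 40; disp <- 0.3
  cm <- generate_community(
    d, genus_spec("g", 250L, diel_fraction = 0, base_mean = mu,
                  nb_dispersion = disp, n_contigs_per_family = 1L),
    seed = 9, unannotated_fraction = 0)
  x <- as.vector(cm$contigs$counts)
  n <- length(x)
  expect_gte(n, 10000)
  sigma2 <- mu + disp * mu^2
  expect_lt(abs(mean(x) - mu), 3 * sqrt(sigma2 / n))
  se_var <- sqrt((nb_moment4(mu, 1 / disp) - sigma2^2) / n)
  expect_lt(abs(var(x) - sigma2), 3 * se_var)
})

test_that("amplitudes that drive the expectation negative are rejected", {
  d <- default_design()
  expect_error(
    generate_community(d, genus_spec("g", 20L, diel_fraction = 0.5,
                                     amplitude = 1.4), seed = 1),
    "negative")
  # amplitude 1 touches zero at the trough and is allowed
  expect_s3_class(
    generate_community(d, genus_spec("g", 20L, diel_fraction = 0.5,
                                     amplitude = 1), seed = 1)$contigs,
    "contig_table")
})

test_that("the generated taxonomy nests genera under order/class/lineage", {
  cm <- small_community(seed = 2, n_genera = 3)
  tree <- build_taxonomy(cm$taxonomy)
  for (g in c("g01", "g02", "g03")) {
    expect_equal(unname(taxadiel:::.ancestor_at_rank(tree, g, "order")),
                 c(g01 = "ord01", g02 = "ord01", g03 = "ord02")[[g]])
    expect_false(is.na(taxadiel:::.ancestor_at_rank(tree, g, "lineage")))
  }
  # species children route back to their genus
  expect_equal(unname(taxadiel:::.ancestor_at_rank(tree, "g02_sp1", "genus")),
               "g02")
})

test_that("amplitude-zero 'diel' families are indistinguishable from null", {
  d <- default_design()
  cm <- generate_community(
    d, genus_spec("g", 150L, diel_fraction = 0.5, amplitude = 0),
    seed = 17, unannotated_fraction = 0)
  ba <- quantify_bins(cm$contigs, cm$taxonomy, "genus")
  hrs <- d$samples$hour[match(colnames(ba$values), d$samples$sample_id)]
  pvals <- apply(ba$values, 1, function(v)
    kruskal.test(v, factor(hrs))$p.value)
  frac <- mean(pvals < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(pvals)))
})

test_that("pathway maps plant enrichments exactly as requested", {
  d <- default_design()
  universe <- make_family_universe(500)
  # no planting: ledger stays clean
  pm0 <- generate_pathway_map(universe, 10, c(10, 30), NULL, seed = 3)
  expect_equal(nrow(pm0$truth$enrichments), 0L)
  expect_error(generate_pathway_map(universe, 5, c(10, 600), NULL, seed = 1),
               "exceeds")
  # planting marks exactly round(rate * size) members diel at the hour
  cm <- generate_community(d, genus_spec("gA", 200L, diel_fraction = 0.05),
                           seed = 4, universe = universe)
  pm <- generate_pathway_map(
    universe, 10, c(20, 20),
    planted_enrichments = data.frame(taxon_id = "gA", pathway_id = 3,
                                     hour = 6),
    seed = 5, truth = cm$truth, planting_rate = 0.8)
  expect_equal(pm$truth$enrichments,
               data.table::data.table(taxon_id = "gA", pathway_id = "pw03",
                                      hour = 6))
  mem <- pm$pathways[pathway_id == "pw03", gene_family_id]
  expect_length(mem, 20L)
  planted_diel <- pm$truth$families[taxon_id == "gA" &
                                      gene_family_id %in% mem &
                                      is_diel & peak_hour == 6]
  expect_gte(nrow(planted_diel), 16L)  # 20 x 0.8 planted (+ background)
})

test_that("reference presence matrices plant a recoverable core set", {
  # no core families -> empty core set at the 0.95 threshold
  rp0 <- generate_reference_presence(30, 100, core_fraction = 0,
                                     non_core_prevalence = 0.3, seed = 6)
  expect_length(derive_core_set(rp0$presence)$gene_family_ids, 0)
  # 366 reference taxa: core present in >= ceiling(0.95*366) = 348 taxa
  rp <- generate_reference_presence(366, 300, core_fraction = 0.1,
                                    non_core_prevalence = 0.4, seed = 7)
  core_true <- rp$truth$core[is_core == TRUE, gene_family_id]
  prev <- colMeans(rp$presence)
  expect_true(all(prev[core_true] >= 348 / 366))
  recovered <- derive_core_set(rp$presence, 0.95)$gene_family_ids
  expect_setequal(recovered, core_true)
})
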