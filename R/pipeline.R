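#' Default pipeline configuration
#'
#' A self-contained demonstration configuration: a 6-genus synthetic
#' community on the full 6x4x2 diel design, sized so the whole pipeline
#' runs in seconds. Thresholds follow the pipeline conventions (FDR 0.05,
#' core prevalence 0.95, strict >5% ordination prevalence); the
#' bin-inclusion cutoff is scaled to the synthetic family counts (the
#' field convention for deeply sequenced communities is 900).
#'
#' @return nested named list; override entries and pass to
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1234L,
    design = list(times_of_day = c(6, 10, 14, 18, 22, 2),
                  n_days = 4L, n_replicates = 2L, period_hours = 24),
    community = list(n_genera = 6L, n_gene_families = 300L,
                     diel_fraction = 0.15, amplitude = 1, base_mean = 50,
                     nb_dispersion = 0.3, n_contigs_per_family = 2L,
                     contig_length_range = c(300L, 3000L)),
    pathways = list(n_pathways = 12L, size_range = c(10L, 30L),
                    planting_rate = 0.8, planted = NULL),
    reference = list(n_reference_taxa = 40L, core_fraction = 0.15,
                     non_core_prevalence = 0.4),
    thresholds = list(rank = "genus", core_prevalence = 0.95,
                      min_families = 150L, alpha = 0.05, prevalence = 0.05,
                      n_perm = 10000L, fdr_scope = "global",
                      enrichment_mode = "peak_at_t", k = 3L, trymax = 20L,
                      run_global_nmds = FALSE, run_per_bin_nmds = FALSE)
  )
}

# derive stage sub-seeds from the master seed (kept well below 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2000000011L
}

#' Run the full diel metatranscriptome pipeline
#'
#' Stages, in order: simulate inputs (written to `<out>/inputs` and read
#' back through the file readers), taxon binning and bin-denominated FPKM,
#' completeness scoring and the bin-inclusion filter, rhythmicity
#' detection with global BH correction, pathway-by-time enrichment, and
#' the ordination observation matrix (NMDS fits optional). All stage
#' outputs land under `<out>/outputs` together with a `manifest.json`
#' recording the effective configuration, stage seeds and per-stage row
#' counts. Reruns with the same configuration are byte-identical.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir output directory.
#' @param quiet suppress per-stage messages.
#' @return invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs_dir <- file.path(out_dir, "inputs")
  outputs_dir <- file.path(out_dir, "outputs")
  dir.create(outputs_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  manifest <- list(package_version = as.character(utils::packageVersion("taxadiel")),
                   config = config, stages = list())

  # -- simulate ------------------------------------------------------------
  design <- do.call(make_design, config$design)
  cc <- config$community
  specs <- lapply(seq_len(cc$n_genera), function(i)
    genus_spec(sprintf("genus%02d", i),
               n_gene_families = cc$n_gene_families,
               diel_fraction = cc$diel_fraction, amplitude = cc$amplitude,
               base_mean = cc$base_mean, nb_dispersion = cc$nb_dispersion,
               n_contigs_per_family = cc$n_contigs_per_family,
               contig_length_range = cc$contig_length_range))
  universe <- make_family_universe(ceiling(1.5 * cc$n_gene_families))
  sim_seed <- .stage_seed(config$seed, 1L)
  set.seed(sim_seed)
  truth <- .plan_truth(design, specs, universe)
  pm <- generate_pathway_map(universe, config$pathways$n_pathways,
                             config$pathways$size_range,
                             planted_enrichments = config$pathways$planted,
                             seed = .stage_seed(config$seed, 2L),
                             truth = truth,
                             planting_rate = config$pathways$planting_rate)
  rp <- generate_reference_presence(
    config$reference$n_reference_taxa, length(universe),
    core_fraction = config$reference$core_fraction,
    non_core_prevalence = config$reference$non_core_prevalence,
    seed = .stage_seed(config$seed, 3L), universe = universe,
    truth = pm$truth)
  community <- generate_community(design, specs, seed = sim_seed,
                                  universe = universe, truth = rp$truth)
  write_dataset(community, inputs_dir, pathways = pm$pathways,
                presence = rp$presence, truth = rp$truth)
  say("simulate: %d contigs x %d samples, %d genera",
      nrow(community$contigs$info), design$n_samples, cc$n_genera)
  manifest$stages$simulate <- list(seed = sim_seed,
                                   n_contigs = nrow(community$contigs$info),
                                   n_samples = design$n_samples)

  # -- quantify ------------------------------------------------------------
  ds <- read_dataset(inputs_dir, design)
  issues <- validate_inputs(inputs_dir)
  if (nrow(issues))
    stop("input validation failed at stage quantify: ",
         paste(issues$issue, collapse = "; "))
  ba <- quantify_bins(ds$contigs, ds$taxonomy, th$rank)
  write_bin_abundance(ba, outputs_dir)
  say("quantify: %d (bin, family) rows across %d bins",
      nrow(ba$values), length(unique(ba$keys$taxon_id)))
  manifest$stages$quantify <- list(n_rows = nrow(ba$values),
                                   n_bins = length(unique(ba$keys$taxon_id)))

  # -- completeness --------------------------------------------------------
  core <- derive_core_set(ds$presence, th$core_prevalence)
  comp <- score_bins(ba, core, th$min_families)
  .write_tsv(comp, file.path(outputs_dir, "completeness.tsv"))
  retained <- filter_bins(comp, th$min_families)
  say("completeness: %d/%d bins pass the >%d-family filter",
      length(retained), nrow(comp), th$min_families)
  manifest$stages$completeness <- list(n_bins = nrow(comp),
                                       n_retained = length(retained),
                                       core_size = length(core$gene_family_ids))
  keep <- ba$keys$taxon_id %in% retained
  ba_f <- ba
  ba_f$keys <- ba$keys[keep]
  ba_f$values <- ba$values[keep, , drop = FALSE]

  # -- rhythmicity ---------------------------------------------------------
  rh_seed <- .stage_seed(config$seed, 4L)
  if (length(retained)) {
    rh <- detect_rhythms(ba_f, design, n_perm = th$n_perm, seed = rh_seed,
                         alpha = th$alpha, fdr_scope = th$fdr_scope)
  } else {
    rh <- data.table(taxon_id = character(), gene_family_id = character(),
                     statistic = numeric(), max_statistic = numeric(),
                     p_raw = numeric(), p_adjusted = numeric(),
                     is_diel = logical(), peak_hour = numeric(),
                     n_perm = integer(), seed = integer())
  }
  .write_tsv(rh, file.path(outputs_dir, "rhythm_results.tsv"))
  say("rhythm: %d/%d families called diel (FDR %g)",
      sum(rh$is_diel), nrow(rh), th$alpha)
  manifest$stages$rhythm <- list(seed = rh_seed, n_tested = nrow(rh),
                                 n_diel = sum(rh$is_diel),
                                 critical_p = attr(rh, "critical_p"))

  # -- enrichment ----------------------------------------------------------
  if (nrow(rh)) {
    en <- enrich_all(rh, ds$pathways, design, alpha = th$alpha,
                     mode = th$enrichment_mode)
  } else {
    en <- enrich_all(rh, data.table(pathway_id = character(),
                                    gene_family_id = character()), design)
  }
  .write_tsv(en$results, file.path(outputs_dir, "enrichment.tsv"))
  jsonlite::write_json(en$summary, file.path(outputs_dir, "enrichment_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("enrichment: %d/%d retained tables enriched",
      en$summary$n_enriched, en$summary$n_retained)
  manifest$stages$enrichment <- en$summary

  # -- ordination ----------------------------------------------------------
  if (length(retained)) {
    om <- build_observation_matrix(ba_f, design, prevalence = th$prevalence)
    .write_tsv(cbind(om$row_info, as.data.table(om$values)),
               file.path(outputs_dir, "observations.tsv"))
    d <- bray_curtis(om)
    .write_tsv(data.table(row_id = rownames(d), as.data.table(d)),
               file.path(outputs_dir, "braycurtis.tsv"))
    n_obs <- nrow(om$values)
    if (isTRUE(th$run_global_nmds)) {
      fit <- nmds(d, k = th$k, trymax = th$trymax,
                  seed = .stage_seed(config$seed, 5L))
      ord <- data.table(row_id = rownames(d), fit$points)
      setnames(ord, c("row_id", paste0("dim", seq_len(th$k))))
      .write_tsv(ord, file.path(outputs_dir, "ordination.tsv"))
      manifest$stages$nmds <- list(stress = fit$stress,
                                   converged = fit$converged)
    }
    if (isTRUE(th$run_per_bin_nmds)) {
      pb <- per_bin_ordinations(ba_f, design, k = 2L, trymax = th$trymax,
                                seed = .stage_seed(config$seed, 6L),
                                prevalence = th$prevalence)
      .write_tsv(pb$stress, file.path(outputs_dir, "per_bin_stress.tsv"))
      manifest$stages$per_bin_nmds <- list(mean_stress = pb$mean_stress,
                                           sd_stress = pb$sd_stress)
    }
  } else {
    om <- NULL; n_obs <- 0L
    .write_tsv(data.table(taxon_id = character(), day = integer(),
                          hour = numeric()),
               file.path(outputs_dir, "observations.tsv"))
  }
  say("ordination: %d observation rows", n_obs)
  manifest$stages$ordination <- list(n_observations = n_obs)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns", force = TRUE)
  invisible(list(design = design, community = community, abundance = ba,
                 completeness = comp, retained = retained, rhythm = rh,
                 enrichment = en, observations = om, manifest = manifest))
}
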