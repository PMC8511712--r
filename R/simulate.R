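#' Specify a synthetic genus
#'
#' Parameters controlling the simulated transcriptome of one genus-level
#' taxon: how many gene families it expresses, what fraction of them are
#' truly diel, the sinusoid amplitude of diel families, and the
#' negative-binomial noise on fragment counts. Defaults are calibrated to a
#' surface-ocean eukaryote bin: ~2,000 expressed gene families per genus,
#' ~9% of them diel, fragment counts with mean 50 and NB dispersion 0.3
#' (variance mu + 0.3 mu^2), two contigs per family, contig lengths
#' 300-3,000 bp.
#'
#' @param taxon_id character id of the genus node.
#' @param n_gene_families families expressed by this genus.
#' @param diel_fraction proportion in `[0,1]` of families that are truly
#'   diel; exactly `round(diel_fraction * n_gene_families)` are flagged.
#' @param peak_phase_distribution weights over the design's sampling hours
#'   used to draw each diel family's peak phase (default uniform).
#' @param amplitude relative cosine amplitude `a >= 0`; the expected count
#'   at hour t for a family peaking at phi is
#'   `base_mean * (1 + a * cos(2*pi*(t - phi)/period))`. Values of `a` that
#'   would make the expectation negative at a sampled hour are rejected at
#'   generation time.
#' @param base_mean mean fragment count per family per sample.
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param n_contigs_per_family contigs splitting each family's expectation.
#' @param contig_length_range `(min_bp, max_bp)` for uniform contig lengths.
#' @return a `genus_spec` list.
#' @export
genus_spec <- function(taxon_id, n_gene_families = 2000L, diel_fraction = 0.09,
                       peak_phase_distribution = NULL, amplitude = 1,
                       base_mean = 50, nb_dispersion = 0.3,
                       n_contigs_per_family = 2L,
                       contig_length_range = c(300L, 3000L)) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L,
            n_gene_families >= 1, diel_fraction >= 0, diel_fraction <= 1,
            amplitude >= 0, base_mean > 0, nb_dispersion > 0,
            n_contigs_per_family >= 1, length(contig_length_range) == 2L,
            contig_length_range[1] > 0,
            contig_length_range[2] >= contig_length_range[1])
  structure(list(taxon_id = taxon_id,
                 n_gene_families = as.integer(n_gene_families),
                 diel_fraction = diel_fraction,
                 peak_phase_distribution = peak_phase_distribution,
                 amplitude = amplitude, base_mean = base_mean,
                 nb_dispersion = nb_dispersion,
                 n_contigs_per_family = as.integer(n_contigs_per_family),
                 contig_length_range = as.integer(contig_length_range)),
            class = "genus_spec")
}

#' Build a gene-family identifier universe
#'
#' @param n number of identifiers.
#' @return character vector `K00001 ...` style ids.
#' @export
make_family_universe <- function(n) sprintf("K%05d", seq_len(n))

# uniform integer draw on [lo, hi] that is safe when lo == hi
.sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else
    sample(seq(as.integer(lo), as.integer(hi)), n, replace = TRUE)
}

# empty truth ledger
.new_truth <- function() {
  structure(list(
    families = data.table(taxon_id = character(), gene_family_id = character(),
                          is_diel = logical(), peak_hour = numeric(),
                          amplitude = numeric()),
    enrichments = data.table(taxon_id = character(), pathway_id = character(),
                             hour = numeric()),
    core = data.table(gene_family_id = character(), is_core = logical())
  ), class = "truth_ledger")
}

# Draw the per-family truth (which families each genus expresses, which are
# diel and at what phase). Consumes RNG state; call under set.seed().
.plan_truth <- function(design, genus_specs, universe) {
  truth <- .new_truth()
  fam <- lapply(genus_specs, function(sp) {
    fams <- sort(sample(universe, sp$n_gene_families))
    n_diel <- round(sp$diel_fraction * sp$n_gene_families)
    is_diel <- rep(FALSE, sp$n_gene_families)
    if (n_diel > 0) is_diel[sample.int(sp$n_gene_families, n_diel)] <- TRUE
    w <- sp$peak_phase_distribution
    if (is.null(w)) w <- rep(1, length(design$times_of_day))
    if (length(w) != length(design$times_of_day))
      stop("peak_phase_distribution must have one weight per sampling hour")
    peaks <- rep(NA_real_, sp$n_gene_families)
    if (n_diel > 0)
      peaks[is_diel] <- sample(design$times_of_day, n_diel,
                               replace = TRUE, prob = w)
    data.table(taxon_id = sp$taxon_id, gene_family_id = fams,
               is_diel = is_diel, peak_hour = peaks,
               amplitude = ifelse(is_diel, sp$amplitude, 0))
  })
  truth$families <- rbindlist(fam)
  truth
}

# Nest genera under order/class/lineage nodes so taxonomic roll-up is
# exercised: two genera per order, two orders per class, two classes per
# lineage. Each genus additionally gets two species child nodes.
.build_taxonomy_table <- function(genus_ids) {
  g <- length(genus_ids)
  ord <- sprintf("ord%02d", ceiling(seq_len(g) / 2))
  cls <- sprintf("cls%02d", ceiling(seq_len(g) / 4))
  lin <- sprintf("lin%02d", ceiling(seq_len(g) / 8))
  rows <- list(data.table(taxon_id = "root", parent_id = NA_character_,
                          rank = "root", name = "root"))
  add <- function(ids, parents, rk) {
    u <- !duplicated(ids)
    rows[[length(rows) + 1L]] <<- data.table(
      taxon_id = ids[u], parent_id = parents[u], rank = rk, name = ids[u])
  }
  add(lin, rep("root", g), "lineage")
  add(cls, lin, "class")
  add(ord, cls, "order")
  add(genus_ids, ord, "genus")
  sp_ids <- as.vector(t(outer(genus_ids, c("_sp1", "_sp2"), paste0)))
  add(sp_ids, rep(genus_ids, each = 2L), "species")
  rbindlist(rows)
}

#' Simulate a diel metatranscriptome community
#'
#' Generates every input table the pipeline consumes, together with a
#' ground-truth ledger. For a truly diel family with peak hour `phi` and
#' amplitude `a`, the expected fragment count at hour `t` is
#' `base_mean * (1 + a*cos(2*pi*(t - phi)/period))`; non-diel families have
#' constant expectation `base_mean`. Realized counts are drawn
#' negative-binomial (variance `mu + dispersion*mu^2`) independently per
#' contig and sample, with each family's expectation split equally across
#' its contigs. Contigs are annotated either at the genus node or at one of
#' two species child nodes, so bin construction must follow daughter nodes.
#' Identical `(seed, parameters)` reproduce identical output.
#'
#' @param design a [make_design()] object.
#' @param genus_specs list of [genus_spec()] objects.
#' @param seed integer seed.
#' @param universe optional gene-family id universe (character); defaults to
#'   1.5x the largest per-genus family count so genera overlap partially.
#' @param truth optional pre-built truth ledger (e.g. updated by
#'   [generate_pathway_map()]); when supplied, counts are realized from it
#'   instead of drawing a fresh ledger.
#' @param unannotated_fraction fraction of extra contigs per genus carrying
#'   a taxon but no gene-family annotation (they contribute to bin totals
#'   but not to the family tensor).
#' @param n_unassigned_contigs contigs with no taxonomic assignment at all.
#' @return list of class `diel_community` with elements `contigs` (a
#'   `contig_table`), `taxonomy`, `samples`, `truth`, `design`.
#' @export
generate_community <- function(design, genus_specs, seed, universe = NULL,
                               truth = NULL, unannotated_fraction = 0.05,
                               n_unassigned_contigs = 0L) {
  stopifnot(inherits(design, "diel_design"), length(genus_specs) >= 1)
  if (inherits(genus_specs, "genus_spec")) genus_specs <- list(genus_specs)
  set.seed(as.integer(seed))
  if (is.null(universe))
    universe <- make_family_universe(
      ceiling(1.5 * max(vapply(genus_specs, `[[`, 1L, "n_gene_families"))))
  if (is.null(truth)) truth <- .plan_truth(design, genus_specs, universe)

  hours <- design$samples$hour
  n_s <- design$n_samples
  genus_ids <- vapply(genus_specs, `[[`, "", "taxon_id")
  taxonomy <- .build_taxonomy_table(genus_ids)

  info_list <- list()
  counts_list <- list()
  contig_counter <- 0L
  for (sp in genus_specs) {
    fam <- truth$families[taxon_id == sp$taxon_id]
    if (nrow(fam) == 0L)
      stop("truth ledger has no families for taxon ", sp$taxon_id)
    # family x sample expectation
    rel <- matrix(1, nrow(fam), n_s)
    di <- which(fam$is_diel)
    if (length(di)) {
      ph <- outer(fam$peak_hour[di], hours,
                  function(p, t) cos(2 * pi * (t - p) / design$period_hours))
      rel[di, ] <- 1 + fam$amplitude[di] * ph
    }
    if (min(rel) < -1e-9)
      stop(sprintf(
        "amplitude %g makes the expected count negative at a sampled hour for taxon %s",
        sp$amplitude, sp$taxon_id))
    rel[rel < 0] <- 0
    k <- sp$n_contigs_per_family
    mu <- (sp$base_mean / k) * rel[rep(seq_len(nrow(fam)), each = k), , drop = FALSE]
    n_extra <- max(0L, round(unannotated_fraction * nrow(fam) * k))
    if (n_extra > 0)
      mu <- rbind(mu, matrix(sp$base_mean, n_extra, n_s))
    n_c <- nrow(mu)
    cnt <- matrix(rnbinom(n_c * n_s, mu = as.vector(mu),
                          size = 1 / sp$nb_dispersion),
                  nrow = n_c, ncol = n_s)
    nodes <- c(sp$taxon_id, paste0(sp$taxon_id, c("_sp1", "_sp2")))
    info <- data.table(
      contig_id = sprintf("c%07d", contig_counter + seq_len(n_c)),
      length_bp = .sample_range(sp$contig_length_range[1],
                                sp$contig_length_range[2], n_c),
      taxon_id = sample(nodes, n_c, replace = TRUE, prob = c(0.5, 0.25, 0.25)),
      gene_family_id = c(rep(fam$gene_family_id, each = k),
                         rep(NA_character_, n_extra)))
    contig_counter <- contig_counter + n_c
    info_list[[sp$taxon_id]] <- info
    counts_list[[sp$taxon_id]] <- cnt
  }
  if (n_unassigned_contigs > 0) {
    n_c <- as.integer(n_unassigned_contigs)
    base <- mean(vapply(genus_specs, `[[`, 0, "base_mean"))
    info_list[["..unassigned"]] <- data.table(
      contig_id = sprintf("c%07d", contig_counter + seq_len(n_c)),
      length_bp = sample(300:3000, n_c, replace = TRUE),
      taxon_id = NA_character_, gene_family_id = NA_character_)
    counts_list[["..unassigned"]] <-
      matrix(rnbinom(n_c * n_s, mu = base, size = 1 / 0.3), n_c, n_s)
  }
  info <- rbindlist(info_list)
  counts <- do.call(rbind, counts_list)
  dimnames(counts) <- list(info$contig_id, design$samples$sample_id)
  structure(list(
    contigs = contig_table(info, counts),
    taxonomy = taxonomy,
    samples = copy(design$samples),
    truth = truth,
    design = design
  ), class = "diel_community")
}

#' Generate a pathway membership map, optionally planting enrichments
#'
#' Draws `n_pathways` pathways of sizes uniform in `pathway_size_range` from
#' the gene-family universe (pathways may share families). For each planted
#' `(taxon, pathway, hour)` enrichment, the pathway's members are drawn from
#' that taxon's expressed families and exactly
#' `round(planting_rate * size)` of them are set diel with the planted peak
#' hour in the truth ledger, an elevated in-pathway diel rate versus the
#' background `diel_fraction`. Counts must therefore be realized *after*
#' planting by passing the updated ledger to [generate_community()].
#'
#' @param gene_family_universe character vector of family ids.
#' @param n_pathways number of pathways.
#' @param pathway_size_range `(min, max)` member counts.
#' @param planted_enrichments `NULL` or data.frame with columns
#'   `taxon_id`, `pathway_id` (index in `1..n_pathways` or `pwNN` id),
#'   `hour`.
#' @param seed integer seed.
#' @param truth truth ledger to update (required when planting).
#' @param planting_rate fraction of planted-pathway members made diel at the
#'   planted hour (default 0.8).
#' @return list with `pathways` (long table `pathway_id`, `gene_family_id`)
#'   and the updated `truth` ledger.
#' @export
generate_pathway_map <- function(gene_family_universe, n_pathways = 10L,
                                 pathway_size_range = c(10L, 30L),
                                 planted_enrichments = NULL, seed = 1L,
                                 truth = NULL, planting_rate = 0.8) {
  stopifnot(length(gene_family_universe) >= 1, n_pathways >= 1,
            planting_rate >= 0, planting_rate <= 1)
  if (max(pathway_size_range) > length(gene_family_universe))
    stop(sprintf("pathway size %d exceeds the %d-family universe",
                 max(pathway_size_range), length(gene_family_universe)))
  set.seed(as.integer(seed))
  if (is.null(truth)) truth <- .new_truth() else truth <- .copy_truth(truth)
  ids <- sprintf("pw%02d", seq_len(n_pathways))
  sizes <- .sample_range(pathway_size_range[1], pathway_size_range[2],
                         n_pathways)
  planted <- if (is.null(planted_enrichments)) NULL else
    as.data.table(planted_enrichments)
  if (!is.null(planted) && is.numeric(planted$pathway_id))
    planted[, pathway_id := ids[pathway_id]]
  members <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    pw <- ids[i]
    pl <- if (is.null(planted)) NULL else planted[pathway_id == pw]
    if (!is.null(pl) && nrow(pl)) {
      # draw members from the planted taxon's family set so the planting
      # arithmetic (round(rate x size) diel members) is exact
      tx <- pl$taxon_id[1]
      fams <- truth$families[taxon_id == tx, gene_family_id]
      if (length(fams) == 0L)
        stop("planted enrichment references taxon absent from the truth ledger: ", tx)
      if (sizes[i] > length(fams)) sizes[i] <- length(fams)
      mem <- sample(fams, sizes[i])
      for (r in seq_len(nrow(pl))) {
        n_plant <- round(planting_rate * length(mem))
        make_diel <- sample(mem, n_plant)
        truth$families[taxon_id == pl$taxon_id[r] &
                         gene_family_id %in% make_diel,
                       `:=`(is_diel = TRUE, peak_hour = pl$hour[r],
                            amplitude = pmax(amplitude, 1))]
        truth$enrichments <- rbind(
          truth$enrichments,
          data.table(taxon_id = pl$taxon_id[r], pathway_id = pw,
                     hour = pl$hour[r]))
      }
    } else {
      mem <- sample(gene_family_universe, sizes[i])
    }
    members[[i]] <- data.table(pathway_id = pw, gene_family_id = sort(mem))
  }
  # sanity: planted triples must exceed the background diel rate
  if (nrow(truth$enrichments)) {
    pwdt <- rbindlist(members)
    for (r in seq_len(nrow(truth$enrichments))) {
      e <- truth$enrichments[r]
      fams <- truth$families[taxon_id == e$taxon_id]
      mem <- pwdt[pathway_id == e$pathway_id, gene_family_id]
      inp <- fams[gene_family_id %in% mem]
      bg <- fams[!gene_family_id %in% mem]
      if (mean(inp$is_diel & inp$peak_hour == e$hour) <=
          mean(bg$is_diel & bg$peak_hour == e$hour, na.rm = TRUE))
        stop("planted enrichment did not exceed the background diel rate")
    }
  }
  list(pathways = rbindlist(members), truth = truth)
}

#' Generate a reference presence matrix with a planted core set
#'
#' Emulates mapping reference proteomes against gene-family profiles:
#' families flagged core are present in at least 95% of reference taxa by
#' construction; the rest are present at `non_core_prevalence`.
#'
#' @param n_reference_taxa number of reference organisms.
#' @param n_gene_families number of families (columns).
#' @param core_fraction fraction of families planted as core.
#' @param non_core_prevalence per-taxon presence probability of non-core
#'   families; keep it below the core threshold for exact recovery.
#' @param seed integer seed.
#' @param universe optional family ids (first `n_gene_families` are used).
#' @param truth optional truth ledger to update with core flags.
#' @return list with `presence` (0/1 integer matrix, reference taxa x
#'   families) and the updated `truth` ledger.
#' @export
generate_reference_presence <- function(n_reference_taxa, n_gene_families,
                                        core_fraction = 0.1,
                                        non_core_prevalence = 0.4, seed = 1L,
                                        universe = NULL, truth = NULL) {
  stopifnot(n_reference_taxa >= 1, n_gene_families >= 1,
            core_fraction >= 0, core_fraction <= 1,
            non_core_prevalence >= 0, non_core_prevalence <= 1)
  set.seed(as.integer(seed))
  if (is.null(truth)) truth <- .new_truth() else truth <- .copy_truth(truth)
  fams <- if (is.null(universe)) make_family_universe(n_gene_families) else
    head(universe, n_gene_families)
  n_core <- round(core_fraction * n_gene_families)
  core <- rep(FALSE, n_gene_families)
  if (n_core > 0) core[sample.int(n_gene_families, n_core)] <- TRUE
  pres <- matrix(0L, n_reference_taxa, n_gene_families,
                 dimnames = list(sprintf("ref%03d", seq_len(n_reference_taxa)),
                                 fams))
  lo <- ceiling(0.95 * n_reference_taxa)
  for (j in which(core)) {
    k <- if (lo >= n_reference_taxa) n_reference_taxa else
      sample(lo:n_reference_taxa, 1L)
    pres[sample.int(n_reference_taxa, k), j] <- 1L
  }
  nc <- which(!core)
  if (length(nc))
    pres[, nc] <- matrix(
      rbinom(n_reference_taxa * length(nc), 1L, non_core_prevalence),
      n_reference_taxa, length(nc))
  truth$core <- data.table(gene_family_id = fams, is_core = core)
  list(presence = pres, truth = truth)
}

.copy_truth <- function(truth) {
  structure(list(families = copy(truth$families),
                 enrichments = copy(truth$enrichments),
                 core = copy(truth$core)), class = "truth_ledger")
}

#' @importFrom stats rbinom
NULL
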