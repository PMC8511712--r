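# shared fixtures built in code

default_design <- function() make_design(c(6, 10, 14, 18, 22, 2), 4L, 2L)

# small community for end-to-end tests
small_community <- function(seed = 1, n_genera = 2, n_fam = 60,
                            diel_fraction = 0.2, amplitude = 1,
                            base_mean = 50, nb_dispersion = 0.3,
                            design = default_design(), ...) {
  specs <- lapply(seq_len(n_genera), function(i)
    genus_spec(sprintf("g%02d", i), n_gene_families = n_fam,
               diel_fraction = diel_fraction, amplitude = amplitude,
               base_mean = base_mean, nb_dispersion = nb_dispersion, ...))
  generate_community(design, specs, seed = seed)
}

# toy 7-node taxonomy used by the binning tests
toy_taxonomy <- function() {
  data.table::data.table(
    taxon_id  = c("root", "lin1", "cls1", "ord1", "gA", "gA_sp1", "gB"),
    parent_id = c(NA, "root", "lin1", "cls1", "ord1", "gA", "ord1"),
    rank      = c("root", "lineage", "class", "order", "genus", "species",
                  "genus"),
    name      = c("root", "lin1", "cls1", "ord1", "gA", "gA_sp1", "gB"))
}

# contig table over the toy taxonomy with hand-set counts
toy_contigs <- function() {
  info <- data.table::data.table(
    contig_id = paste0("c", 1:6),
    length_bp = c(1000L, 500L, 800L, 1000L, 400L, 600L),
    taxon_id = c("gA_sp1", "gA", "cls1", "gB", "gA", NA),
    gene_family_id = c("K1", "K1", "K2", "K2", NA, "K3"))
  counts <- matrix(c(10, 4,
                     6, 0,
                     3, 3,
                     8, 2,
                     1, 5,
                     7, 7), ncol = 2, byrow = TRUE,
                   dimnames = list(info$contig_id, c("s1", "s2")))
  contig_table(info, counts)
}
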