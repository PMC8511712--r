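#' Construct a contig table
#'
#' Bundles per-contig metadata (length, taxonomic and gene-family
#' annotation) with the contig x sample fragment-count matrix. The sample
#' set is identical across contigs by construction of the matrix.
#'
#' @param info data.frame with columns `contig_id`, `length_bp`,
#'   `taxon_id` (NA allowed), `gene_family_id` (NA allowed).
#' @param counts integer matrix, rows = contigs (rownames = contig ids),
#'   columns = samples.
#' @return object of class `contig_table`.
#' @export
contig_table <- function(info, counts) {
  info <- as.data.table(info)
  need <- c("contig_id", "length_bp", "taxon_id", "gene_family_id")
  if (!all(need %in% names(info)))
    stop("contig info needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(info$contig_id)) stop("duplicated contig ids")
  if (any(info$length_bp <= 0)) stop("contig lengths must be positive")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- info$contig_id
  if (!identical(rownames(counts), info$contig_id))
    counts <- counts[info$contig_id, , drop = FALSE]
  if (any(counts < 0)) stop("negative fragment counts")
  structure(list(info = info[], counts = counts), class = "contig_table")
}

#' @export
print.contig_table <- function(x, ...) {
  cat(sprintf("contig table: %d contigs x %d samples (%d with taxon, %d with gene family)\n",
              nrow(x$info), ncol(x$counts), sum(!is.na(x$info$taxon_id)),
              sum(!is.na(x$info$gene_family_id))))
  invisible(x)
}

.write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE, na = "")
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  x <- fread(path, sep = "\t", header = TRUE, na.strings = "")
  if (!is.null(required) && !all(required %in% names(x)))
    stop(sprintf("%s lacks required column(s): %s", basename(path),
                 paste(setdiff(required, names(x)), collapse = ", ")))
  x
}

#' Write a simulated dataset to a directory of flat files
#'
#' Emits the tab-delimited dialects the pipeline readers consume:
#' `counts.tsv` (contig_id, length_bp, one integer column per sample),
#' `annotations.tsv`, `taxonomy.tsv`, `samples.tsv`, and optionally
#' `pathways.tsv`, `reference_presence.tsv` and the `truth.json` ledger.
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @param pathways optional pathway table.
#' @param presence optional reference presence matrix.
#' @param truth optional truth ledger (defaults to the community's).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(community, dir, pathways = NULL, presence = NULL,
                          truth = community$truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct <- community$contigs
  .write_tsv(cbind(ct$info[, .(contig_id, length_bp)],
                   as.data.table(ct$counts)), file.path(dir, "counts.tsv"))
  .write_tsv(ct$info[, .(contig_id, taxon_id, gene_family_id)],
             file.path(dir, "annotations.tsv"))
  .write_tsv(community$taxonomy, file.path(dir, "taxonomy.tsv"))
  .write_tsv(community$samples, file.path(dir, "samples.tsv"))
  if (!is.null(pathways))
    .write_tsv(pathways, file.path(dir, "pathways.tsv"))
  if (!is.null(presence)) {
    long <- data.table(
      ref_taxon_id = rep(rownames(presence), ncol(presence)),
      gene_family_id = rep(colnames(presence), each = nrow(presence)),
      present = as.integer(presence))
    .write_tsv(long, file.path(dir, "reference_presence.tsv"))
  }
  if (!is.null(truth)) write_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param design the sampling design the files were generated under; when
#'   NULL it is rebuilt from `samples.tsv`.
#' @export
read_dataset <- function(dir, design = NULL) {
  samples <- .read_tsv(file.path(dir, "samples.tsv"),
                       c("sample_id", "day", "hour", "replicate"))
  if (is.null(design))
    design <- make_design(unique(samples$hour), max(samples$day),
                          max(samples$replicate))
  cnt <- .read_tsv(file.path(dir, "counts.tsv"), c("contig_id", "length_bp"))
  ann <- .read_tsv(file.path(dir, "annotations.tsv"),
                   c("contig_id", "taxon_id", "gene_family_id"))
  taxonomy <- .read_tsv(file.path(dir, "taxonomy.tsv"),
                        c("taxon_id", "parent_id", "rank", "name"))
  info <- merge(cnt[, .(contig_id, length_bp)], ann, by = "contig_id",
                sort = FALSE)
  m <- as.matrix(cnt[, setdiff(names(cnt), c("contig_id", "length_bp")),
                     with = FALSE])
  rownames(m) <- cnt$contig_id
  out <- list(contigs = contig_table(info, m), taxonomy = taxonomy,
              samples = samples, design = design)
  pw <- file.path(dir, "pathways.tsv")
  if (file.exists(pw))
    out$pathways <- .read_tsv(pw, c("pathway_id", "gene_family_id"))
  rp <- file.path(dir, "reference_presence.tsv")
  if (file.exists(rp)) out$presence <- read_reference_presence(rp)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- read_truth(tj)
  out
}

#' Read a long-format reference presence file into a 0/1 matrix
#' @param path `reference_presence.tsv` path.
#' @export
read_reference_presence <- function(path) {
  long <- .read_tsv(path, c("ref_taxon_id", "gene_family_id", "present"))
  wide <- dcast(long, ref_taxon_id ~ gene_family_id, value.var = "present",
                fill = 0L)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$ref_taxon_id
  m
}

#' Serialize / read the ground-truth ledger
#' @param truth a truth ledger.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(families = truth$families, enrichments = truth$enrichments,
         core = truth$core),
    path, dataframe = "columns", na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_dt <- function(d, template) {
    if (length(d) == 0 || (is.list(d) && !length(d[[1]]))) return(template)
    as.data.table(d)
  }
  t0 <- .new_truth()
  structure(list(families = as_dt(x$families, t0$families),
                 enrichments = as_dt(x$enrichments, t0$enrichments),
                 core = as_dt(x$core, t0$core)), class = "truth_ledger")
}

#' Validate a directory of pipeline input tables
#'
#' Schema and referential-integrity checks: required columns per dialect,
#' count columns matching `samples.tsv`, annotation contigs present in
#' `counts.tsv`, annotation taxa present in `taxonomy.tsv`, pathway members
#' being plausible family ids. Returns a machine-readable issue list; an
#' empty table means the inputs validate.
#'
#' @param dir directory holding the input TSVs.
#' @return data.table with columns `table`, `issue`, `context`.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(tab, issue, context = "") {
    issues[[length(issues) + 1L]] <<- data.table(
      table = tab, issue = issue, context = context)
  }
  req <- list(
    counts.tsv = c("contig_id", "length_bp"),
    annotations.tsv = c("contig_id", "taxon_id", "gene_family_id"),
    taxonomy.tsv = c("taxon_id", "parent_id", "rank", "name"),
    samples.tsv = c("sample_id", "day", "hour", "replicate"))
  tabs <- list()
  for (f in names(req)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) { note(f, "file missing"); next }
    x <- fread(p, sep = "\t", header = TRUE, na.strings = "")
    miss <- setdiff(req[[f]], names(x))
    if (length(miss)) note(f, "missing column", paste(miss, collapse = ","))
    tabs[[f]] <- x
  }
  cnt <- tabs[["counts.tsv"]]; ann <- tabs[["annotations.tsv"]]
  tax <- tabs[["taxonomy.tsv"]]; smp <- tabs[["samples.tsv"]]
  if (!is.null(cnt) && !is.null(smp)) {
    cols <- setdiff(names(cnt), c("contig_id", "length_bp"))
    extra <- setdiff(cols, smp$sample_id)
    for (colname in extra)
      note("counts.tsv", "count column not in samples.tsv", colname)
    for (s in setdiff(smp$sample_id, cols))
      note("counts.tsv", "sample without count column", s)
  }
  if (!is.null(cnt) && "length_bp" %in% names(cnt) &&
      any(cnt$length_bp <= 0, na.rm = TRUE))
    note("counts.tsv", "non-positive contig length",
         cnt$contig_id[which(cnt$length_bp <= 0)[1]])
  if (!is.null(ann) && !is.null(cnt)) {
    unknown <- setdiff(ann$contig_id, cnt$contig_id)
    if (length(unknown))
      note("annotations.tsv", "contig not in counts.tsv", unknown[1])
  }
  if (!is.null(ann) && !is.null(tax)) {
    bad <- ann[!is.na(taxon_id) & !taxon_id %in% tax$taxon_id]
    if (nrow(bad))
      note("annotations.tsv", "annotation references unknown taxon",
           bad$contig_id[1])
  }
  if (!is.null(tax)) {
    orphans <- tax[!is.na(parent_id) & !parent_id %in% tax$taxon_id]
    if (nrow(orphans))
      note("taxonomy.tsv", "parent node missing", orphans$taxon_id[1])
  }
  pw <- file.path(dir, "pathways.tsv")
  if (file.exists(pw)) {
    x <- fread(pw, sep = "\t", header = TRUE, na.strings = "")
    if (!all(c("pathway_id", "gene_family_id") %in% names(x)))
      note("pathways.tsv", "missing column")
    else if (anyNA(x$gene_family_id))
      note("pathways.tsv", "empty gene family id")
  }
  if (length(issues)) rbindlist(issues) else
    data.table(table = character(), issue = character(), context = character())
}
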