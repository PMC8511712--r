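#' Build the (bin x time point) observation matrix
#'
#' One row per (bin, day-by-hour time point): the replicate-averaged FPKM
#' of every gene family. Columns (families) with a positive value in
#' strictly more than `prevalence` of the rows are retained; rows are then
#' normalized to sum to 1 (all-zero rows are kept as zero and flagged, so
#' the row bookkeeping -- e.g. 48 bins x 24 time points = 1,152
#' observations -- holds). Averaging precedes the prevalence filter, and
#' the filter precedes normalization; the two steps do not commute.
#'
#' @param ba a `bin_abundance`.
#' @param design the sampling design.
#' @param bins optional subset of bin taxon ids (default: all).
#' @param prevalence strict presence-fraction cutoff, default 0.05.
#' @return object of class `observation_matrix`: `values` (row-normalized
#'   matrix), `row_info` (taxon_id, day, hour), `families`,
#'   `zero_rows` (flags).
#' @export
build_observation_matrix <- function(ba, design, bins = NULL,
                                     prevalence = 0.05) {
  if (design$n_replicates < 1) stop("design must have replicates")
  if (is.null(bins)) bins <- unique(ba$keys$taxon_id)
  keep <- ba$keys$taxon_id %in% bins
  keys <- ba$keys[keep]
  vals <- ba$values[keep, , drop = FALSE]
  smp <- design$samples
  tp <- paste(smp$day, smp$hour)                      # day x hour time point
  tps <- unique(tp)
  # replicate means per time point (columns)
  avg <- sapply(tps, function(t1)
    rowMeans(vals[, which(tp == t1), drop = FALSE]))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1)
  # long -> rows = (bin, time point)
  bins_here <- sort(unique(keys$taxon_id))
  fams <- sort(unique(keys$gene_family_id))
  n_row <- length(bins_here) * length(tps)
  M <- matrix(0, n_row, length(fams),
              dimnames = list(NULL, fams))
  row_info <- data.table(
    taxon_id = rep(bins_here, each = length(tps)),
    day = rep(smp$day[match(tps, tp)], length(bins_here)),
    hour = rep(smp$hour[match(tps, tp)], length(bins_here)))
  row_of <- function(tx) (match(tx, bins_here) - 1L) * length(tps)
  for (tx in bins_here) {
    sel <- which(keys$taxon_id == tx)
    M[row_of(tx) + seq_along(tps),
      match(keys$gene_family_id[sel], fams)] <-
      t(avg[sel, , drop = FALSE])
  }
  pres <- colMeans(M > 0)
  M <- M[, pres > prevalence, drop = FALSE]
  rs <- rowSums(M)
  zero <- rs == 0
  M[!zero, ] <- M[!zero, , drop = FALSE] / rs[!zero]
  rownames(M) <- paste(row_info$taxon_id,
                       sprintf("d%d_h%02d", row_info$day, row_info$hour),
                       sep = "|")
  structure(list(values = M, row_info = row_info,
                 families = colnames(M), zero_rows = zero),
            class = "observation_matrix")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = 1 - 2 * sum_j min(u_j, v_j) / (sum_j u_j + sum_j v_j)`,
#' computed with vegan. Pairs where both rows are all-zero are undefined
#' under the formula; they are set to 0 and flagged. Bray-Curtis is
#' symmetric with range [0, 1] but does not satisfy the triangle
#' inequality in general.
#'
#' @param x an `observation_matrix` or a non-negative numeric matrix.
#' @return symmetric dissimilarity matrix with a `flagged_pairs` attribute
#'   counting double-zero pairs.
#' @export
bray_curtis <- function(x) {
  M <- if (inherits(x, "observation_matrix")) x$values else as.matrix(x)
  if (any(M < 0)) stop("Bray-Curtis requires non-negative values")
  # all-zero rows are legal here (flagged below); silence vegdist's caution
  d <- as.matrix(suppressWarnings(vegan::vegdist(M, method = "bray")))
  nan <- is.nan(d)
  d[nan] <- 0
  diag(d) <- 0
  attr(d, "flagged_pairs") <- sum(nan[upper.tri(nan)])
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via vegan's `metaMDS` with `trymax` random
#' restarts; the best-stress configuration is returned with centered
#' coordinates. Stress is on the 0-1 scale. Non-convergence across all
#' restarts is reported in the `converged` flag, never as an error.
#' Deterministic for a fixed `seed`.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension.
#' @param trymax random restarts.
#' @param seed integer seed.
#' @return object of class `nmds_result`: `points`, `stress`, `k`,
#'   `converged`, `trymax`, `seed`.
#' @export
nmds <- function(d, k = 3L, trymax = 100L, seed = 1L) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8) ||
      any(abs(diag(dm)) > 1e-8))
    stop("need a symmetric zero-diagonal dissimilarity matrix")
  if (k < 1) stop("k must be >= 1")
  n <- nrow(dm)
  if (n <= 2) {
    pts <- matrix(0, n, k)
    if (n == 2) pts[, 1] <- c(-dm[1, 2], dm[1, 2]) / 2
    rownames(pts) <- rownames(dm)
    return(structure(list(points = pts, stress = 0, k = k, converged = TRUE,
                          trymax = trymax, seed = seed),
                     class = "nmds_result"))
  }
  set.seed(as.integer(seed))
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  structure(list(points = pts, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged) || is.numeric(fit$converged) &&
                   all(fit$converged > 0),
                 trymax = trymax, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS k=%d: stress %.4f (%sconverged, trymax %d)\n",
              x$k, x$stress, if (x$converged) "" else "not ", x$trymax))
  invisible(x)
}

#' Per-bin NMDS ordinations
#'
#' Runs an independent ordination of each bin's (time point x family)
#' profile (24 observations in the default design), mirroring the
#' clock-like per-taxon layouts of diel communities. Reports mean and SD
#' of the per-bin stress values alongside the individual fits.
#'
#' @inheritParams build_observation_matrix
#' @param k embedding dimension (2 by convention for per-bin fits).
#' @param trymax restarts per bin.
#' @param seed integer seed.
#' @return list: `fits` (named list of `nmds_result`), `stress` table,
#'   `mean_stress`, `sd_stress`.
#' @export
per_bin_ordinations <- function(ba, design, bins = NULL, k = 2L,
                                trymax = 50L, seed = 1L, prevalence = 0.05) {
  if (is.null(bins)) bins <- sort(unique(ba$keys$taxon_id))
  fits <- list()
  for (i in seq_along(bins)) {
    om <- build_observation_matrix(ba, design, bins = bins[i],
                                   prevalence = prevalence)
    d <- bray_curtis(om)
    fits[[bins[i]]] <- nmds(d, k = k, trymax = trymax,
                            seed = as.integer(seed) + i)
  }
  st <- data.table(taxon_id = names(fits),
                   stress = vapply(fits, `[[`, 0, "stress"),
                   converged = vapply(fits, `[[`, TRUE, "converged"))
  list(fits = fits, stress = st,
       mean_stress = mean(st$stress), sd_stress = sd(st$stress))
}

#' Per-hour profile summary of one gene family in one bin
#'
#' Pools the `n_days x n_replicates` observations at each sampling hour
#' (n = 8 in the default design) and reports mean, standard error
#' (SD/sqrt(n)) and the min-max-normalized trace of the hourly means
#' (mapped to [0, 1]; a constant trace maps to 0.5 everywhere and is
#' flagged).
#'
#' @param ba a `bin_abundance`.
#' @param design the sampling design.
#' @param taxon_id bin id.
#' @param gene_family_id family id (must be present in the bin).
#' @return data.table: hour, n, mean, se, minmax; attribute `constant`.
#' @export
profile_summary <- function(ba, design, taxon_id, gene_family_id) {
  i <- which(ba$keys$taxon_id == taxon_id &
               ba$keys$gene_family_id == gene_family_id)
  if (length(i) != 1)
    stop(sprintf("family %s not present in bin %s", gene_family_id, taxon_id))
  vals <- ba$values[i, ]
  hours <- design$samples$hour[match(colnames(ba$values),
                                     design$samples$sample_id)]
  out <- rbindlist(lapply(design$times_of_day, function(h) {
    v <- vals[hours == h]
    data.table(hour = h, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)))
  }))
  rng <- range(out$mean)
  constant <- diff(rng) == 0
  out[, minmax := if (constant) 0.5 else (mean - rng[1]) / diff(rng)]
  setattr(out, "constant", constant)
  out[]
}
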