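#' Build pathway-by-time contingency tables for one bin
#'
#' For a sampling hour t, a family is "diel at t" when it is significantly
#' diel and its assigned peak is t. For each pathway with at least one
#' member detected in the bin, a 2x2 table partitions the bin's tested
#' family universe: a = in pathway and diel at t, b = in pathway not diel
#' at t, c = diel at t outside the pathway, d = neither. Pathways with no
#' member in the bin are removed before testing.
#'
#' @param rhythm data.table of rhythm results for one bin (columns
#'   `gene_family_id`, `is_diel`, `peak_hour`); its rows define the tested
#'   universe.
#' @param pathways long table `pathway_id`, `gene_family_id`.
#' @param hour the sampling hour t.
#' @param hours the design's times of day (for validation).
#' @param mode `"peak_at_t"` (default) or `"any_time"` (diel at any hour).
#' @return data.table: pathway_id, hour, a, b, c, d.
#' @export
build_contingency <- function(rhythm, pathways, hour, hours = NULL,
                              mode = c("peak_at_t", "any_time")) {
  mode <- match.arg(mode)
  if (!is.null(hours) && !hour %in% hours)
    stop(sprintf("hour %s is not a design sampling time", format(hour)))
  rhythm <- as.data.table(rhythm)
  universe <- unique(rhythm$gene_family_id)
  diel <- if (mode == "peak_at_t")
    rhythm[is_diel & !is.na(peak_hour) & peak_hour == hour, gene_family_id]
  else rhythm[is_diel == TRUE, gene_family_id]
  n_diel <- length(unique(diel))
  pw <- as.data.table(pathways)[gene_family_id %in% universe]
  if (nrow(pw) == 0)
    return(data.table(pathway_id = character(), hour = numeric(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer()))
  tab <- pw[, .(a = sum(gene_family_id %in% diel), n_in = .N),
            by = pathway_id]
  tab[, `:=`(hour = hour, b = n_in - a, c = n_diel - a,
             d = length(universe) - n_in - (n_diel - a))]
  tab[, n_in := NULL]
  setcolorder(tab, c("pathway_id", "hour", "a", "b", "c", "d"))
  tab[]
}

#' One-sided Fisher exact test for enrichment (vectorized)
#'
#' Upper hypergeometric tail
#' `p = P(X >= a)` for `X ~ Hypergeom(a+b, c+d, a+c)`, i.e. the chance of
#' seeing at least `a` diel members in the pathway given the margins. The
#' odds ratio is the unconditional cross-product `(a*d)/(b*c)` (infinite
#' when `b*c = 0` with `a*d > 0`).
#'
#' @param a,b,c,d table cells (vectors allowed).
#' @param alternative `"greater"` (default) or `"two.sided"` (sum of all
#'   hypergeometric outcomes no more probable than the observed table).
#' @return data.table with `odds_ratio` and `p`.
#' @export
fisher_greater <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("contingency cells must be non-negative")
  if (alternative == "greater") {
    p <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(a), function(i) {
      m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
      x <- max(0, k - nn):min(m, k)
      dens <- stats::dhyper(x, m, nn, k)
      sum(dens[dens <= stats::dhyper(a[i], m, nn, k) * (1 + 1e-7)])
    }, 0)
  }
  or <- ifelse(b * c > 0, (a * d) / (b * c),
               ifelse(a * d > 0, Inf, NA_real_))
  data.table(odds_ratio = or, p = pmin(1, p))
}

#' Pathway-by-time enrichment across all bins
#'
#' Enumerates one contingency table per (bin, sampling hour, pathway),
#' removes tables with no pathway member detected in the bin, tests each
#' retained table one-sided for over-representation of diel-at-t families,
#' and applies a single BH correction across all retained tables of the
#' run. Order-level runs are the same code path applied to rhythm results
#' computed on rolled-up bins.
#'
#' @param rhythm_results output of [detect_rhythms()] (any rank).
#' @param pathways long pathway membership table.
#' @param design the sampling design (supplies the hours).
#' @param alpha FDR level for the enriched flag.
#' @param mode diel-at-t semantics, see [build_contingency()].
#' @param alternative test sidedness, see [fisher_greater()].
#' @param exclude_pathways optional pathway ids to drop before testing.
#' @return list: `results` (taxon_id, hour, pathway_id, a, b, c, d,
#'   odds_ratio, p_raw, p_adjusted, enriched) and `summary` with counts
#'   `n_enumerated`, `n_retained`, `n_enriched`, `critical_p`.
#' @export
enrich_all <- function(rhythm_results, pathways, design, alpha = 0.05,
                       mode = c("peak_at_t", "any_time"),
                       alternative = "greater", exclude_pathways = NULL) {
  mode <- match.arg(mode)
  pathways <- as.data.table(pathways)
  if (!is.null(exclude_pathways))
    pathways <- pathways[!pathway_id %in% exclude_pathways]
  hours <- design$times_of_day
  bins <- unique(rhythm_results$taxon_id)
  n_enumerated <- length(bins) * length(hours) *
    length(unique(pathways$pathway_id))
  tabs <- list()
  for (tx in bins) {
    rb <- rhythm_results[taxon_id == tx]
    for (h in hours) {
      t1 <- build_contingency(rb, pathways, h, hours, mode)
      if (nrow(t1)) tabs[[length(tabs) + 1L]] <- cbind(taxon_id = tx, t1)
    }
  }
  if (!length(tabs)) {
    empty <- data.table(taxon_id = character(), hour = numeric(),
                        pathway_id = character(), a = integer(),
                        b = integer(), c = integer(), d = integer(),
                        odds_ratio = numeric(), p_raw = numeric(),
                        p_adjusted = numeric(), enriched = logical())
    return(list(results = empty,
                summary = list(n_enumerated = n_enumerated, n_retained = 0L,
                               n_enriched = 0L, critical_p = 0)))
  }
  res <- rbindlist(tabs)
  ft <- fisher_greater(res$a, res$b, res$c, res$d, alternative)
  res[, `:=`(odds_ratio = ft$odds_ratio, p_raw = ft$p)]
  bh <- bh_adjust(res$p_raw, alpha)
  res[, `:=`(p_adjusted = bh$p_adjusted, enriched = bh$is_discovery)]
  setcolorder(res, c("taxon_id", "hour", "pathway_id", "a", "b", "c", "d",
                     "odds_ratio", "p_raw", "p_adjusted", "enriched"))
  list(results = res[],
       summary = list(n_enumerated = n_enumerated, n_retained = nrow(res),
                      n_enriched = bh$k, critical_p = bh$critical_p))
}
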