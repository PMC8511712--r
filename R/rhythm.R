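# ---- umbrella rank test for diel periodicity -------------------------------
#
# The test screens each (bin, gene family) FPKM series for a 24-h rhythm of
# arbitrary waveform: for every candidate (peak, trough) placement on the
# cyclic hour axis, a Jonckheere-Terpstra-type umbrella statistic counts
# rank concordances along the rising arm (trough -> peak) and the falling
# arm (peak -> trough); the per-pattern permutation p-values are combined
# with a Bonferroni factor over the pattern family.

# cyclic index walk from `from` to `to` on 1..n
.cyc_seq <- function(from, to, n) {
  if (to >= from) from:to else c(from:n, 1:to)
}

#' Enumerate umbrella (peak, trough) patterns on a cyclic group axis
#'
#' For `G` time-of-day groups there are `G*(G-1)` distinct patterns: every
#' ordered (peak, trough) pair with peak != trough. The rising chain walks
#' the cyclic axis from trough to peak (both included); the falling chain
#' walks from peak back to trough, excluding the trough so that each group
#' pair is compared exactly once (Mack-Wolfe convention).
#'
#' @param n_groups number of time-of-day groups (>= 3).
#' @return list of `umbrella_pattern` objects in deterministic
#'   (peak, trough) order.
#' @examples
#' length(umbrella_patterns(6))  # 30
#' @export
umbrella_patterns <- function(n_groups) {
  if (n_groups < 3) stop("need at least 3 groups")
  pats <- list()
  for (peak in seq_len(n_groups)) for (trough in seq_len(n_groups)) {
    if (peak == trough) next
    rising <- .cyc_seq(trough, peak, n_groups)
    falling <- .cyc_seq(peak, trough, n_groups)
    falling <- falling[-length(falling)]
    pats[[length(pats) + 1L]] <- structure(
      list(peak_index = peak, trough_index = trough,
           rising_chain = rising, falling_chain = falling),
      class = "umbrella_pattern")
  }
  pats
}

# directed group pairs of a pattern; row (i, j) contributes U[i, j], the
# count of (x in group i) < (y in group j) with ties at 1/2
.pattern_dirpairs <- function(pattern) {
  out <- list()
  rp <- pattern$rising_chain
  if (length(rp) >= 2) {
    cmb <- combn(length(rp), 2)
    out[[1L]] <- cbind(rp[cmb[1, ]], rp[cmb[2, ]])
  }
  fp <- pattern$falling_chain
  if (length(fp) >= 2) {
    cmb <- combn(length(fp), 2)
    out[[length(out) + 1L]] <- cbind(fp[cmb[2, ]], fp[cmb[1, ]])
  }
  do.call(rbind, out)
}

# patterns as a 0/1 matrix over the G*G directed-pair cells
.pattern_matrix <- function(patterns, G) {
  P <- matrix(0, length(patterns), G * G)
  for (k in seq_along(patterns)) {
    dp <- .pattern_dirpairs(patterns[[k]])
    P[k, (dp[, 1] - 1L) * G + dp[, 2]] <- 1
  }
  P
}

# directed Mann-Whitney counts for many series at once.
# X: n_series x N value matrix; group: integer vector of group memberships.
# Returns n_series x (G*G) matrix, column (a-1)*G + b = U[a, b].
.umbrella_U <- function(X, group) {
  G <- max(group)
  idx <- split(seq_along(group), factor(group, levels = seq_len(G)))
  n <- nrow(X)
  U <- matrix(0, n, G * G)
  for (a in seq_len(G - 1L)) for (b in seq(a + 1L, G)) {
    ia <- idx[[a]]; ib <- idx[[b]]
    acc <- numeric(n)
    for (i in ia) {
      xi <- X[, i]
      for (j in ib) {
        xj <- X[, j]
        acc <- acc + (xi < xj) + 0.5 * (xi == xj)
      }
    }
    U[, (a - 1L) * G + b] <- acc
    U[, (b - 1L) * G + a] <- length(ia) * length(ib) - acc
  }
  U
}

.as_grouped <- function(grouped_series) {
  if (!is.list(grouped_series)) stop("grouped_series must be a list of numeric vectors")
  if (any(lengths(grouped_series) == 0)) stop("empty time-of-day group")
  grouped_series
}

#' Umbrella statistic of a grouped series under one pattern
#'
#' Sums, over ordered group pairs within the rising chain, the number of
#' observation pairs increasing in the expected direction (ties count 1/2),
#' plus the mirrored count over the falling chain. The attainable maximum
#' is the total number of compared observation pairs.
#'
#' @param grouped_series list of numeric vectors, one per time-of-day group
#'   in hour order.
#' @param pattern an [umbrella_patterns()] element.
#' @return list with `statistic` and `maximum`.
#' @export
umbrella_statistic <- function(grouped_series, pattern) {
  gs <- .as_grouped(grouped_series)
  group <- rep(seq_along(gs), lengths(gs))
  X <- matrix(unlist(gs, use.names = FALSE), nrow = 1)
  G <- length(gs)
  P <- .pattern_matrix(list(pattern), G)
  nn <- as.vector(outer(lengths(gs), lengths(gs)))  # column-major: n_a*n_b at (a-1)*G+b? see below
  # outer gives cell (a, b) at position (b-1)*G + a; rebuild explicitly
  nn <- numeric(G * G)
  for (a in seq_len(G)) for (b in seq_len(G))
    nn[(a - 1L) * G + b] <- length(gs[[a]]) * length(gs[[b]])
  list(statistic = as.vector(.umbrella_U(X, group) %*% t(P)),
       maximum = as.vector(P %*% nn))
}

# all permutations of 1..n as an (n! x n) matrix
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

#' Permutation p-value of the umbrella statistic for one pattern
#'
#' p = Pr(statistic >= observed) under random reassignment of the pooled
#' observations to groups with group sizes fixed. The exhaustive engine
#' enumerates all `n!` orderings (exact p); the Monte-Carlo engine samples
#' `n_perm` random permutations and uses the add-one estimator
#' `(r + 1)/(n_perm + 1)`.
#'
#' @inheritParams umbrella_statistic
#' @param null_engine `"auto"`, `"exhaustive"` or `"monte_carlo"`; auto
#'   picks exhaustive when `n! <= exhaustive_limit`.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed optional seed for the Monte-Carlo draw.
#' @param exhaustive_limit largest permutation count allowed for the
#'   exhaustive engine.
#' @return the p-value.
#' @export
pattern_pvalue <- function(grouped_series, pattern,
                           null_engine = c("auto", "exhaustive", "monte_carlo"),
                           n_perm = 10000L, seed = NULL,
                           exhaustive_limit = 1e6) {
  gs <- .as_grouped(grouped_series)
  null_engine <- match.arg(null_engine)
  values <- unlist(gs, use.names = FALSE)
  group <- rep(seq_along(gs), lengths(gs))
  N <- length(values)
  total <- factorial(N)
  if (null_engine == "auto")
    null_engine <- if (total <= exhaustive_limit) "exhaustive" else "monte_carlo"
  obs <- umbrella_statistic(gs, pattern)$statistic
  G <- length(gs)
  P <- .pattern_matrix(list(pattern), G)
  if (null_engine == "exhaustive") {
    if (total > exhaustive_limit)
      stop(sprintf("exhaustive null would require %.0f permutations (limit %g)",
                   total, exhaustive_limit))
    perms <- .all_perms(N)
    X <- matrix(values[perms], nrow(perms), N)
    stats <- as.vector(.umbrella_U(X, group) %*% t(P))
    mean(stats >= obs - 0.25)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))
    X <- matrix(values[perms], n_perm, N)
    stats <- as.vector(.umbrella_U(X, group) %*% t(P))
    (sum(stats >= obs - 0.25) + 1) / (n_perm + 1)
  }
}

#' Nonparametric rhythm test for one grouped series
#'
#' Scans all `G*(G-1)` umbrella patterns, computes each pattern's
#' permutation p-value (sharing one set of permutation draws across
#' patterns), and combines them with a Bonferroni factor:
#' `p_raw = min(1, n_patterns * min_p)`. The best pattern is the argmin,
#' ties broken by smaller peak then smaller trough index. The test depends
#' on the data only through ranks, so any strictly monotone transform of
#' the series leaves the result unchanged. A series with zero variance is
#' assigned `p_raw = 1` without permutation.
#'
#' @inheritParams pattern_pvalue
#' @param design optional [make_design()]; when given, group count is
#'   checked and the best pattern's peak is reported as an hour.
#' @return object of class `rain_result`: `p_raw`, `statistic`,
#'   `max_statistic`, `best_pattern`, `pattern_p`, `pattern_stats`,
#'   `group_means`, `peak_hour` (when `design` given), `engine`, `n_perm`.
#' @export
rain_test <- function(grouped_series, design = NULL, n_perm = 10000L,
                      seed = NULL,
                      null_engine = c("auto", "exhaustive", "monte_carlo"),
                      exhaustive_limit = 1e6) {
  gs <- .as_grouped(grouped_series)
  G <- length(gs)
  if (G < 3) stop("need at least 3 time-of-day groups")
  if (!is.null(design) && G != length(design$times_of_day))
    stop("series group count does not match the design")
  null_engine <- match.arg(null_engine)
  values <- unlist(gs, use.names = FALSE)
  group <- rep(seq_along(gs), lengths(gs))
  N <- length(values)
  patterns <- umbrella_patterns(G)
  P <- .pattern_matrix(patterns, G)
  nn <- numeric(G * G)
  for (a in seq_len(G)) for (b in seq_len(G))
    nn[(a - 1L) * G + b] <- length(gs[[a]]) * length(gs[[b]])
  maxs <- as.vector(P %*% nn)
  obs <- as.vector(.umbrella_U(matrix(values, nrow = 1), group) %*% t(P))
  group_means <- vapply(gs, mean, 0)
  res <- list(n_groups = G, group_means = group_means,
              pattern_stats = obs, max_statistic = NA_real_,
              n_perm = n_perm, engine = null_engine)
  if (diff(range(values)) == 0) {
    res$pattern_p <- rep(1, length(patterns))
    res$p_raw <- 1
    res$best_pattern <- NULL
    res$statistic <- NA_real_
    class(res) <- "rain_result"
    return(res)
  }
  total <- factorial(N)
  if (null_engine == "auto")
    null_engine <- if (total <= exhaustive_limit) "exhaustive" else "monte_carlo"
  if (null_engine == "exhaustive") {
    if (total > exhaustive_limit)
      stop(sprintf("exhaustive null would require %.0f permutations (limit %g)",
                   total, exhaustive_limit))
    perms <- .all_perms(N)
    null_stats <- .umbrella_U(matrix(values[perms], nrow(perms), N), group) %*% t(P)
    pp <- colMeans(sweep(null_stats, 2, obs - 0.25, ">="))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))
    null_stats <- .umbrella_U(matrix(values[perms], n_perm, N), group) %*% t(P)
    pp <- (colSums(sweep(null_stats, 2, obs - 0.25, ">=")) + 1) / (n_perm + 1)
  }
  best <- which.min(pp)   # patterns enumerated by (peak, trough): first min wins
  res$engine <- null_engine
  res$pattern_p <- pp
  res$p_raw <- min(1, length(patterns) * min(pp))
  res$best_pattern <- patterns[[best]]
  res$statistic <- obs[best]
  res$max_statistic <- maxs[best]
  if (!is.null(design))
    res$peak_hour <- design$times_of_day[patterns[[best]]$peak_index]
  class(res) <- "rain_result"
  res
}

#' @export
print.rain_result <- function(x, ...) {
  cat(sprintf("umbrella rhythm test: p_raw = %.4g, statistic %s/%s%s\n",
              x$p_raw, format(x$statistic), format(x$max_statistic),
              if (!is.null(x$peak_hour)) sprintf(", peak %02d:00", x$peak_hour)
              else ""))
  invisible(x)
}

# circular first-harmonic phase (in hours) of a set of hourly means
.harmonic_phase <- function(group_means, hours, period) {
  ang <- 2 * pi * hours / period
  (atan2(sum(group_means * sin(ang)), sum(group_means * cos(ang))) *
      period / (2 * pi)) %% period
}

.circ_dist <- function(a, b, period) {
  abs(((a - b + period / 2) %% period) - period / 2)
}

#' Assign the peak hour from a rhythm test
#'
#' The peak is the sampling hour of the best pattern's peak group. The
#' Monte-Carlo null cannot resolve p-values below `1/(n_perm + 1)`, so a
#' strongly rhythmic series leaves several patterns tied at the floor and
#' the argmin pattern is censored. Ties are therefore resolved by a phase
#' estimate: under the default `"harmonic"` rule the tied pattern whose
#' peak group lies nearest (on the cyclic clock) to the first-harmonic
#' (cosinor) phase of the hourly means wins; under `"pattern_mean"` the
#' tied pattern whose peak group has the largest mean abundance wins.
#' Remaining exact ties fall back to the largest peak-group mean and then
#' to the smaller peak index.
#'
#' @param result a [rain_test()] result.
#' @param hours the design's times of day (optional; index returned
#'   otherwise, and the harmonic rule needs them).
#' @param rule `"harmonic"` (default) or `"pattern_mean"`.
#' @param period rhythm period in hours.
#' @return list with `peak_index` and (when `hours` given) `peak_hour`.
#' @export
assign_peak <- function(result, hours = NULL,
                        rule = c("harmonic", "pattern_mean"), period = 24) {
  rule <- match.arg(rule)
  if (is.null(result$pattern_p) || is.null(result$best_pattern))
    stop("no pattern information in this result (constant series?)")
  G <- result$n_groups
  patterns <- umbrella_patterns(G)
  tied <- which(result$pattern_p <= min(result$pattern_p) + 1e-12)
  peaks <- vapply(patterns[tied], `[[`, 0L, "peak_index")
  if (rule == "harmonic" && !is.null(hours)) {
    phase <- .harmonic_phase(result$group_means, hours, period)
    dist <- .circ_dist(hours[peaks], phase, period)
    tied <- tied[dist <= min(dist) + 1e-9]
    peaks <- vapply(patterns[tied], `[[`, 0L, "peak_index")
  }
  score <- result$group_means[peaks]
  pick <- tied[which.max(score)]   # first max: smaller peak/trough on ties
  out <- list(peak_index = patterns[[pick]]$peak_index)
  if (!is.null(hours)) out$peak_hour <- hours[out$peak_index]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, `adjusted_i = min_{j >= i} (m/rank_j) p_j`
#' capped at 1. A test is a discovery when its adjusted p falls below
#' `alpha`; the critical p-value is `(k/m) * alpha` with `k` discoveries,
#' the largest raw p still called significant.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return list: `p_adjusted`, `is_discovery`, `k`, `m`, `critical_p`.
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.2, 0.9))$k
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  disc <- adj < alpha
  list(p_adjusted = adj, is_discovery = disc, k = sum(disc), m = length(p),
       critical_p = sum(disc) / length(p) * alpha)
}

#' Detect diel gene families across all bins of a bin abundance
#'
#' Batch umbrella testing of every (bin, gene family) FPKM series against
#' the sampling design, followed by one FDR correction across all series
#' (global scope by default, mirroring a single pooled test family) and
#' peak-hour assignment for significant families.
#'
#' The default engine draws one set of `n_perm` label permutations of a
#' tie-free rank vector and reuses its null statistic distribution for
#' every series; this is exact for tie-free data (the statistic is
#' rank-based and distribution-free) and conservative for series with tied
#' values, whose tie-adjusted statistic is stochastically narrower. The
#' `per_series` engine instead runs [rain_test()] on each series with its
#' own values.
#'
#' @param ba a `bin_abundance`.
#' @param design the [make_design()] the samples follow.
#' @param n_perm permutations for the Monte-Carlo null.
#' @param seed integer seed for the permutation draw.
#' @param alpha FDR level.
#' @param fdr_scope `"global"` (one BH across all bins, default) or
#'   `"per_bin"`.
#' @param engine `"shared_null"` (default) or `"per_series"`.
#' @param peak_rule tie-break rule for peak assignment, see
#'   [assign_peak()].
#' @return data.table with one row per (taxon_id, gene_family_id):
#'   `statistic`, `max_statistic`, `p_raw`, `p_adjusted`, `is_diel`,
#'   `peak_hour` (NA when not significant), `n_perm`, `seed`; attribute
#'   `critical_p`.
#' @export
detect_rhythms <- function(ba, design, n_perm = 10000L, seed = 1L,
                           alpha = 0.05, fdr_scope = c("global", "per_bin"),
                           engine = c("shared_null", "per_series"),
                           peak_rule = c("harmonic", "pattern_mean")) {
  fdr_scope <- match.arg(fdr_scope)
  engine <- match.arg(engine)
  peak_rule <- match.arg(peak_rule)
  hours <- design$samples$hour[match(colnames(ba$values),
                                     design$samples$sample_id)]
  if (anyNA(hours)) stop("abundance samples not found in the design")
  group <- .hour_group(design, hours)
  G <- length(design$times_of_day)
  if (G < 3) stop("need at least 3 times of day")
  X <- ba$values
  N <- ncol(X)
  n <- nrow(X)
  patterns <- umbrella_patterns(G)
  P <- .pattern_matrix(patterns, G)
  sizes <- tabulate(group, G)
  nn <- numeric(G * G)
  for (a in seq_len(G)) for (b in seq_len(G))
    nn[(a - 1L) * G + b] <- sizes[a] * sizes[b]
  maxs <- as.vector(P %*% nn)
  pat_peak <- vapply(patterns, `[[`, 0L, "peak_index")

  if (engine == "per_series") {
    rows <- lapply(seq_len(n), function(i) {
      gs <- split(X[i, ], factor(group, levels = seq_len(G)))
      r <- rain_test(gs, design, n_perm = n_perm, seed = seed,
                     null_engine = "monte_carlo")
      pk <- if (!is.null(r$best_pattern))
        assign_peak(r, design$times_of_day, rule = peak_rule,
                    period = design$period_hours)$peak_hour else NA_real_
      data.table(statistic = r$statistic,
                 max_statistic = r$max_statistic,
                 p_raw = r$p_raw, peak_hour = pk)
    })
    res <- cbind(copy(ba$keys), rbindlist(rows))
  } else {
    obs <- .umbrella_U(X, group) %*% t(P)
    set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(N), integer(N)))
    null_stats <- .umbrella_U(matrix(as.numeric(perms), n_perm, N), group) %*% t(P)
    p_mat <- matrix(NA_real_, n, length(patterns))
    for (j in seq_along(patterns)) {
      s <- sort(null_stats[, j])
      cnt_ge <- n_perm - findInterval(obs[, j] - 0.25, s)
      p_mat[, j] <- (cnt_ge + 1) / (n_perm + 1)
    }
    minp <- p_mat[, 1]
    for (j in seq(2, ncol(p_mat))) minp <- pmin(minp, p_mat[, j])
    praw <- pmin(1, length(patterns) * minp)
    constant <- .constant_rows(X)
    praw[constant] <- 1
    best <- max.col(-p_mat, ties.method = "first")
    # peak choice among patterns tied at the minimal p: harmonic rule first
    # narrows to peaks nearest the cosinor phase of the hourly means, then
    # the largest peak-group mean wins, then pattern order
    GM <- matrix(0, n, G)
    idx <- split(seq_along(group), factor(group, levels = seq_len(G)))
    for (g in seq_len(G)) GM[, g] <- rowMeans(X[, idx[[g]], drop = FALSE])
    tied <- p_mat <= minp + 1e-12
    score <- GM[, pat_peak, drop = FALSE]   # n x n_patterns peak-group means
    if (peak_rule == "harmonic") {
      ang <- 2 * pi * design$times_of_day / design$period_hours
      phase <- (atan2(GM %*% sin(ang), GM %*% cos(ang)) *
                  design$period_hours / (2 * pi)) %% design$period_hours
      D <- .circ_dist(
        matrix(design$times_of_day[pat_peak], n, length(patterns),
               byrow = TRUE),
        matrix(phase, n, length(patterns)), design$period_hours)
      D[!tied] <- Inf
      minD <- D[, 1]
      for (j in seq(2, ncol(D))) minD <- pmin(minD, D[, j])
      score[D > minD + 1e-9] <- -Inf
    } else {
      score[!tied] <- -Inf
    }
    pick <- max.col(score, ties.method = "first")
    res <- cbind(copy(ba$keys), data.table(
      statistic = obs[cbind(seq_len(n), best)],
      max_statistic = maxs[best],
      p_raw = praw,
      peak_hour = design$times_of_day[pat_peak[pick]]))
    res[constant, peak_hour := NA_real_]
  }
  if (fdr_scope == "global") {
    bh <- bh_adjust(res$p_raw, alpha)
    res[, p_adjusted := bh$p_adjusted]
    critical <- bh$critical_p
  } else {
    res[, p_adjusted := bh_adjust(p_raw, alpha)$p_adjusted, by = taxon_id]
    critical <- NA_real_
  }
  res[, is_diel := p_adjusted < alpha]
  res[is_diel == FALSE, peak_hour := NA_real_]
  res[, `:=`(n_perm = as.integer(n_perm), seed = as.integer(seed))]
  setcolorder(res, c("taxon_id", "gene_family_id", "statistic",
                     "max_statistic", "p_raw", "p_adjusted", "is_diel",
                     "peak_hour", "n_perm", "seed"))
  setattr(res, "critical_p", critical)
  res[]
}

# rows with zero variance
.constant_rows <- function(X) {
  apply(X, 1, function(r) diff(range(r)) == 0)
}
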