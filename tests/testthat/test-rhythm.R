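test_that("pattern enumeration covers every (peak, trough) pair once", {
  expect_length(umbrella_patterns(6), 30)
  expect_length(umbrella_patterns(3), 6)
  expect_error(umbrella_patterns(2), "3 groups")
  for (p in umbrella_patterns(6)) {
    expect_true(p$peak_index != p$trough_index)
    expect_gte(length(p$rising_chain), 1)
    expect_gte(length(p$falling_chain), 1)
    # chains jointly visit every group, sharing only the peak
    expect_setequal(c(p$rising_chain, p$falling_chain), 1:6)
    expect_equal(intersect(p$rising_chain, p$falling_chain), p$peak_index)
  }
  keys <- vapply(umbrella_patterns(6),
                 function(p) paste(p$peak_index, p$trough_index), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("the umbrella statistic counts directed rank concordances", {
  pats <- umbrella_patterns(3)
  pt <- Filter(function(p) p$peak_index == 2 && p$trough_index == 1, pats)[[1]]
  # perfect rise {1,2}->{3,4} and fall {3,4}->{2,1}: all 8 pairs concordant
  s <- umbrella_statistic(list(c(1, 2), c(3, 4), c(2, 1)), pt)
  expect_equal(s$statistic, 8)
  expect_equal(s$maximum, 8)
  # all-tied data sit exactly at half the maximum
  tied <- umbrella_statistic(list(c(5, 5), c(5, 5), c(5, 5)), pt)
  expect_equal(tied$statistic, tied$maximum / 2)
  expect_error(umbrella_statistic(list(c(1, 2), numeric(0), 3), pt), "empty")
})

test_that("statistic matches the naive oracle and is antisymmetric", {
  set.seed(21)
  for (rep in 1:10) {
    G <- sample(3:5, 1)
    gs <- lapply(seq_len(G), function(i) round(rnorm(sample(2:4, 1)), 1))
    for (pt in umbrella_patterns(G)[sample(G * (G - 1), 3)]) {
      s <- umbrella_statistic(gs, pt)
      expect_equal(s$statistic, naive_umbrella_stat(gs, pt))
      # sign flip maps S to max - S
      s2 <- umbrella_statistic(lapply(gs, function(v) -v), pt)
      expect_equal(s$statistic + s2$statistic, s$maximum)
    }
  }
})

test_that("exhaustive permutation p-values match full enumeration", {
  pats3 <- umbrella_patterns(3)
  pt <- Filter(function(p) p$peak_index == 2 && p$trough_index == 1, pats3)[[1]]
  # {1},{2},{1.5}: two of the 6 orderings attain the maximal statistic
  expect_equal(pattern_pvalue(list(1, 2, 1.5), pt, "exhaustive"), 1 / 3)
  expect_equal(naive_exhaustive_p(list(1, 2, 1.5), pt), 1 / 3)
  set.seed(31)
  for (rep in 1:4) {
    gs <- list(round(runif(2), 1), round(runif(2), 1), round(runif(2), 1))
    for (pt in pats3[c(1, 4)]) {
      expect_equal(pattern_pvalue(gs, pt, "exhaustive"),
                   naive_exhaustive_p(gs, pt))
    }
  }
  expect_error(pattern_pvalue(list(1:5, 1:5, 1:5), pats3[[1]], "exhaustive",
                              exhaustive_limit = 100), "permutations")
})

test_that("Monte-Carlo p-values agree with the exhaustive null", {
  pt <- umbrella_patterns(3)[[3]]
  set.seed(41)
  for (rep in 1:3) {
    gs <- list(rnorm(3), rnorm(2), rnorm(3))
    pex <- pattern_pvalue(gs, pt, "exhaustive")
    pmc <- pattern_pvalue(gs, pt, "monte_carlo", n_perm = 4000, seed = rep)
    tol <- 3 * sqrt(pex * (1 - pex) / 4000) + 1 / 4000
    expect_lt(abs(pmc - pex), tol + 1e-12)
  }
  # constant series: p = 1 under any engine
  expect_equal(pattern_pvalue(list(c(1, 1), c(1, 1), c(1, 1)), pt,
                              "exhaustive"), 1)
})

test_that("rain_test detects a noiseless diel cosine and is rank-invariant", {
  d <- default_design()
  hrs <- d$samples$hour
  gs <- split(10 * (1 + cos(2 * pi * (hrs - 6) / 24)),
              factor(hrs, levels = d$times_of_day))
  r <- rain_test(gs, d, n_perm = 2000, seed = 5)
  expect_lt(r$p_raw, 0.05)
  expect_equal(r$p_raw, min(1, 30 * min(r$pattern_p)))
  expect_equal(assign_peak(r, d$times_of_day)$peak_hour, 6)
  # strictly monotone transforms leave everything unchanged
  r2 <- rain_test(lapply(gs, function(v) exp(v / 3) + 100), d,
                  n_perm = 2000, seed = 5)
  expect_equal(r2$p_raw, r$p_raw)
  expect_equal(r2$statistic, r$statistic)
  expect_equal(assign_peak(r2, d$times_of_day)$peak_hour, 6)
  # zero-variance series are assigned p = 1 outright
  rc <- rain_test(split(rep(3, 48), factor(hrs, levels = d$times_of_day)), d)
  expect_equal(rc$p_raw, 1)
})

test_that("peak ties are broken by phase estimate then peak-group mean", {
  # fabricated result with two patterns tied at the minimal p
  pats <- umbrella_patterns(3)
  pp <- rep(1, 6)
  i1 <- which(vapply(pats, function(p) p$peak_index == 1 &&
                       p$trough_index == 2, TRUE))[1]
  i2 <- which(vapply(pats, function(p) p$peak_index == 2 &&
                       p$trough_index == 3, TRUE))[1]
  pp[c(i1, i2)] <- 0.001
  res <- structure(list(n_groups = 3L, pattern_p = pp,
                        group_means = c(5, 7, 1),
                        best_pattern = pats[[i1]]), class = "rain_result")
  # mean rule: the tied pattern whose peak group has mean 7 wins
  expect_equal(assign_peak(res, hours = c(0, 8, 16),
                           rule = "pattern_mean")$peak_hour, 8)
  # harmonic rule agrees here (phase pulled toward the heavy group)
  expect_equal(assign_peak(res, hours = c(0, 8, 16))$peak_hour, 8)
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(rep(1, 50))$k, 0L)
  expect_true(all(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$is_discovery))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(51)
  for (rep in 1:5) {
    p <- runif(200)^sample(1:3, 1)
    bh <- bh_adjust(p, 0.05)
    expect_equal(bh$p_adjusted, naive_bh(p))
    expect_equal(bh$k, sum(naive_bh(p) < 0.05))
    expect_true(all(bh$p_adjusted >= p - 1e-12))
  }
})

test_that("null series keep the advertised false-positive rate", {
  d <- default_design()
  cm <- generate_community(d, genus_spec("g", 300L, diel_fraction = 0),
                           seed = 61, unannotated_fraction = 0)
  ba <- quantify_bins(cm$contigs, cm$taxonomy, "genus")
  rh <- detect_rhythms(ba, d, n_perm = 1000, seed = 62)
  frac <- mean(rh$p_raw < 0.05)
  # Bonferroni over patterns makes the raw test conservative
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(rh)))
  expect_equal(sum(rh$is_diel), 0L)
})

test_that("detection power is non-decreasing in amplitude", {
  d <- default_design()
  rate <- vapply(c(0.2, 1.0), function(a) {
    cm <- generate_community(
      d, genus_spec("g", 100L, diel_fraction = 0.4, amplitude = a),
      seed = 71, unannotated_fraction = 0)
    ba <- quantify_bins(cm$contigs, cm$taxonomy, "genus")
    rh <- detect_rhythms(ba, d, n_perm = 4000, seed = 72)
    tr <- merge(rh, cm$truth$families,
                by = c("taxon_id", "gene_family_id"))
    mean(tr[is_diel.y == TRUE, is_diel.x])
  }, 0)
  expect_gte(rate[2], rate[1])
  expect_gt(rate[2], 0.9)
})

test_that("per-series and shared-null engines agree on strong signals", {
  d <- default_design()
  cm <- generate_community(
    d, genus_spec("g", 12L, diel_fraction = 0.5, amplitude = 1),
    seed = 81, unannotated_fraction = 0)
  ba <- quantify_bins(cm$contigs, cm$taxonomy, "genus")
  a <- detect_rhythms(ba, d, n_perm = 2000, seed = 82, engine = "shared_null")
  b <- detect_rhythms(ba, d, n_perm = 2000, seed = 82, engine = "per_series")
  # same calls, and p-values within Monte-Carlo resolution of each other
  agree <- abs(a$p_raw - b$p_raw) <
    3 * sqrt(pmax(a$p_raw, 1 / 2001) / 2000) * 30 + 30 / 2000
  expect_true(mean(agree) >= 0.9)
  both <- merge(a[is_diel == TRUE], b[is_diel == TRUE],
                by = c("taxon_id", "gene_family_id"))
  expect_gt(nrow(both), 0)
  expect_equal(both$peak_hour.x, both$peak_hour.y)
})
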