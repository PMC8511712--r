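#' Define a diel sampling design
#'
#' A diel design is a regular grid of sampling times-of-day repeated over
#' several days with replicate samples at each (day, time) point. Times are
#' stored on a `[0, period_hours)` clock, so 02:00 sorts before 06:00. The
#' default reproduces a 4-day, 4-hourly, duplicate-sample cruise design:
#' 6 times x 4 days x 2 replicates = 48 samples, with
#' `n_days * n_replicates = 8` observations per time-of-day group.
#'
#' @param times_of_day numeric hours on a 24-h clock; must be evenly spaced
#'   around the cycle (spacing `period_hours / length(times_of_day)`).
#' @param n_days number of consecutive sampling days.
#' @param n_replicates replicate samples per (day, time).
#' @param period_hours rhythm period, 24 for a diel design.
#' @return An object of class `diel_design`: the normalized hour grid plus a
#'   `samples` table enumerating sample ids as (day, hour, replicate) triples
#'   in deterministic order.
#' @examples
#' d <- make_design()
#' nrow(d$samples)    # 48
#' d$group_size       # 8
#' @export
make_design <- function(times_of_day = c(6, 10, 14, 18, 22, 2),
                        n_days = 4L, n_replicates = 2L, period_hours = 24) {
  if (!is.numeric(times_of_day) || length(times_of_day) < 2)
    stop("need at least two times of day")
  if (n_days < 1 || n_replicates < 1)
    stop("n_days and n_replicates must be >= 1")
  if (period_hours <= 0) stop("period_hours must be positive")
  hours <- sort(times_of_day %% period_hours)
  if (anyDuplicated(hours)) stop("times of day must be distinct on the clock")
  spacing <- period_hours / length(hours)
  gaps <- diff(c(hours, hours[1] + period_hours))
  bad <- which(abs(gaps - spacing) > 1e-8)
  if (length(bad)) {
    b <- bad[1]
    to <- if (b == length(hours)) hours[1] else hours[b + 1]
    stop(sprintf(
      "uneven sampling times: interval %g:00 -> %g:00 spans %g h, expected %g h",
      hours[b], to, gaps[b], spacing))
  }
  samples <- CJ(day = seq_len(n_days), hour = hours,
                replicate = seq_len(n_replicates), sorted = TRUE)
  samples[, sample_id := sprintf("d%d_h%02d_r%d", day, hour, replicate)]
  setcolorder(samples, c("sample_id", "day", "hour", "replicate"))
  structure(list(
    times_of_day = hours,
    n_days = as.integer(n_days),
    n_replicates = as.integer(n_replicates),
    period_hours = period_hours,
    n_samples = nrow(samples),
    group_size = as.integer(n_days) * as.integer(n_replicates),
    samples = samples[]
  ), class = "diel_design")
}

#' @export
print.diel_design <- function(x, ...) {
  cat(sprintf(
    "diel design: %d times of day (%s h), %d days x %d replicates = %d samples (%d per time group)\n",
    length(x$times_of_day), paste(x$times_of_day, collapse = ","),
    x$n_days, x$n_replicates, x$n_samples, x$group_size))
  invisible(x)
}

# map sample hours to 1-based group indices on the design's hour grid
.hour_group <- function(design, hours) {
  g <- match(hours %% design$period_hours, design$times_of_day)
  if (anyNA(g)) stop("sample hour not on the design grid")
  g
}
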