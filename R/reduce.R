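#' Savings from learning and relearning times
#'
#' Savings is the relative amount of time saved on relearning as a result
#' of the original learning: \eqn{Q = (S_1 - S_2) / S_1}, where \eqn{S_1}
#' is the time spent learning a list to criterion and \eqn{S_2} the time
#' spent relearning it after the retention interval. \eqn{Q = 1} when
#' relearning is instantaneous, 0 when it takes as long as learning, and
#' negative when relearning takes longer. The measure is scale-invariant:
#' measuring both times in other units leaves it unchanged.
#'
#' @param S1 first-learning time(s), seconds; must be positive.
#' @param S2 relearning time(s), seconds; must be non-negative.
#' @return Dimensionless savings, same length as the inputs.
#' @examples
#' savings(1405, 670)    # 0.523
#' savings(1440, 1510)   # negative: relearning took longer
#' @export
savings <- function(S1, S2) {
  if (any(S1 <= 0)) stop("learning time S1 must be positive", call. = FALSE)
  if (any(S2 < 0)) stop("relearning time S2 must be >= 0", call. = FALSE)
  (S1 - S2) / S1
}

#' Aggregate per-list learning records into a savings curve
#'
#' Computes per-list savings and summarizes them within each retention
#' interval, yielding one curve point per interval together with the
#' per-interval standard deviation of per-list savings and the list count.
#'
#' Two summary conventions are offered. `"pooled"` (the default) computes
#' the interval's savings from the mean times,
#' \eqn{\bar Q = (\bar S_1 - \bar S_2)/\bar S_1} — this is the convention
#' behind the published per-interval averages this package's fixtures
#' reproduce. `"mean_q"` averages the per-list savings values instead. The
#' two differ in the third decimal on real data (e.g. 0.315 vs 0.312 at
#' the 1-day interval of the bundled records); see the methods vignette.
#'
#' @param records a data frame of learning records with columns
#'   `interval_seconds`, `S1_seconds`, `S2_seconds` (as read by
#'   [read_learning_records()] or produced by [simulate_experiment()]).
#' @param subject label for the resulting curve.
#' @param method `"pooled"` (savings of the mean times) or `"mean_q"`
#'   (mean of per-list savings).
#' @return A [savings_curve()] with columns `t_seconds`, `savings`, `sd`,
#'   `n`. Intervals with no records are dropped.
#' @examples
#' recs <- load_fixture("table2")
#' aggregate_savings(recs, subject = "Dros")
#' @export
aggregate_savings <- function(records, subject = "subject",
                              method = c("pooled", "mean_q")) {
  stopifnot(all(c("interval_seconds", "S1_seconds", "S2_seconds") %in%
                  names(records)))
  method <- match.arg(method)
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  q <- savings(records$S1_seconds, records$S2_seconds)
  idx <- split(seq_len(nrow(records)), records$interval_seconds)
  t <- as.numeric(names(idx))
  o <- order(t)
  qbar <- vapply(idx, function(i) {
    if (method == "pooled") {
      savings(mean(records$S1_seconds[i]), mean(records$S2_seconds[i]))
    } else {
      mean(q[i])
    }
  }, 0)
  savings_curve(
    t[o], qbar[o],
    subject = subject,
    sd = vapply(idx, function(i)
      if (length(i) > 1) stats::sd(q[i]) else 0, 0)[o],
    n = vapply(idx, length, 0L)[o]
  )
}

#' Linear drift of learning time over the experimental calendar
#'
#' Ordinary least-squares regression of first-learning time on the
#' calendar day of first learning, per list. A positive slope indicates
#' that lists learned later in the experiment took longer to learn
#' (commonly attributed to proactive interference or fatigue); it biases
#' savings downward at long retention intervals when those lists were
#' learned early.
#'
#' @param records data frame with columns `S1_seconds` and `day` (calendar
#'   day index of first learning).
#' @return List with `slope` (seconds/day), `intercept` (seconds),
#'   `r_squared` (proportion of variance explained), `n`, and the
#'   underlying [stats::lm()] fit as `fit`.
#' @examples
#' recs <- simulate_experiment("power", c(1.5, 0.15), drift = 2.67, seed = 1)
#' drift_fit(recs)$slope
#' @export
drift_fit <- function(records) {
  stopifnot(all(c("S1_seconds", "day") %in% names(records)))
  records <- records[is.finite(records$day), ]
  if (nrow(records) < 3) stop("need at least 3 records with a day",
                              call. = FALSE)
  if (length(unique(records$day)) < 2) {
    stop("all records share one day; drift is not identifiable",
         call. = FALSE)
  }
  fit <- stats::lm(S1_seconds ~ day, data = records)
  list(slope = unname(stats::coef(fit)[["day"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = summary(fit)$r.squared,
       n = nrow(records), fit = fit)
}

#' Drift-corrected savings
#'
#' Recomputes savings after inflating the first-learning time by the
#' estimated drift accumulated over the retention interval:
#' \eqn{Q' = (S_1^* - S_2)/S_1^*} with
#' \eqn{S_1^* = S_1 + slope \cdot (interval\ in\ days)}. The rationale: had
#' the list been first learned when it was relearned, learning would have
#' taken about \eqn{S_1^*} seconds, so \eqn{Q'} compares relearning against
#' a contemporaneous baseline. This is one plausible reading of the
#' correction; see the methods vignette.
#'
#' @param S1,S2 learning and relearning times in seconds.
#' @param interval_seconds retention interval in seconds.
#' @param slope drift slope in seconds per day (non-negative).
#' @return Corrected savings.
#' @examples
#' drift_corrected_savings(1684, 1532, 31 * 86400, 2.67)  # about 0.133
#' @export
drift_corrected_savings <- function(S1, S2, interval_seconds, slope) {
  if (any(slope < 0)) stop("drift slope must be >= 0", call. = FALSE)
  S1_star <- S1 + slope * interval_seconds / 86400
  if (any(S1_star <= 0)) stop("corrected S1 must be positive", call. = FALSE)
  savings(S1_star, S2)
}

#' Time-of-day correction of learning times
#'
#' Normalizes learning times recorded in later daily sessions to the
#' morning baseline: session A (morning) is left unchanged, 5% is
#' subtracted for session B (noon) and 13% for session C (evening),
#' reflecting the classically observed faster learning in the morning.
#'
#' @param S learning time(s) in seconds.
#' @param session session label(s): `"A"`, `"B"` or `"C"` (recycled
#'   against `S`).
#' @return Corrected time(s) in seconds.
#' @examples
#' timeofday_correction(1000, "C")  # 870
#' @export
timeofday_correction <- function(S, session) {
  factor <- c(A = 1, B = 0.95, C = 0.87)[as.character(session)]
  if (any(is.na(factor))) {
    stop("unknown session label; use A, B or C", call. = FALSE)
  }
  unname(S * factor)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way independent ANOVA from per-group size, mean
#' and standard deviation (no raw data needed):
#' \eqn{SS_b = \sum_i n_i (m_i - \bar m)^2} with \eqn{\bar m} the weighted
#' grand mean, \eqn{SS_w = \sum_i (n_i - 1) s_i^2}, degrees of freedom
#' \eqn{(g - 1, N - g)}, \eqn{F = MS_b / MS_w}, and the p-value from the
#' upper tail of the F distribution.
#'
#' @param n integer vector of group sizes (each at least 2).
#' @param mean group means.
#' @param sd group standard deviations.
#' @return List of class `summary_anova` with `F`, `df_between`,
#'   `df_within`, `p`, and the mean squares.
#' @examples
#' tab1 <- load_fixture("table1")
#' anova_from_summary(tab1$n, tab1$learning_mean, tab1$learning_sd)
#' @export
anova_from_summary <- function(n, mean, sd) {
  g <- length(n)
  stopifnot(length(mean) == g, length(sd) == g)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  N <- sum(n)
  gm <- sum(n * mean) / N
  ss_b <- sum(n * (mean - gm)^2)
  ss_w <- sum((n - 1) * sd^2)
  df_b <- g - 1
  df_w <- N - g
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  F <- if (ms_w == 0) Inf else ms_b / ms_w
  structure(list(F = F, df_between = df_b, df_within = df_w,
                 p = stats::pf(F, df_b, df_w, lower.tail = FALSE),
                 ms_between = ms_b, ms_within = ms_w),
            class = "summary_anova")
}

#' @export
print.summary_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA from summary statistics: F(%d, %d) = %.3f, p = %.3f\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Read and write learning-record CSV files
#'
#' The on-disk format is a CSV with columns
#' `list_id,interval_seconds,S1_seconds,S2_seconds` and optional `day`
#' (calendar day of first learning) and `session` (A/B/C) columns.
#'
#' @param file path to a CSV file.
#' @param records a learning-record data frame.
#' @return `read_learning_records()`: a data frame;
#'   `write_learning_records()`: `file`, invisibly.
#' @export
read_learning_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("list_id", "interval_seconds", "S1_seconds", "S2_seconds")
  if (!all(need %in% names(df))) {
    stop("learning-record CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$S1_seconds <= 0)) stop("S1_seconds must be positive",
                                    call. = FALSE)
  df
}

#' @rdname read_learning_records
#' @export
write_learning_records <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
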