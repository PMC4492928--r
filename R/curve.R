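#' Savings curves
#'
#' A savings curve is one subject's sequence of (retention interval,
#' savings) observations — the unit of model fitting. It is stored as a
#' data frame with columns `t_seconds` and `savings` (optionally `sd` and
#' `n` when the points are per-interval averages) and a `subject`
#' attribute.
#'
#' Retention intervals must be strictly increasing and positive; at least
#' two points are required. Savings values need not lie in \[0, 1\]
#' (negative observed savings are legitimate: relearning can take longer
#' than learning).
#'
#' @param t_seconds retention intervals in seconds, strictly increasing.
#' @param savings observed savings at each interval.
#' @param subject subject label.
#' @param sd,n optional per-point standard deviation and number of lists
#'   (carried along by [aggregate_savings()]).
#' @param x object to coerce or print.
#' @param ... further arguments passed on.
#' @return A data frame of class `savings_curve`.
#' @examples
#' savings_curve(c(1200, 3600, 86400), c(0.58, 0.44, 0.34), "demo")
#' @export
savings_curve <- function(t_seconds, savings, subject = "subject",
                          sd = NULL, n = NULL) {
  t_seconds <- as.numeric(t_seconds)
  savings <- as.numeric(savings)
  if (length(t_seconds) != length(savings)) {
    stop("t_seconds and savings must have equal length", call. = FALSE)
  }
  if (length(t_seconds) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(t_seconds)) || any(t_seconds <= 0)) {
    stop("retention intervals must be positive and finite", call. = FALSE)
  }
  if (any(diff(t_seconds) <= 0)) {
    stop("retention intervals must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(t_seconds = t_seconds, savings = savings)
  if (!is.null(sd)) out$sd <- as.numeric(sd)
  if (!is.null(n)) out$n <- as.integer(n)
  attr(out, "subject") <- as.character(subject)
  class(out) <- c("savings_curve", "data.frame")
  out
}

#' @rdname savings_curve
#' @export
as_savings_curve <- function(x, subject = NULL) {
  if (inherits(x, "savings_curve")) {
    if (!is.null(subject)) attr(x, "subject") <- subject
    return(x)
  }
  if (!is.data.frame(x) || !all(c("t_seconds", "savings") %in% names(x))) {
    stop("need a data frame with columns t_seconds and savings",
         call. = FALSE)
  }
  x <- x[order(x$t_seconds), , drop = FALSE]
  savings_curve(x$t_seconds, x$savings,
                subject = subject %||%
                  (if ("subject" %in% names(x)) x$subject[[1]] else "subject"),
                sd = if ("sd" %in% names(x)) x$sd,
                n = if ("n" %in% names(x)) x$n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname savings_curve
#' @export
print.savings_curve <- function(x, ...) {
  cat(sprintf("Savings curve '%s' (%d retention intervals)\n",
              attr(x, "subject"), nrow(x)))
  df <- as.data.frame(x)
  df$interval <- format_interval(df$t_seconds)
  print(df[, c("interval", setdiff(names(df), "interval"))],
        row.names = FALSE, ...)
  invisible(x)
}

#' Canonical retention-interval sets
#'
#' The seven canonical retention intervals of the classical savings
#' paradigm, in seconds. Under the `"replication"` convention the short
#' intervals are 20 min, 1 h and 9 h; under the `"stated"` convention they
#' are the corrected values 19 min, 63 min and 8.75 h that Ebbinghaus
#' reports for his own study. The long intervals (1, 2, 6, 31 days) are
#' common to both.
#'
#' @param convention `"replication"` (default) or `"stated"`.
#' @return Numeric vector of seven interval lengths in seconds.
#' @examples
#' canonical_intervals()
#' canonical_intervals("stated")
#' @export
canonical_intervals <- function(convention = c("replication", "stated")) {
  convention <- match.arg(convention)
  days <- c(1, 2, 6, 31) * 86400
  short <- switch(convention,
    replication = c(20 * 60, 3600, 9 * 3600),
    stated = c(19 * 60, 63 * 60, 525 * 60)
  )
  c(short, days)
}

# interval label <-> seconds, used by fixtures and printing
.interval_labels <- c("20 min" = 1200, "1 hour" = 3600, "9 hours" = 32400,
                      "1 day" = 86400, "2 days" = 172800,
                      "6 days" = 518400, "31 days" = 2678400)

format_interval <- function(t_seconds) {
  vapply(t_seconds, function(t) {
    hit <- names(.interval_labels)[match(t, .interval_labels)]
    if (!is.na(hit)) return(hit)
    if (t < 3600) sprintf("%g min", t / 60)
    else if (t < 86400) sprintf("%g hours", t / 3600)
    else sprintf("%g days", t / 86400)
  }, "")
}

#' Normalize a savings curve to its first point
#'
#' Rescales a curve so that its first (shortest-interval) savings value is
#' exactly 1, the transformation used to overlay curves from different
#' subjects for visual comparison.
#'
#' @param curve a [savings_curve()] (or data frame coercible to one).
#' @return A `savings_curve` with all savings divided by the first point's
#'   savings.
#' @examples
#' dros <- load_fixture("table3")$Dros
#' normalize_curve(dros)
#' @export
normalize_curve <- function(curve) {
  curve <- as_savings_curve(curve)
  q1 <- curve$savings[[1]]
  if (q1 == 0) {
    stop("first point has zero savings; cannot normalize", call. = FALSE)
  }
  curve$savings <- curve$savings / q1
  if (!is.null(curve$sd)) curve$sd <- curve$sd / abs(q1)
  curve
}

#' Read and write savings-curve CSV files
#'
#' The on-disk format is a UTF-8 CSV with header
#' `subject,t_seconds,savings` ('.' decimal separator). A file may hold
#' several subjects; one curve per subject is returned.
#'
#' @param file path to a CSV file.
#' @param curves a single `savings_curve` or a (named) list of them.
#' @return `read_savings_curves()`: a named list of [savings_curve()]
#'   objects. `write_savings_curves()`: `file`, invisibly.
#' @export
read_savings_curves <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject", "t_seconds", "savings")
  if (!all(need %in% names(df))) {
    stop("savings-curve CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$subject), function(d) {
    d <- d[order(d$t_seconds), ]
    savings_curve(d$t_seconds, d$savings, subject = d$subject[[1]])
  })
  out[unique(df$subject)]
}

#' @rdname read_savings_curves
#' @export
write_savings_curves <- function(curves, file) {
  if (inherits(curves, "savings_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(subject = attr(cu, "subject"),
               t_seconds = cu$t_seconds, savings = cu$savings)
  }))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
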