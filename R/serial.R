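#' Serial-position analysis of relearning recall
#'
#' Lists in the savings paradigm are rows of 13 syllables; recall at first
#' relearning shows the classic serial-position pattern: near-ceiling
#' performance at the first (primacy) and last (recency) positions and
#' poorer, time-sensitive performance in the middle.
#'
#' `position_curves()` tabulates the proportion of correct recalls per
#' retention interval and serial position. Scoring leniency (counting a
#' syllable correct even when produced at the wrong position) is the
#' caller's upstream responsibility.
#'
#' @param records data frame of recall records with columns
#'   `interval_seconds`, `row_id`, `position` (1..13) and `correct` (0/1
#'   or logical).
#' @param n_positions number of serial positions (default 13).
#' @return A data frame of class `serial_position_table` with columns
#'   `interval_seconds`, `position`, `n_trials`, `n_correct`,
#'   `proportion`. Cells with no trials are reported with `proportion =
#'   NA`.
#' @examples
#' rec <- simulate_serial(trials = 50, seed = 1)
#' tab <- position_curves(rec)
#' group_slopes(tab)
#' @export
position_curves <- function(records, n_positions = 13) {
  stopifnot(all(c("interval_seconds", "position", "correct") %in%
                  names(records)))
  if (any(records$position < 1 | records$position > n_positions |
            records$position != round(records$position))) {
    stop(sprintf("positions must be integers in 1..%d", n_positions),
         call. = FALSE)
  }
  intervals <- sort(unique(records$interval_seconds))
  grid <- expand.grid(position = seq_len(n_positions),
                      interval_seconds = intervals)[, 2:1]
  key <- interaction(records$interval_seconds, records$position, drop = FALSE)
  gkey <- interaction(grid$interval_seconds, grid$position)
  grid$n_trials <- as.integer(table(factor(key, levels = levels(gkey)))[
    as.character(gkey)])
  corr <- tapply(as.numeric(records$correct), factor(key, levels = levels(gkey)),
                 sum)
  grid$n_correct <- as.integer(ifelse(is.na(corr[as.character(gkey)]), 0,
                                      corr[as.character(gkey)]))
  grid$proportion <- ifelse(grid$n_trials > 0,
                            grid$n_correct / grid$n_trials, NA_real_)
  class(grid) <- c("serial_position_table", "data.frame")
  grid
}

#' Default serial-position groups
#'
#' The partition of positions 1..13 used to contrast flat primacy and
#' recency segments with the time-sensitive middle of the list.
#'
#' @return Named list of integer vectors: `1-2`, `3-8`, `9-10`, `11-13`.
#' @export
serial_position_groups <- function() {
  list(`1-2` = 1:2, `3-8` = 3:8, `9-10` = 9:10, `11-13` = 11:13)
}

#' Forgetting slopes for groups of serial positions
#'
#' For each group of serial positions, regresses the group-mean proportion
#' correct on the retention interval (expressed in days, untransformed —
#' no logarithmic axis) and reports the ordinary least-squares slope. An
#' `all` row gives the slope of the mean over every position. Missing
#' cells are excluded pairwise.
#'
#' @param table a `serial_position_table` from [position_curves()].
#' @param groups named list of position vectors (default
#'   [serial_position_groups()]); must partition the positions.
#' @return Data frame with columns `group`, `slope` (proportion per day),
#'   `intercept`, `n_intervals`.
#' @export
group_slopes <- function(table, groups = serial_position_groups()) {
  stopifnot(inherits(table, "serial_position_table") || is.data.frame(table))
  if (length(unique(table$interval_seconds)) < 2) {
    stop("need at least 2 retention intervals for a slope", call. = FALSE)
  }
  positions <- sort(unique(table$position))
  covered <- sort(unlist(groups))
  if (!identical(as.integer(covered), as.integer(positions))) {
    stop("groups must partition the serial positions", call. = FALSE)
  }
  groups <- c(groups, list(all = positions))
  out <- lapply(names(groups), function(g) {
    sub <- table[table$position %in% groups[[g]], ]
    m <- tapply(sub$proportion, sub$interval_seconds,
                function(x) mean(x, na.rm = TRUE))
    days <- as.numeric(names(m)) / 86400
    ok <- is.finite(m)
    if (sum(ok) < 2) {
      return(data.frame(group = g, slope = NA_real_, intercept = NA_real_,
                        n_intervals = sum(ok)))
    }
    fit <- stats::lm(y ~ d, data = data.frame(y = m[ok], d = days[ok]))
    data.frame(group = g, slope = unname(stats::coef(fit)[["d"]]),
               intercept = unname(stats::coef(fit)[["(Intercept)"]]),
               n_intervals = sum(ok))
  })
  do.call(rbind, out)
}

#' Read recall-record CSV files
#'
#' Columns: `interval_seconds,row_id,position,correct` with `correct`
#' coded 0/1.
#'
#' @param file path to a CSV file.
#' @return A data frame suitable for [position_curves()].
#' @export
read_recall_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("interval_seconds", "row_id", "position", "correct")
  if (!all(need %in% names(df))) {
    stop("recall CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
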