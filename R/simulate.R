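#' Simulate a savings (relearning) experiment
#'
#' Generates per-list learning records emulating the single-subject
#' relearning design: for each retention interval a number of lists is
#' first learned (learning time drawn from a normal distribution, with an
#' optional linear drift over the experimental calendar) and later
#' relearned; observed savings is the true retention function plus
#' Gaussian observation noise, and the relearning time is derived from it.
#'
#' Concretely, with first-learning day `d` drawn uniformly over the
#' experiment length: `S1 ~ Normal(S1_mean + drift * d, S1_sd)` truncated
#' below at 300 s; `Q_obs = Q_true(t) + Normal(0, noise_sd)`;
#' `S2 = S1 * (1 - Q_obs)` truncated below at 60 s (the truncations keep
#' times physically meaningful; with the default noise they are almost
#' never active). Output is deterministic given `seed`.
#'
#' Defaults mirror the replication study's conditions: 10 lists per
#' interval at the seven canonical intervals, learning times around 1840 s
#' with a spread of 150 s, observation noise of 0.03 on savings, a 75-day
#' experiment, and no drift unless requested.
#'
#' @param model,pars true retention law and its parameters (any model of
#'   [retention_models()]).
#' @param intervals retention intervals in seconds.
#' @param lists_per_interval number of lists learned per interval.
#' @param S1_mean,S1_sd mean and SD of first-learning time, seconds.
#' @param noise_sd SD of additive Gaussian observation noise on savings.
#' @param drift linear increase of learning time, seconds per day.
#' @param experiment_days length of the experimental phase in days.
#' @param seed integer seed; the same seed reproduces the records exactly.
#' @return A learning-record data frame with columns `list_id`,
#'   `interval_seconds`, `S1_seconds`, `S2_seconds`, `day`, ready for
#'   [aggregate_savings()] and [drift_fit()]. The seed is stored in
#'   `attr(, "seed")`.
#' @examples
#' recs <- simulate_experiment("power", c(mu1 = 1.5, a1 = 0.15), seed = 1)
#' aggregate_savings(recs)
#' @export
simulate_experiment <- function(model = "power", pars,
                                intervals = canonical_intervals(),
                                lists_per_interval = 10,
                                S1_mean = 1840, S1_sd = 150,
                                noise_sd = 0.03, drift = 0,
                                experiment_days = 75, seed = 0) {
  stopifnot(lists_per_interval >= 1, S1_sd >= 0, noise_sd >= 0,
            experiment_days > 0)
  if (drift > 0 && any(intervals / 86400 > experiment_days)) {
    warning("some retention intervals exceed the experiment length; ",
            "records are generated anyway")
  }
  q_true <- retention_q(model, intervals, pars)
  with_seed(seed, {
    rows <- lapply(seq_along(intervals), function(i) {
      m <- lists_per_interval
      day <- stats::runif(m, 0, experiment_days)
      S1 <- pmax(300, stats::rnorm(m, S1_mean + drift * day, S1_sd))
      q_obs <- q_true[i] + stats::rnorm(m, 0, noise_sd)
      S2 <- pmax(60, S1 * (1 - q_obs))
      data.frame(list_id = seq_len(m), interval_seconds = intervals[i],
                 S1_seconds = S1, S2_seconds = S2, day = day)
    })
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a single noisy savings curve
#'
#' The curve-level counterpart of [simulate_experiment()]: evaluates the
#' true retention law at the given intervals and adds independent Gaussian
#' noise to each savings value.
#'
#' @inheritParams simulate_experiment
#' @param subject label for the generated curve.
#' @return A [savings_curve()].
#' @examples
#' simulate_savings_curve("power_boost", c(2.13, 0.194, 0.131),
#'                        noise_sd = 0.02, seed = 3)
#' @export
simulate_savings_curve <- function(model = "power", pars,
                                   intervals = canonical_intervals(),
                                   noise_sd = 0.03, seed = 0,
                                   subject = "simulated") {
  q <- retention_q(model, intervals, pars)
  obs <- with_seed(seed, q + stats::rnorm(length(q), 0, noise_sd))
  savings_curve(intervals, obs, subject = subject)
}

#' Simulate serial-position recall records
#'
#' Generates per-cell recall counts emulating the serial-position
#' structure of relearning recall: each position group has a baseline
#' proportion correct that decays linearly in time at a per-group rate,
#' and each (interval, position) cell draws
#' `Binomial(trials, clamp(baseline - decay * t_days, 0, 1))` successes.
#' The default profile has flat, near-ceiling primacy (positions 1-2) and
#' recency (11-13) groups and time-decaying middle positions — the
#' qualitative pattern seen in relearning recall data.
#'
#' @param baseline named numeric vector of baseline proportions, one per
#'   group of [serial_position_groups()].
#' @param decay named numeric vector of decay rates (proportion per day,
#'   non-negative), one per group.
#' @param trials number of recall trials per (interval, position) cell.
#' @param intervals retention intervals in seconds.
#' @param groups named list of position vectors.
#' @param seed integer seed.
#' @return A recall-record data frame with columns `interval_seconds`,
#'   `row_id`, `position`, `correct`, suitable for [position_curves()].
#' @examples
#' rec <- simulate_serial(trials = 100, seed = 2)
#' group_slopes(position_curves(rec))
#' @export
simulate_serial <- function(baseline = c(`1-2` = 0.95, `3-8` = 0.55,
                                         `9-10` = 0.60, `11-13` = 0.92),
                            decay = c(`1-2` = 0, `3-8` = 0.01,
                                      `9-10` = 0.01, `11-13` = 0),
                            trials = 100,
                            intervals = canonical_intervals(),
                            groups = serial_position_groups(),
                            seed = 0) {
  stopifnot(all(baseline >= 0 & baseline <= 1), all(decay >= 0),
            trials >= 1)
  if (!setequal(names(baseline), names(groups)) ||
      !setequal(names(decay), names(groups))) {
    stop("baseline and decay must be named after the position groups",
         call. = FALSE)
  }
  pos_group <- character(0)
  for (g in names(groups)) pos_group[as.character(groups[[g]])] <- g
  positions <- sort(unlist(groups))
  with_seed(seed, {
    rows <- list()
    for (t in intervals) {
      t_days <- t / 86400
      for (pos in positions) {
        g <- pos_group[[as.character(pos)]]
        p <- min(max(baseline[[g]] - decay[[g]] * t_days, 0), 1)
        correct <- stats::rbinom(trials, 1, p)
        rows[[length(rows) + 1L]] <- data.frame(
          interval_seconds = t, row_id = seq_len(trials),
          position = pos, correct = correct)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    out
  })
}
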