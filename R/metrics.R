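#' Session load in arbitrary units (sRPE)
#'
#' Internal training load of a single session: duration in minutes multiplied
#' by the session rating of perceived exertion on the Borg CR-10 scale
#' (e.g. a 60-minute session rated 4 yields 240 AU). Vectorised.
#'
#' @param duration_min Session duration in minutes (non-negative).
#' @param rpe Session RPE on the CR-10 scale, in \[0, 10\]; half-point
#'   ratings are accepted.
#' @return Numeric vector of session loads in arbitrary units (AU).
#' @examples
#' session_load(60, 4) # 240 AU
#' @export
session_load <- function(duration_min, rpe) {
  if (!is.numeric(duration_min) || !is.numeric(rpe)) {
    abort_invalid("`duration_min` and `rpe` must be numeric.")
  }
  if (any(duration_min < 0, na.rm = TRUE)) {
    abort_invalid("`duration_min` must be non-negative.")
  }
  if (any(rpe < 0 | rpe > 10, na.rm = TRUE)) {
    abort_invalid("`rpe` must lie in [0, 10] (Borg CR-10).")
  }
  duration_min * rpe
}

#' Acute (weekly) load of one player-week
#'
#' Sum of the session loads over one week for one player. All records must
#' belong to the same player and week; an empty record set yields 0 AU.
#'
#' @param sessions Data frame with columns `player_id`, `week`,
#'   `duration_min`, `rpe` (one player-week of session records).
#' @return Acute load in AU (scalar).
#' @export
acute_load <- function(sessions) {
  check_session_cols(sessions)
  if (nrow(sessions) == 0) {
    return(0)
  }
  if (dplyr::n_distinct(sessions$player_id) > 1 ||
    dplyr::n_distinct(sessions$week) > 1) {
    abort_invalid("`sessions` must contain a single player-week.")
  }
  sum(session_load(sessions$duration_min, sessions$rpe))
}

#' Cumulative load over the trailing k weeks
#'
#' @param weekly_acute Ordered numeric vector of weekly acute loads
#'   (oldest first, last element = current week).
#' @param k Number of trailing weeks to sum, in 1..4.
#' @return Sum of the last `k` weekly acute loads, in AU.
#' @export
cumulative_load <- function(weekly_acute, k) {
  if (!k %in% 1:4) abort_invalid("`k` must be 1, 2, 3 or 4.")
  if (length(weekly_acute) < k) {
    abort_undefined(sprintf(
      "cumulative load over %d weeks needs %d trailing weeks; got %d.",
      k, k, length(weekly_acute)
    ))
  }
  sum(tail(weekly_acute, k))
}

#' Chronic load (4-week rolling average of acute load)
#'
#' Arithmetic mean of the last four weekly acute loads. By the coupled
#' convention the current week is included in the window.
#'
#' @inheritParams cumulative_load
#' @return Chronic load in AU.
#' @export
chronic_load <- function(weekly_acute) {
  if (length(weekly_acute) < 4) {
    abort_undefined("chronic load needs at least 4 trailing weeks.")
  }
  mean(tail(weekly_acute, 4))
}

#' Acute:chronic workload ratio
#'
#' @param acute Acute load, AU.
#' @param chronic Chronic load, AU; must be positive.
#' @return Dimensionless ratio acute / chronic.
#' @export
acwr <- function(acute, chronic) {
  if (any(chronic <= 0, na.rm = TRUE)) {
    abort_undefined("ACWR is undefined for non-positive chronic load.")
  }
  acute / chronic
}

#' Randomised-denominator workload ratio (ACWRr)
#'
#' Null comparator for the ACWR: the acute load divided by a random
#' denominator gamma drawn once per observation from
#' Normal(`denominator_mean`, `denominator_sd`^2), so that the ratio retains
#' no information about the player's own chronic state. Draws at or below
#' `floor` AU are rejected and redrawn to keep the denominator positive.
#'
#' @param acute Acute load(s), AU (non-negative).
#' @param denominator_mean Mean of the random denominator, AU. The default
#'   1900 AU is the squad-level median chronic load scale.
#' @param denominator_sd Standard deviation of the random denominator, AU
#'   (default 730, the squad-level acute-load spread).
#' @param floor Positivity floor in AU; draws `<= floor` are redrawn.
#' @param seed Integer seed for the denominator draws. Required.
#' @return Numeric vector of ACWRr values, one per element of `acute`.
#' @export
acwrr <- function(acute, denominator_mean = 1900, denominator_sd = 730,
                  floor = 50, seed) {
  if (missing(seed) || is.null(seed)) {
    abort_invalid("`seed` is required: ACWRr has a random denominator.")
  }
  if (denominator_sd <= 0) abort_invalid("`denominator_sd` must be positive.")
  if (any(acute < 0, na.rm = TRUE)) abort_invalid("`acute` must be non-negative.")
  gamma <- withr::with_seed(
    as.integer(seed),
    draw_truncated_normal(length(acute), denominator_mean, denominator_sd, floor)
  )
  acute / gamma
}

# Rejection sampling of Normal(mean, sd^2) truncated to (floor, Inf).
draw_truncated_normal <- function(n, mean, sd, floor) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= floor)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= floor]
  }
  x
}

#' Training monotony of one week
#'
#' Mean daily load divided by the standard deviation of the daily loads
#' (sample SD, n-1 denominator). High monotony indicates low day-to-day
#' variation in training.
#'
#' @param daily_loads Numeric vector of daily loads (AU) for the week;
#'   at least two days.
#' @return Dimensionless monotony index.
#' @export
monotony <- function(daily_loads) {
  daily_loads <- daily_loads[!is.na(daily_loads)]
  if (length(daily_loads) < 2) {
    abort_invalid("monotony needs at least two days with defined load.")
  }
  s <- sd(daily_loads)
  if (s == 0) {
    abort_undefined("monotony is undefined for constant daily load (SD = 0).")
  }
  mean(daily_loads) / s
}

#' Fit a quartile binning to pooled metric values
#'
#' Cut points are the 25th/50th/75th empirical percentiles
#' (linear-interpolation convention). Assignment is upper-inclusive: a value
#' equal to a cut point falls in the lower bin.
#'
#' @param values Pooled metric values (at least 4 distinct).
#' @param metric_name Label for the metric being binned.
#' @return An object of class `quantile_binning` with elements `cut_points`
#'   (length 3) and `metric_name`.
#' @export
fit_quantile_binning <- function(values, metric_name = "metric") {
  values <- values[!is.na(values)]
  if (dplyr::n_distinct(values) < 4) {
    abort_invalid("quartile binning needs at least 4 distinct values.")
  }
  cp <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(cut_points = cp, metric_name = metric_name),
    class = "quantile_binning"
  )
}

#' Assign values to quartile groups
#'
#' @param binning A `quantile_binning` fitted by [fit_quantile_binning()].
#' @param values Values to assign.
#' @return Integer vector of group labels in 1..4 (NA propagates).
#' @export
bin_values <- function(binning, values) {
  stopifnot(inherits(binning, "quantile_binning"))
  cp <- binning$cut_points
  1L + (values > cp[1]) + (values > cp[2]) + (values > cp[3])
}

#' @export
print.quantile_binning <- function(x, ...) {
  cat(sprintf(
    "Quartile binning of %s: cut points %.4g / %.4g / %.4g\n",
    x$metric_name, x$cut_points[1], x$cut_points[2], x$cut_points[3]
  ))
  invisible(x)
}

check_session_cols <- function(sessions) {
  needed <- c("player_id", "week", "duration_min", "rpe")
  missing_cols <- setdiff(needed, names(sessions))
  if (length(missing_cols) > 0) {
    abort_invalid(sprintf(
      "session table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(sessions)
}

#' Per player-week load metrics
#'
#' Collapses a session log to one row per player-week on each player's full
#' calendar-week grid (first to last recorded week). Weeks without any
#' session are absence/unrecorded weeks: they appear with `trained = FALSE`
#' and acute load NA, and they break the rolling windows, so cumulative and
#' chronic loads are only defined where the player trained in every week of
#' the window.
#'
#' @param sessions Session log: `player_id`, `week`, `day`, `duration_min`,
#'   `rpe`.
#' @param coupled If `TRUE` (default) the chronic window is the current week
#'   plus the three preceding weeks; if `FALSE` (uncoupled) it is the four
#'   weeks strictly before the current one.
#' @return Tibble with one row per player-week: acute, cumulative (2-4 wk),
#'   chronic loads, ACWR and monotony.
#' @export
weekly_loads <- function(sessions, coupled = TRUE) {
  check_session_cols(sessions)
  if (!"day" %in% names(sessions)) {
    abort_invalid("session table is missing column(s): day.")
  }
  if (nrow(sessions) == 0) {
    return(tibble(
      player_id = character(), week = integer(), trained = logical(),
      n_sessions = integer(), acute_load = double(),
      cumulative_load_2w = double(), cumulative_load_3w = double(),
      cumulative_load_4w = double(), chronic_load = double(),
      acwr = double(), monotony = double()
    ))
  }

  per_week <- sessions %>%
    mutate(.load = session_load(.data$duration_min, .data$rpe)) %>%
    group_by(.data$player_id, .data$week) %>%
    summarise(
      n_sessions = dplyr::n(),
      acute_load = sum(.data$.load),
      monotony = weekly_monotony(.data$day, .data$.load),
      .groups = "drop"
    )

  grid <- per_week %>%
    group_by(.data$player_id) %>%
    dplyr::reframe(week = seq(min(.data$week), max(.data$week)))

  out <- grid %>%
    left_join(per_week, by = c("player_id", "week")) %>%
    mutate(trained = !is.na(.data$acute_load)) %>%
    group_by(.data$player_id) %>%
    arrange(.data$week, .by_group = TRUE) %>%
    mutate(
      cumulative_load_2w = zoo::rollsumr(.data$acute_load, 2, fill = NA),
      cumulative_load_3w = zoo::rollsumr(.data$acute_load, 3, fill = NA),
      cumulative_load_4w = zoo::rollsumr(.data$acute_load, 4, fill = NA),
      chronic_load = if (coupled) {
        .data$cumulative_load_4w / 4
      } else {
        lag(.data$cumulative_load_4w) / 4
      },
      acwr = if_else(
        !is.na(.data$chronic_load) & .data$chronic_load > 0,
        .data$acute_load / .data$chronic_load,
        NA_real_
      )
    ) %>%
    ungroup() %>%
    select(
      "player_id", "week", "trained", "n_sessions", "acute_load",
      "cumulative_load_2w", "cumulative_load_3w", "cumulative_load_4w",
      "chronic_load", "acwr", "monotony"
    )
  out
}

# Monotony from session records of one week: daily totals over the 7
# calendar days, rest days counted as 0 AU (Foster convention); NA when the
# daily SD is 0.
weekly_monotony <- function(day, load) {
  daily <- rep(0, 7)
  agg <- tapply(load, factor(day, levels = 1:7), sum)
  daily[!is.na(agg)] <- agg[!is.na(agg)]
  s <- sd(daily)
  if (is.na(s) || s == 0) {
    return(NA_real_)
  }
  mean(daily) / s
}

#' Build the player-week observation table
#'
#' The analysis table behind everything downstream: one row per player-week
#' with a complete 4-week training history, carrying acute/cumulative/
#' chronic loads, ACWR, the randomised-denominator ACWRr, quartile labels
#' for acute load, ACWR and ACWRr (quartiles of the pooled observation
#' rows), and `injured` = TRUE when the player has an injury onset in the
#' following week. Weeks without a complete window (early season, absence
#' or unrecorded weeks within the window) are excluded. Injuries whose
#' preceding week has no observation row cannot be attached and trigger a
#' warning.
#'
#' @inheritParams weekly_loads
#' @param injuries Injury records: `player_id`, `onset_week` and optionally
#'   `days_lost`.
#' @param acwrr_mean,acwrr_sd,acwrr_floor Parameters of the ACWRr random
#'   denominator, AU (see [acwrr()]).
#' @param seed Integer seed for the ACWRr denominator draws. Required.
#' @return Tibble of observation rows (class `acwr_observations`).
#' @export
build_observation_table <- function(sessions, injuries = NULL,
                                    coupled = TRUE,
                                    acwrr_mean = 1900, acwrr_sd = 730,
                                    acwrr_floor = 50, seed = NULL) {
  if (is.null(seed)) {
    abort_invalid("`seed` is required (ACWRr has a random denominator).")
  }
  if (is.null(injuries) || nrow(injuries) == 0) {
    injuries <- tibble(
      player_id = character(), onset_week = integer(), days_lost = double()
    )
  }
  if (!all(c("player_id", "onset_week") %in% names(injuries))) {
    abort_invalid("injury table needs columns player_id, onset_week.")
  }
  unknown <- setdiff(injuries$player_id, unique(sessions$player_id))
  if (length(unknown) > 0) {
    abort_invalid(sprintf(
      "injury record references unknown player(s): %s.",
      paste(unknown, collapse = ", ")
    ))
  }

  weekly <- weekly_loads(sessions, coupled = coupled)
  obs <- weekly %>%
    filter(.data$trained, !is.na(.data$chronic_load), .data$chronic_load > 0)

  obs$acwrr <- acwrr(obs$acute_load,
    denominator_mean = acwrr_mean,
    denominator_sd = acwrr_sd, floor = acwrr_floor, seed = seed
  )

  injury_key <- injuries %>%
    mutate(pred_week = .data$onset_week - 1L) %>%
    distinct(.data$player_id, .data$pred_week)
  obs <- obs %>%
    mutate(injured = paste(.data$player_id, .data$week) %in%
      paste(injury_key$player_id, injury_key$pred_week))

  matched <- paste(injury_key$player_id, injury_key$pred_week) %in%
    paste(obs$player_id, obs$week)
  if (any(!matched)) {
    warn(
      sprintf(
        "%d injur%s could not be attached to an observation row (no complete 4-week history in the preceding week) and do not appear as injured rows.",
        sum(!matched), if (sum(!matched) == 1) "y" else "ies"
      ),
      class = "acwrbayes_warning_unattached_injury"
    )
  }

  for (m in c("acute_load", "acwr", "acwrr")) {
    qcol <- paste0(sub("_load", "", m), "_quantile")
    b <- tryCatch(fit_quantile_binning(obs[[m]], metric_name = m),
      acwrbayes_error_invalid_input = function(e) NULL
    )
    if (is.null(b)) {
      warn(
        sprintf("too few distinct %s values to form quartiles; labels set to NA.", m),
        class = "acwrbayes_warning_binning"
      )
      obs[[qcol]] <- NA_integer_
    } else {
      obs[[qcol]] <- bin_values(b, obs[[m]])
      attr(obs, paste0("binning_", m)) <- b
    }
  }
  class(obs) <- c("acwr_observations", class(obs))
  obs
}
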