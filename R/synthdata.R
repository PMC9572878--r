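#' Configuration for the synthetic team season
#'
#' Describes a professional squad followed over one season: a core of
#' players tracked for a full year and a second group tracked for half a
#' season, logging sRPE for every session. Defaults are calibrated so that
#' the pooled weekly acute load has median near 1800 AU with IQR near
#' (1400, 2308) AU, the observation table holds roughly 815 player-weeks,
#' and a baseline weekly injury probability of 0.037 yields roughly 30
#' time-loss injuries per season.
#'
#' @param n_players_full Players followed for `weeks_full` weeks (default 12).
#' @param n_players_half Players followed for `weeks_half` weeks (default 23).
#' @param weeks_full,weeks_half Follow-up lengths in weeks (52 and 26).
#' @param sessions_per_week Integer vector of admissible weekly session
#'   counts, sampled uniformly (default 5:7).
#' @param duration_mean,duration_sd Session duration, minutes (70, 15).
#' @param rpe_mean,rpe_sd Session RPE on CR-10 (4.3, 1.5); draws are rounded
#'   to the nearest 0.5 and clipped to \[1, 10\].
#' @param load_autocorrelation AR(1) coefficient of the weekly log-load
#'   multiplier, in \[0, 1) (default 0.6): training periodisation makes
#'   adjacent weeks similar.
#' @param load_week_sd Stationary SD of the weekly log-load multiplier
#'   (default 0.30); together with session-level noise this sets the ACWR
#'   spread.
#' @param player_sd Between-player SD of the log-load level (default 0.08).
#' @param missing_week_prob Probability that a player-week goes unrecorded
#'   (matches away, illness, data-collection gaps; default 0.04). Missing
#'   weeks break rolling windows and drive the reduction from nominal
#'   player-weeks to complete observation rows.
#' @param injury_model One of `"null"`, `"acute_dependent"`,
#'   `"acwr_dependent"`: whether the injury hazard depends on the quartile
#'   of acute load, of ACWR, or on nothing.
#' @param baseline_weekly_injury_prob Weekly injury probability at the
#'   centre of the quartile scale (default 0.037).
#' @param effect_log_odds_per_quantile Log-odds increment per quartile step
#'   away from the centre (default 0; only used by the dependent models).
#' @param days_lost_meanlog,days_lost_sdlog Log-normal time-loss duration
#'   (median 10 days).
#' @param seed Integer seed; mandatory.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_players_full = 12, n_players_half = 23,
                             weeks_full = 52, weeks_half = 26,
                             sessions_per_week = 5:7,
                             duration_mean = 70, duration_sd = 15,
                             rpe_mean = 4.3, rpe_sd = 1.5,
                             load_autocorrelation = 0.6,
                             load_week_sd = 0.30,
                             player_sd = 0.08,
                             missing_week_prob = 0.04,
                             injury_model = c("null", "acute_dependent", "acwr_dependent"),
                             baseline_weekly_injury_prob = 0.037,
                             effect_log_odds_per_quantile = 0,
                             days_lost_meanlog = log(10),
                             days_lost_sdlog = 0.5,
                             seed = NULL) {
  injury_model <- match.arg(injury_model)
  if (is.null(seed)) abort_invalid("`seed` is mandatory in synthetic_config().")
  if (load_autocorrelation < 0 || load_autocorrelation >= 1) {
    abort_invalid("`load_autocorrelation` must lie in [0, 1).")
  }
  if (baseline_weekly_injury_prob < 0 || baseline_weekly_injury_prob > 1 ||
    missing_week_prob < 0 || missing_week_prob > 1) {
    abort_invalid("probabilities must lie in [0, 1].")
  }
  if (n_players_full < 0 || n_players_half < 0 ||
    (n_players_full + n_players_half) == 0) {
    abort_invalid("player counts must be non-negative and not both zero.")
  }
  structure(
    list(
      n_players_full = n_players_full, n_players_half = n_players_half,
      weeks_full = weeks_full, weeks_half = weeks_half,
      sessions_per_week = sessions_per_week,
      duration_mean = duration_mean, duration_sd = duration_sd,
      rpe_mean = rpe_mean, rpe_sd = rpe_sd,
      load_autocorrelation = load_autocorrelation,
      load_week_sd = load_week_sd, player_sd = player_sd,
      missing_week_prob = missing_week_prob,
      injury_model = injury_model,
      baseline_weekly_injury_prob = baseline_weekly_injury_prob,
      effect_log_odds_per_quantile = effect_log_odds_per_quantile,
      days_lost_meanlog = days_lost_meanlog,
      days_lost_sdlog = days_lost_sdlog,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Simulate a season of session records
#'
#' Each player gets a persistent log-load level, a weekly AR(1) log-load
#' multiplier, and per-session durations/RPEs; some weeks go unrecorded.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return Session tibble: `player_id`, `week`, `day`, `duration_min`, `rpe`.
#' @export
simulate_sessions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_sessions_impl(config))
}

simulate_sessions_impl <- function(config) {
  n_weeks <- c(
    rep(config$weeks_full, config$n_players_full),
    rep(config$weeks_half, config$n_players_half)
  )
  players <- sprintf("P%02d", seq_along(n_weeks))
  phi <- config$load_autocorrelation
  innov_sd <- config$load_week_sd * sqrt(1 - phi^2)

  res <- vector("list", length(players))
  for (i in seq_along(players)) {
    nw <- n_weeks[i]
    level <- rnorm(1, 0, config$player_sd)
    z <- numeric(nw)
    z[1] <- rnorm(1, 0, config$load_week_sd)
    for (w in seq_len(nw)[-1]) z[w] <- phi * z[w - 1] + rnorm(1, 0, innov_sd)
    recorded <- runif(nw) >= config$missing_week_prob

    weeks <- list()
    for (w in seq_len(nw)) {
      if (!recorded[w]) next
      ns <- if (length(config$sessions_per_week) == 1) {
        config$sessions_per_week
      } else {
        sample(config$sessions_per_week, 1)
      }
      if (ns == 0) next
      mult <- exp(level + z[w])
      duration <- pmax(20, rnorm(ns, config$duration_mean * mult, config$duration_sd))
      rpe <- round(2 * pmin(10, pmax(1, rnorm(ns, config$rpe_mean, config$rpe_sd)))) / 2
      days <- sort(sample(1:7, ns, replace = ns > 7))
      weeks[[length(weeks) + 1]] <- tibble(
        player_id = players[i], week = w, day = days,
        duration_min = duration, rpe = rpe
      )
    }
    res[[i]] <- bind_rows(weeks)
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      player_id = character(), week = integer(), day = integer(),
      duration_min = double(), rpe = double()
    )
  }
  out
}

#' Simulate injury onsets from an observation table
#'
#' Walks each player's observation rows in week order and draws a Bernoulli
#' injury onset for the following week with
#' `logit(p) = logit(baseline) + effect * (quantile - 2.5)` where the
#' quantile is that of acute load or ACWR per `config$injury_model`
#' (constant baseline under the null model). At most one injury can be open
#' per player: rows during the time-loss absence cannot produce a new
#' onset. Deterministic given `config$seed`.
#'
#' @param observations Observation table from [build_observation_table()].
#' @param config A [synthetic_config()].
#' @return Injury tibble: `player_id`, `onset_week`, `days_lost`.
#' @export
simulate_injuries <- function(observations, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, simulate_injuries_impl(observations, config))
}

simulate_injuries_impl <- function(observations, config) {
  qcol <- switch(config$injury_model,
    null = NULL,
    acute_dependent = "acute_quantile",
    acwr_dependent = "acwr_quantile"
  )
  base_logit <- qlogis(config$baseline_weekly_injury_prob)
  obs <- observations %>% arrange(.data$player_id, .data$week)

  out <- list()
  open_until <- list() # player -> last week of current absence
  for (r in seq_len(nrow(obs))) {
    pid <- obs$player_id[r]
    wk <- obs$week[r]
    until <- open_until[[pid]]
    if (!is.null(until) && wk <= until) next
    eta <- base_logit
    if (!is.null(qcol)) {
      eta <- eta + config$effect_log_odds_per_quantile * (obs[[qcol]][r] - 2.5)
    }
    if (rbinom(1, 1, plogis(eta)) == 1) {
      days_lost <- rlnorm(1, config$days_lost_meanlog, config$days_lost_sdlog)
      onset <- wk + 1L
      out[[length(out) + 1]] <- tibble(
        player_id = pid, onset_week = onset, days_lost = days_lost
      )
      open_until[[pid]] <- onset + ceiling(days_lost / 7) - 1L
    }
  }
  if (length(out) == 0) {
    return(tibble(
      player_id = character(), onset_week = integer(), days_lost = double()
    ))
  }
  bind_rows(out)
}

#' Simulate a full team season (sessions + injuries)
#'
#' Generates the session log, derives the provisional observation table,
#' draws injuries from it, and removes the sessions of absence weeks
#' (onset week until return, per drawn time loss) so the returned log
#' reflects the injuries. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `sessions`, `injuries` and `config`.
#' @export
simulate_team_season <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sessions <- simulate_sessions(config)
  if (nrow(sessions) == 0) {
    return(list(
      sessions = sessions,
      injuries = tibble(
        player_id = character(), onset_week = integer(), days_lost = double()
      ),
      config = config
    ))
  }
  provisional <- suppressWarnings(build_observation_table(
    sessions,
    injuries = NULL, seed = config$seed + 2L
  ))
  injuries <- simulate_injuries(provisional, config)

  if (nrow(injuries) > 0) {
    absence <- injuries %>%
      mutate(last_week = .data$onset_week + ceiling(.data$days_lost / 7) - 1L)
    keep <- rep(TRUE, nrow(sessions))
    for (j in seq_len(nrow(absence))) {
      keep <- keep & !(sessions$player_id == absence$player_id[j] &
        sessions$week >= absence$onset_week[j] &
        sessions$week <= absence$last_week[j])
    }
    sessions <- sessions[keep, ]
  }
  list(sessions = sessions, injuries = injuries, config = config)
}
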