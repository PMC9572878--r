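# Shared fixtures, built in code.

# A small deterministic session log: one player, 5 recorded weeks,
# 2 sessions/week with known loads.
toy_sessions <- function() {
  tibble::tibble(
    player_id = "A",
    week = rep(1:5, each = 2),
    day = rep(c(2L, 5L), 5),
    duration_min = rep(c(60, 90), 5),
    rpe = rep(c(5, 6), 5) # weekly acute load = 300 + 540 = 840 AU
  )
}

# Reference injury contingencies of the motivating elite-soccer cohort
# (815 player-weeks, 30 time-loss injuries), by quartile of each metric.
acwr_contingency <- function() {
  tibble::tibble(
    quantile = 1:4,
    injured = c(3L, 6L, 5L, 16L),
    not_injured = c(202L, 213L, 182L, 188L)
  )
}

acwrr_contingency <- function() {
  tibble::tibble(
    quantile = 1:4,
    injured = c(3L, 4L, 9L, 14L),
    not_injured = c(201L, 200L, 194L, 190L)
  )
}

# Expand a contingency into Bernoulli observation rows.
contingency_to_rows <- function(tab) {
  tibble::tibble(
    q = rep(tab$quantile, tab$injured + tab$not_injured),
    inj = unlist(purrr::map2(
      tab$injured, tab$not_injured,
      ~ rep(c(TRUE, FALSE), c(.x, .y))
    ))
  )
}

# Reduced MCMC settings for unit tests (fast, still >= 100 draws/chain).
fast_mcmc <- list(n_chains = 2, n_iter = 1500, warmup = 500)
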