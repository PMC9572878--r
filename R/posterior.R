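#' Highest-density interval of a sample
#'
#' Narrowest contiguous interval containing `mass` of the draws, by the
#' sorted-window method: over the sorted sample, the shortest window
#' spanning `ceiling(mass * n)` draws.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Probability mass of the interval, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 100) {
    abort_invalid("hdi() needs at least 100 draws.")
  }
  if (mass <= 0 || mass >= 1) abort_invalid("`mass` must lie in (0, 1).")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) {
    return(c(lower = x[1], upper = x[n]))
  }
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half and the classic Gelman-Rubin statistic is
#' computed on the split chains: `sqrt(var_plus / W)` where `W` is the mean
#' within-chain variance and `var_plus = (n-1)/n * W + B/n`. Values near 1
#' indicate the chains have mixed.
#'
#' @param chains A matrix (iterations x chains), or a list of equal-length
#'   numeric vectors, with at least 2 chains of at least 100 iterations.
#' @return The split-Rhat statistic (scalar; 1 when all draws are
#'   identical).
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) {
      abort_invalid("all chains must have the same length.")
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) abort_invalid("psrf() needs at least 2 chains.")
  if (nrow(chains) < 100) abort_invalid("psrf() needs chains of length >= 100.")

  half <- floor(nrow(chains) / 2)
  split <- cbind(chains[1:half, , drop = FALSE],
                 chains[(half + 1):(2 * half), , drop = FALSE])
  n <- nrow(split)
  m <- ncol(split)
  chain_means <- colMeans(split)
  chain_vars <- apply(split, 2, var)
  w <- mean(chain_vars)
  b <- n * var(chain_means)
  if (w == 0) {
    return(1)
  } # all chains constant and equal
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

#' Effective sample size of an autocorrelated chain
#'
#' `n / (1 + 2 * sum(rho_k))` with Geyer's initial-positive-sequence
#' truncation: autocorrelations are summed in consecutive pairs
#' `rho_{2m} + rho_{2m+1}` until the first non-positive pair.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @return Effective sample size (scalar, capped at `length(draws)`).
#' @export
ess <- function(draws) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) abort_invalid("ess() needs at least 100 draws.")
  if (var(draws) == 0) {
    abort_undefined("ESS is undefined for a constant chain.")
  }
  rho <- autocorr_fft(draws)
  # Geyer initial positive sequence over pairs (rho_0 + rho_1), (rho_2 + rho_3), ...
  max_pairs <- floor(length(rho) / 2)
  tau <- 0
  for (m in seq_len(max_pairs)) {
    pair <- rho[2 * m - 1] + rho[2 * m] # rho_{2m-2} + rho_{2m-1} (1-based)
    if (pair <= 0) break
    tau <- tau + pair
  }
  # tau accumulates starting at rho_0 + rho_1 with rho_0 = 1, so
  # 1 + 2*sum_{k>=1} rho_k = 2*tau - 1.
  max(1, min(n, n / (2 * tau - 1)))
}

# Autocorrelation function via FFT (biased estimator, standard for ESS).
autocorr_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- nextn(2 * n)
  f <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[1:n] / m
  ac / ac[1]
}

#' Tidy posterior draws container
#'
#' A tibble with one row per (chain, iteration) and one column per
#' parameter, plus bookkeeping columns `.chain` and `.iteration`.
#'
#' @param draws Data frame with `.chain`, `.iteration` and parameter
#'   columns.
#' @param seed Seed the draws were generated under (for provenance).
#' @return The tibble with class `posterior_draws`.
#' @export
posterior_draws <- function(draws, seed = NA_integer_) {
  stopifnot(all(c(".chain", ".iteration") %in% names(draws)))
  if (anyNA(draws)) abort_invalid("posterior draws must not contain NA.")
  out <- as_tibble(draws)
  attr(out, "seed") <- seed
  class(out) <- c("posterior_draws", class(out))
  out
}

#' Parameter names of a posterior_draws object
#' @param draws A `posterior_draws` tibble.
#' @return Character vector of parameter column names.
#' @export
draw_parameters <- function(draws) {
  setdiff(names(draws), c(".chain", ".iteration"))
}

#' Posterior summary table
#'
#' Mean, 95% highest-density interval, effective sample size (summed over
#' chains) and split-Rhat for each parameter column.
#'
#' @param draws A `posterior_draws` tibble.
#' @param pars Parameters to summarise (default: all).
#' @param mass HDI mass (default 0.95).
#' @return Tibble: `term`, `mean`, `hdi_low`, `hdi_high`, `ess`, `psrf`.
#' @export
summarise_posterior <- function(draws, pars = draw_parameters(draws),
                                mass = 0.95) {
  purrr::map_dfr(pars, function(p) {
    x <- draws[[p]]
    iv <- hdi(x, mass)
    by_chain <- split(x, draws$.chain)
    ess_total <- sum(purrr::map_dbl(by_chain, function(ch) {
      if (var(ch) == 0) 0 else ess(ch)
    }))
    rhat <- if (length(by_chain) >= 2) psrf(by_chain) else NA_real_
    tibble(
      term = p, mean = mean(x),
      hdi_low = iv[["lower"]], hdi_high = iv[["upper"]],
      ess = ess_total, psrf = rhat
    )
  })
}

#' Export posterior draws in long format
#'
#' @param draws A `posterior_draws` tibble.
#' @return Tibble: `parameter`, `chain`, `iteration`, `value`.
#' @export
draws_long <- function(draws) {
  draws %>%
    as_tibble() %>%
    tidyr::pivot_longer(
      cols = -c(".chain", ".iteration"),
      names_to = "parameter", values_to = "value"
    ) %>%
    rename(chain = ".chain", iteration = ".iteration") %>%
    select("parameter", "chain", "iteration", "value") %>%
    arrange(.data$parameter, .data$chain, .data$iteration)
}
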