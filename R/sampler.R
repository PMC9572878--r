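#' Draw posterior samples from a JAGS model
#'
#' Thin, reproducible wrapper around rjags: compiles `code`, runs
#' `n_chains` chains with per-chain RNG seeds derived deterministically
#' from `seed`, discards `warmup` iterations and returns the retained
#' draws as a [posterior_draws()] tibble (array-valued JAGS nodes are
#' flattened to `name[i]` columns). Optionally gates the result on
#' convergence diagnostics.
#'
#' @param code JAGS model code (character scalar).
#' @param data Named list of data passed to the model.
#' @param params Character vector of parameters to monitor.
#' @param n_chains Number of chains (default 4).
#' @param n_iter Retained iterations per chain (default 10000).
#' @param warmup Burn-in iterations discarded after adaptation (default
#'   2000).
#' @param seed Integer seed; chain seeds are derived from it, so the same
#'   seed reproduces the draws exactly.
#' @param inits Optional function `function(chain)` returning a named list
#'   of initial values for that chain.
#' @param check One of `"error"`, `"warn"`, `"none"`: what to do when a
#'   monitored parameter fails the convergence gate.
#' @param psrf_max Maximum acceptable split-Rhat (default 1.01).
#' @param ess_min Minimum acceptable effective sample size (default 400);
#'   set to 0 to gate on Rhat only.
#' @param n_adapt JAGS adaptation iterations (default 1000).
#' @return A [posterior_draws()] tibble. On a failed gate with
#'   `check = "error"` an `acwrbayes_error_diagnostics` condition is
#'   signalled whose `result` field carries the draws and whose `report`
#'   field carries the diagnostics table.
#' @export
sample_posterior <- function(code, data, params,
                             n_chains = 4, n_iter = 10000, warmup = 2000,
                             seed, inits = NULL,
                             check = c("error", "warn", "none"),
                             psrf_max = 1.01, ess_min = 400,
                             n_adapt = 1000) {
  check <- match.arg(check)
  if (missing(seed) || is.null(seed)) abort_invalid("`seed` is required.")
  seed <- as.integer(seed)
  if (n_chains < 2) abort_invalid("at least 2 chains are required.")

  chain_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, n_chains)
  )
  init_list <- lapply(seq_len(n_chains), function(i) {
    ini <- if (is.null(inits)) list() else inits(i)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- chain_seeds[i]
    ini
  })

  model <- tryCatch(
    rjags::jags.model(textConnection(code),
      data = data, inits = init_list,
      n.chains = n_chains, n.adapt = n_adapt, quiet = TRUE
    ),
    error = function(e) {
      abort(
        paste0("JAGS model initialization failed: ", conditionMessage(e)),
        class = "acwrbayes_error_initialization"
      )
    }
  )
  if (warmup > 0) stats::update(model, n.iter = warmup, progress.bar = "none")
  mcmc <- rjags::coda.samples(model, variable.names = params, n.iter = n_iter,
                              progress.bar = "none")

  draws <- purrr::imap_dfr(as.list(mcmc), function(ch, i) {
    m <- as.matrix(ch)
    df <- as_tibble(m)
    df$.chain <- as.integer(i)
    df$.iteration <- seq_len(nrow(m))
    df
  })
  draws <- posterior_draws(
    draws[, c(".chain", ".iteration", setdiff(names(draws), c(".chain", ".iteration")))],
    seed = seed
  )

  if (check != "none") {
    report <- summarise_posterior(draws)
    bad <- report %>%
      filter(.data$psrf >= psrf_max | .data$ess <= ess_min)
    if (nrow(bad) > 0) {
      msg <- sprintf(
        "MCMC diagnostics failed for %s (split-Rhat limit %.3f, ESS floor %g).",
        paste(bad$term, collapse = ", "), psrf_max, ess_min
      )
      if (check == "error") {
        abort_diagnostics(msg, result = draws, report = report)
      }
      warn(msg, class = "acwrbayes_warning_diagnostics")
    }
  }
  draws
}
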