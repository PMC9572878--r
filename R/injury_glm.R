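#' Priors for the quantile injury GLM
#'
#' The intercept (baseline log-odds) gets a Normal(0, `intercept_sd`^2)
#' prior on the logit scale. The per-quantile deviations get a hierarchical
#' Normal(0, sigma_beta^2) prior with sigma_beta ~ half-Cauchy(0,
#' `deviation_scale`) -- the standard weakly-informative choice for a
#' group-level scale over few groups, inducing mild shrinkage of the
#' deviations toward zero. Set `hierarchical = FALSE` for fixed
#' Normal(0, `deviation_sd`^2) deviation priors (e.g. effectively flat
#' with a large `deviation_sd`).
#'
#' @param intercept_sd SD of the intercept prior, log-odds (default 2).
#' @param deviation_scale Half-Cauchy scale of the deviation SD (default
#'   2.5).
#' @param hierarchical Use the hierarchical shrinkage prior (default TRUE).
#' @param deviation_sd Fixed deviation prior SD when
#'   `hierarchical = FALSE` (default 10, effectively flat).
#' @return A `glm_priors` list.
#' @export
glm_priors <- function(intercept_sd = 2, deviation_scale = 2.5,
                       hierarchical = TRUE, deviation_sd = 10) {
  structure(
    list(
      intercept_sd = intercept_sd, deviation_scale = deviation_scale,
      hierarchical = hierarchical, deviation_sd = deviation_sd
    ),
    class = "glm_priors"
  )
}

glm_jags_code <- function(hierarchical) {
  prior_block <- if (hierarchical) {
    "  tau_b <- 1 / (sigma_b * sigma_b)
  sigma_b ~ dt(0, cauchy_prec, 1) T(0,)"
  } else {
    "  tau_b <- dev_prec"
  }
  paste0("
model {
  for (q in 1:K) {
    y[q] ~ dbin(p[q], n[q])
    logit(p[q]) <- a0 + a[q]
    a[q] ~ dnorm(0, tau_b)
  }
  a0 ~ dnorm(0, int_prec)
", prior_block, "
}
")
}

#' Aggregate observation rows to an injury contingency table
#'
#' @param data Observation rows.
#' @param quantile Column (tidy-eval) of quartile labels (integers 1..K).
#' @param injured Column (tidy-eval) of logical injury indicators.
#' @return Tibble: `quantile`, `injured`, `not_injured` (counts).
#' @export
as_contingency <- function(data, quantile, injured) {
  q <- dplyr::pull(data, {{ quantile }})
  inj <- dplyr::pull(data, {{ injured }})
  if (!is.logical(inj)) abort_invalid("`injured` must be a logical column.")
  keep <- !is.na(q) & !is.na(inj)
  q <- as.integer(q[keep])
  inj <- inj[keep]
  k <- max(q)
  if (!setequal(unique(q), seq_len(k))) {
    abort_invalid("every quantile category 1..K must have observations.")
  }
  tibble(
    quantile = seq_len(k),
    injured = as.integer(tapply(inj, q, sum)),
    not_injured = as.integer(tapply(!inj, q, sum))
  )
}

#' Bayesian logistic GLM of injury probability over load quantiles
#'
#' Likelihood `injured_q ~ Binomial(n_q, inverse_logit(beta0 + beta_q))`
#' with sum-to-zero deviation coding: the model is sampled in a redundant
#' parameterisation (free intercept plus free per-quantile effects) and
#' the category mean is swept into the intercept after sampling, so
#' `sum(beta_q) = 0` holds for every posterior draw at machine precision.
#' Bernoulli observation rows and an aggregated contingency table are
#' likelihood-equivalent inputs: rows are aggregated internally, so both
#' forms give identical posteriors under the same seed.
#'
#' @param data Either observation rows (then give `quantile` and
#'   `injured` columns) or a contingency table with numeric columns
#'   `quantile`, `injured`, `not_injured`.
#' @param quantile,injured Tidy-eval columns for the observation-row form;
#'   ignored when `data` is already a contingency table.
#' @param priors A [glm_priors()] specification.
#' @param n_chains,n_iter,warmup MCMC settings (defaults 4, 10000, 2000).
#' @param seed Integer seed (required).
#' @param check Convergence gate behaviour (see [sample_posterior()]);
#'   gates on split-Rhat only.
#' @param psrf_max Split-Rhat limit (default 1.01).
#' @param metric Optional label of the discretised metric (for printing).
#' @return Object of class `quantile_glm`: list with `draws` (beta0,
#'   beta_1..K, p_q1..K, sigma_beta), `summary`, `contingency`, `metric`,
#'   `priors`, `seed`.
#' @export
fit_quantile_glm <- function(data, quantile = NULL, injured = NULL,
                             priors = glm_priors(),
                             n_chains = 4, n_iter = 10000, warmup = 2000,
                             seed, check = c("error", "warn", "none"),
                             psrf_max = 1.01, metric = NULL) {
  check <- match.arg(check)
  if (missing(seed) || is.null(seed)) abort_invalid("`seed` is required.")

  is_contingency <- all(c("quantile", "injured", "not_injured") %in% names(data)) &&
    is.numeric(data$injured)
  tab <- if (is_contingency) {
    as_tibble(data[, c("quantile", "injured", "not_injured")])
  } else {
    as_contingency(data, {{ quantile }}, {{ injured }})
  }
  tab <- arrange(tab, .data$quantile)
  k <- nrow(tab)
  if (!identical(as.integer(tab$quantile), seq_len(k))) {
    abort_invalid("contingency must have one row per quantile 1..K.")
  }
  totals <- tab$injured + tab$not_injured
  if (any(totals == 0)) {
    abort_invalid("every quantile category needs at least one observation.")
  }
  if (sum(tab$injured) < 1) abort_invalid("at least one injury is required.")

  jdata <- list(
    y = tab$injured, n = totals, K = k,
    int_prec = 1 / priors$intercept_sd^2
  )
  if (priors$hierarchical) {
    jdata$cauchy_prec <- 1 / priors$deviation_scale^2
  } else {
    jdata$dev_prec <- 1 / priors$deviation_sd^2
  }
  params <- c("a0", "a", if (priors$hierarchical) "sigma_b")

  # The redundant parameterisation leaves a0 and mean(a) individually
  # non-identified (only their sum matters), so convergence is gated on the
  # reported swept parameters below, not on the raw draws.
  raw <- sample_posterior(
    glm_jags_code(priors$hierarchical), jdata, params = params,
    n_chains = n_chains, n_iter = n_iter, warmup = warmup,
    seed = seed, check = "none"
  )

  a_cols <- paste0("a[", seq_len(k), "]")
  a_mat <- as.matrix(as_tibble(raw)[, a_cols])
  a_bar <- rowMeans(a_mat)
  out <- tibble(.chain = raw$.chain, .iteration = raw$.iteration)
  out$beta0 <- raw$a0 + a_bar
  for (q in seq_len(k)) out[[paste0("beta", q)]] <- a_mat[, q] - a_bar
  for (q in seq_len(k)) {
    out[[paste0("p_q", q)]] <- plogis(out$beta0 + out[[paste0("beta", q)]])
  }
  if (priors$hierarchical) out$sigma_beta <- raw$sigma_b
  draws <- posterior_draws(out, seed = as.integer(seed))

  terms <- c("beta0", paste0("beta", seq_len(k)), paste0("p_q", seq_len(k)))
  summary <- summarise_posterior(draws, pars = terms)
  if (check != "none") {
    bad <- filter(summary, .data$psrf >= psrf_max)
    if (nrow(bad) > 0) {
      msg <- sprintf(
        "MCMC diagnostics failed for %s (split-Rhat limit %.3f).",
        paste(bad$term, collapse = ", "), psrf_max
      )
      if (check == "error") abort_diagnostics(msg, result = draws, report = summary)
      warn(msg, class = "acwrbayes_warning_diagnostics")
    }
  }
  structure(
    list(
      draws = draws,
      summary = summary,
      contingency = tab, metric = metric, priors = priors,
      seed = as.integer(seed)
    ),
    class = "quantile_glm"
  )
}

#' Conditional injury probability for one quantile
#'
#' Posterior of `inverse_logit(beta0 + beta_q)`, i.e. the model-implied
#' probability of injury in the following week given membership of
#' quartile `quantile`.
#'
#' @param result A fitted `quantile_glm`.
#' @param quantile Quartile index (1..K).
#' @return One-row tibble: `term`, `mean`, `hdi_low`, `hdi_high`, `ess`,
#'   `psrf`.
#' @export
conditional_injury_probability <- function(result, quantile) {
  stopifnot(inherits(result, "quantile_glm"))
  k <- nrow(result$contingency)
  if (!(length(quantile) == 1 && quantile %in% seq_len(k))) {
    abort_invalid(sprintf("`quantile` must be a single integer in 1..%d.", k))
  }
  summarise_posterior(result$draws, pars = paste0("p_q", quantile))
}

#' Compare conditional injury probabilities of two fitted metrics
#'
#' Draw-wise difference of the fourth-quantile (by default) injury
#' probability between two fitted models, paired by draw index (the longer
#' draw set is truncated, with a warning). The metrics are declared
#' "similar" when the 95% HDI of the difference contains zero.
#'
#' @param result_a,result_b Fitted `quantile_glm` objects (e.g. ACWR and
#'   ACWRr models on the same rows).
#' @param quantile Quartile whose probabilities are compared (default 4).
#' @return One-row tibble: `term`, `mean`, `hdi_low`, `hdi_high`,
#'   `similar`.
#' @export
compare_metrics <- function(result_a, result_b, quantile = 4) {
  stopifnot(inherits(result_a, "quantile_glm"), inherits(result_b, "quantile_glm"))
  pa <- result_a$draws[[paste0("p_q", quantile)]]
  pb <- result_b$draws[[paste0("p_q", quantile)]]
  if (is.null(pa) || is.null(pb)) abort_invalid("quantile not present in both fits.")
  if (length(pa) != length(pb)) {
    warn(sprintf(
      "draw counts differ (%d vs %d); truncating to the shorter.",
      length(pa), length(pb)
    ))
    m <- min(length(pa), length(pb))
    pa <- pa[seq_len(m)]
    pb <- pb[seq_len(m)]
  }
  d <- pa - pb
  iv <- hdi(d)
  tibble(
    term = sprintf("p_q%d_diff", quantile),
    mean = mean(d), hdi_low = iv[["lower"]], hdi_high = iv[["upper"]],
    similar = iv[["lower"]] <= 0 && iv[["upper"]] >= 0
  )
}

#' @export
tidy.quantile_glm <- function(x, ...) x$summary

#' @export
glance.quantile_glm <- function(x, ...) {
  tibble(
    n_obs = sum(x$contingency$injured + x$contingency$not_injured),
    n_injured = sum(x$contingency$injured),
    n_categories = nrow(x$contingency),
    max_psrf = max(x$summary$psrf, na.rm = TRUE),
    min_ess = min(x$summary$ess),
    seed = x$seed
  )
}

#' @export
print.quantile_glm <- function(x, ...) {
  cat(sprintf(
    "Bayesian quantile injury GLM%s: %d injuries / %d rows in %d quartiles\n",
    if (!is.null(x$metric)) paste0(" (", x$metric, ")") else "",
    sum(x$contingency$injured),
    sum(x$contingency$injured + x$contingency$not_injured),
    nrow(x$contingency)
  ))
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Violin plot of the GLM coefficient posteriors
#'
#' @param object A fitted `quantile_glm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantile_glm <- function(object, ...) {
  k <- nrow(object$contingency)
  cols <- c("beta0", paste0("beta", seq_len(k)))
  long <- object$draws %>%
    as_tibble() %>%
    select(all_of(cols)) %>%
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "coefficient", values_to = "value"
    ) %>%
    mutate(coefficient = factor(.data$coefficient, levels = cols))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$coefficient, y = .data$value)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "Log-odds",
      title = "Posterior distributions of the injury GLM coefficients"
    ) +
    ggplot2::theme_minimal()
}
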