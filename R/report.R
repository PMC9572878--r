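obs_metrics <- c(
  "acwr", "acwrr", "acute_load", "cumulative_load_2w",
  "cumulative_load_3w", "cumulative_load_4w", "chronic_load"
)

#' Descriptive load summary (median and IQR per stratum)
#'
#' Median and interquartile range of every load metric, for all
#' observation rows and for the injured / non-injured strata.
#'
#' @param observations Observation table from [build_observation_table()].
#' @return Tibble: `metric`, `stratum`, `n`, `median`, `q25`, `q75`.
#' @export
descriptive_summary <- function(observations) {
  if (nrow(observations) == 0) abort_invalid("observation table is empty.")
  strata <- list(
    overall = rep(TRUE, nrow(observations)),
    injured = observations$injured,
    not_injured = !observations$injured
  )
  purrr::map_dfr(intersect(obs_metrics, names(observations)), function(m) {
    purrr::imap_dfr(strata, function(sel, sname) {
      v <- observations[[m]][sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        message(sprintf("stratum '%s' empty for %s; emitted as missing.", sname, m))
        return(tibble(
          metric = m, stratum = sname, n = 0L,
          median = NA_real_, q25 = NA_real_, q75 = NA_real_
        ))
      }
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
      tibble(
        metric = m, stratum = sname, n = length(v),
        median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3])
      )
    })
  })
}

#' Quartile membership counts per stratum
#'
#' Counts and within-stratum percentages (rounded to integers) of the
#' quartile groups of acute load, ACWR and ACWRr, for all rows and for the
#' injured / non-injured strata.
#'
#' @param observations Observation table from [build_observation_table()].
#' @return Tibble: `metric`, `quantile`, `stratum`, `count`, `pct`.
#' @export
quantile_counts <- function(observations) {
  if (nrow(observations) == 0) abort_invalid("observation table is empty.")
  qcols <- c(
    acute_load = "acute_quantile", acwr = "acwr_quantile",
    acwrr = "acwrr_quantile"
  )
  qcols <- qcols[qcols %in% names(observations)]
  strata <- list(
    overall = rep(TRUE, nrow(observations)),
    injured = observations$injured,
    not_injured = !observations$injured
  )
  purrr::imap_dfr(qcols, function(qc, m) {
    purrr::imap_dfr(strata, function(sel, sname) {
      qv <- observations[[qc]][sel]
      tot <- sum(!is.na(qv))
      counts <- tabulate(qv, nbins = 4)
      tibble(
        metric = m, quantile = 1:4, stratum = sname, count = counts,
        pct = if (tot > 0) as.integer(round(100 * counts / tot)) else NA_integer_
      )
    })
  })
}

#' Pipeline configuration
#'
#' Bundles the inputs (a session/injury log, or a [synthetic_config()] to
#' simulate one), the MCMC settings and prior overrides, and the output
#' directory, for [run_pipeline()].
#'
#' @param sessions,injuries Data frames or CSV paths (ignored when
#'   `synthetic` is given).
#' @param synthetic Optional [synthetic_config()]; when present the season
#'   is simulated.
#' @param compare_metrics Metrics compared between injured and
#'   non-injured rows by the robust model (default acute load and ACWR).
#' @param glm_metrics Discretised metrics modelled by the injury GLM
#'   (default ACWR and ACWRr).
#' @param n_chains,n_iter,warmup MCMC settings (defaults 4, 10000, 2000).
#' @param seed Integer seed; mandatory, drives every random stage.
#' @param out_dir Output directory for table CSVs and the manifest.
#' @param acwrr_mean,acwrr_sd ACWRr random-denominator parameters, AU.
#' @param coupled Chronic-window convention (see [weekly_loads()]).
#' @param glm_prior,robust_prior Prior specifications.
#' @param save_draws Also write full posterior draws (long CSV) per model.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sessions = NULL, injuries = NULL, synthetic = NULL,
                            compare_metrics = c("acute_load", "acwr"),
                            glm_metrics = c("acwr", "acwrr"),
                            n_chains = 4, n_iter = 10000, warmup = 2000,
                            seed = NULL, out_dir = NULL,
                            acwrr_mean = 1900, acwrr_sd = 730,
                            coupled = TRUE,
                            glm_prior = glm_priors(),
                            robust_prior = robust_priors(),
                            save_draws = FALSE) {
  if (is.null(seed)) abort_invalid("`seed` is mandatory.")
  if (is.null(out_dir)) abort_invalid("`out_dir` is required.")
  if (is.null(synthetic) && is.null(sessions)) {
    abort_invalid("provide either `sessions` (+ `injuries`) or `synthetic`.")
  }
  for (p in list(sessions, injuries)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      abort_invalid(sprintf("input path does not exist: %s", p))
    }
  }
  structure(
    list(
      sessions = sessions, injuries = injuries, synthetic = synthetic,
      compare_metrics = compare_metrics, glm_metrics = glm_metrics,
      n_chains = n_chains, n_iter = n_iter, warmup = warmup,
      seed = as.integer(seed), out_dir = out_dir,
      acwrr_mean = acwrr_mean, acwrr_sd = acwrr_sd, coupled = coupled,
      glm_prior = glm_prior, robust_prior = robust_prior,
      save_draws = save_draws
    ),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "acwrbayes_error_pipeline", stage = stage, parent = e
    )
  })
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full workload-injury analysis pipeline
#'
#' Ingests or simulates a team season, builds the player-week observation
#' table, writes the descriptive load table and quartile-count table, fits
#' the robust Student-t comparison for each metric in
#' `config$compare_metrics` and the quantile injury GLM for each metric in
#' `config$glm_metrics`, compares the GLM fourth-quantile injury
#' probabilities across metrics, and writes a convergence-diagnostics
#' summary plus a machine-readable manifest. All randomness derives from
#' `config$seed`: re-running with the same config yields byte-identical
#' CSVs and manifest.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the observation table, all result
#'   objects, the emitted tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  emitted <- list()

  inputs <- with_stage("input", {
    if (!is.null(config$synthetic)) {
      season <- simulate_team_season(config$synthetic)
      list(sessions = season$sessions, injuries = season$injuries)
    } else {
      s <- if (is.character(config$sessions)) {
        read_sessions(config$sessions)
      } else {
        config$sessions
      }
      i <- if (is.character(config$injuries)) {
        read_injuries(config$injuries)
      } else {
        config$injuries
      }
      list(sessions = s, injuries = i)
    }
  })
  message(sprintf(
    "input: %d session records, %d injuries",
    nrow(inputs$sessions), if (is.null(inputs$injuries)) 0L else nrow(inputs$injuries)
  ))

  observations <- with_stage("observations", build_observation_table(
    inputs$sessions, inputs$injuries,
    coupled = config$coupled,
    acwrr_mean = config$acwrr_mean, acwrr_sd = config$acwrr_sd,
    seed = config$seed
  ))
  nominal <- nrow(weekly_loads(inputs$sessions, coupled = config$coupled))
  message(sprintf(
    "observations: %d rows retained of %d nominal player-weeks (%d injured)",
    nrow(observations), nominal, sum(observations$injured)
  ))
  readr::write_csv(observations, out("observations.csv"))
  emitted$observations <- "observation table"

  with_stage("descriptives", {
    readr::write_csv(round_df(descriptive_summary(observations)), out("descriptive_loads.csv"))
    readr::write_csv(quantile_counts(observations), out("quantile_counts.csv"))
  })
  emitted$descriptive_loads <- "median/IQR per metric per stratum"
  emitted$quantile_counts <- "quartile counts and percentages per stratum"

  robust_fits <- list()
  normality <- list()
  for (m in config$compare_metrics) {
    robust_fits[[m]] <- with_stage(paste0("robust_", m), fit_robust_comparison(
      observations,
      value = m, group = "injured",
      priors = config$robust_prior,
      n_chains = config$n_chains, n_iter = config$n_iter,
      warmup = config$warmup, seed = config$seed, check = "warn"
    ))
    readr::write_csv(round_df(tidy(robust_fits[[m]])), out(paste0("robust_", m, ".csv")))
    emitted[[paste0("robust_", m)]] <- paste("robust Student-t comparison of", m)
    if (!is.null(robust_fits[[m]]$normality)) {
      normality[[m]] <- mutate(robust_fits[[m]]$normality, metric = m, .before = 1)
    }
  }
  if (length(normality) > 0) {
    readr::write_csv(round_df(bind_rows(normality), 4), out("normality.csv"))
    emitted$normality <- "Shapiro-Wilk normality gate per metric and stratum"
  }

  glm_fits <- list()
  for (m in config$glm_metrics) {
    qcol <- paste0(sub("_load", "", m), "_quantile")
    glm_fits[[m]] <- with_stage(paste0("glm_", m), fit_quantile_glm(
      observations,
      quantile = qcol, injured = "injured",
      priors = config$glm_prior,
      n_chains = config$n_chains, n_iter = config$n_iter,
      warmup = config$warmup, seed = config$seed, check = "warn", metric = m
    ))
    readr::write_csv(round_df(tidy(glm_fits[[m]])), out(paste0("glm_", m, ".csv")))
    emitted[[paste0("glm_", m)]] <- paste("quantile injury GLM for", m)
  }

  if (length(glm_fits) >= 2) {
    cmp <- with_stage("metric_comparison", compare_metrics(
      glm_fits[[1]], glm_fits[[2]]
    ))
    cmp <- mutate(cmp,
      metric_a = names(glm_fits)[1], metric_b = names(glm_fits)[2],
      .before = 1
    )
    readr::write_csv(round_df(cmp, 4), out("metric_comparison.csv"))
    emitted$metric_comparison <- "fourth-quantile injury-probability difference between metrics"
  }

  diagnostics <- bind_rows(
    purrr::imap_dfr(robust_fits, ~ mutate(tidy(.x), model = paste0("robust_", .y), .before = 1)),
    purrr::imap_dfr(glm_fits, ~ mutate(tidy(.x), model = paste0("glm_", .y), .before = 1))
  )
  readr::write_csv(round_df(diagnostics, 4), out("diagnostics.csv"))
  emitted$diagnostics <- "posterior summaries with ESS and split-Rhat for every parameter"

  if (config$save_draws) {
    for (m in names(robust_fits)) {
      readr::write_csv(draws_long(robust_fits[[m]]$draws), out(paste0("draws_robust_", m, ".csv")))
    }
    for (m in names(glm_fits)) {
      readr::write_csv(draws_long(glm_fits[[m]]$draws), out(paste0("draws_glm_", m, ".csv")))
    }
  }

  manifest <- list(
    package = "acwrbayes",
    version = as.character(utils::packageVersion("acwrbayes")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    n_observations = nrow(observations),
    n_injured = sum(observations$injured),
    tables = emitted
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    observations = observations, robust = robust_fits, glm = glm_fits,
    diagnostics = diagnostics, manifest = manifest
  ))
}
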