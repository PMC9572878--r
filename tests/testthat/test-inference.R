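test_that("HDI of symmetric unimodal samples matches the central interval", {
  set.seed(1)
  x <- rnorm(1e6)
  iv <- hdi(x)
  expect_equal(unname(iv["lower"]), -1.96, tolerance = 0.02)
  expect_equal(unname(iv["upper"]), 1.96, tolerance = 0.02)

  u <- runif(1e5)
  ivu <- hdi(u)
  expect_equal(unname(diff(ivu)), 0.95, tolerance = 0.01)

  cv <- rep(3.2, 200)
  expect_equal(unname(hdi(cv)), c(3.2, 3.2))
  expect_error(hdi(rnorm(50)), class = "acwrbayes_error_invalid_input")
  expect_error(hdi(rnorm(200), mass = 1.2), class = "acwrbayes_error_invalid_input")
})

test_that("HDI is monotone in mass", {
  set.seed(2)
  for (x in list(rnorm(5000), rexp(5000), rbeta(5000, 2, 5))) {
    iv95 <- hdi(x, 0.95)
    iv99 <- hdi(x, 0.99)
    expect_lte(iv99["lower"], iv95["lower"])
    expect_gte(iv99["upper"], iv95["upper"])
  }
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(3)
  mixed <- replicate(4, rnorm(2000), simplify = FALSE)
  expect_equal(psrf(mixed), 1, tolerance = 0.01)

  disjoint <- list(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  r <- psrf(disjoint)
  expect_gt(r, 1.1)
  # independent oracle: direct between/within computation on the split chains
  sp <- cbind(
    disjoint[[1]][1:500], disjoint[[1]][501:1000],
    disjoint[[2]][1:500], disjoint[[2]][501:1000]
  )
  w <- mean(apply(sp, 2, var))
  b <- 500 * var(colMeans(sp))
  r_direct <- sqrt(((500 - 1) / 500 * w + b / 500) / w)
  expect_equal(r, r_direct, tolerance = 1e-10)

  dup <- rnorm(500)
  expect_equal(psrf(list(dup, dup)), 1, tolerance = 0.01)
  expect_error(psrf(list(rnorm(200))), class = "acwrbayes_error_invalid_input")
  expect_error(psrf(list(rnorm(200), rnorm(199))), class = "acwrbayes_error_invalid_input")
})

test_that("ESS recovers nominal size for iid draws and the AR(1) closed form", {
  set.seed(4)
  x <- rnorm(10000)
  expect_equal(ess(x), 10000, tolerance = 0.10)

  for (phi in c(0.3, 0.6)) {
    n <- 30000
    e <- numeric(n)
    e[1] <- rnorm(1)
    innov <- rnorm(n - 1, 0, sqrt(1 - phi^2))
    for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
    expect_equal(ess(e), n * (1 - phi) / (1 + phi), tolerance = 0.2)
  }
  expect_error(ess(rep(1, 500)), class = "acwrbayes_error_undefined_value")
  expect_error(ess(rnorm(50)), class = "acwrbayes_error_invalid_input")
})

test_that("sampling a conjugate Beta-Binomial model matches the closed form", {
  code <- "
model {
  y ~ dbin(p, n)
  p ~ dbeta(2, 3)
}
"
  draws <- sample_posterior(code, list(y = 17, n = 50), "p",
    n_chains = 2, n_iter = 2000, warmup = 500, seed = 42, check = "none"
  )
  a <- 2 + 17
  b <- 3 + 50 - 17
  post_mean <- a / (a + b)
  post_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  mcse <- post_sd / sqrt(sum(vapply(split(draws$p, draws$.chain), ess, numeric(1))))
  expect_lt(abs(mean(draws$p) - post_mean), 3 * mcse + 1e-6)
  expect_equal(sd(draws$p), post_sd, tolerance = 0.1)
})

test_that("sampling a conjugate Normal model with known sigma matches the closed form", {
  set.seed(9)
  y <- rnorm(30, 5, 2)
  code <- "
model {
  for (i in 1:n) { y[i] ~ dnorm(mu, 1 / (sigma * sigma)) }
  mu ~ dnorm(m0, 1 / (s0 * s0))
}
"
  draws <- sample_posterior(code, list(y = y, n = 30, sigma = 2, m0 = 0, s0 = 10),
    "mu",
    n_chains = 2, n_iter = 2000, warmup = 500, seed = 7, check = "none"
  )
  prec <- 1 / 100 + 30 / 4
  post_mean <- (0 / 100 + sum(y) / 4) / prec
  post_sd <- sqrt(1 / prec)
  mcse <- post_sd / sqrt(sum(vapply(split(draws$mu, draws$.chain), ess, numeric(1))))
  expect_lt(abs(mean(draws$mu) - post_mean), 3 * mcse + 1e-6)
  expect_equal(sd(draws$mu), post_sd, tolerance = 0.1)
})

test_that("with no data the posterior equals the prior", {
  code <- "
model {
  mu ~ dnorm(1, 1 / 4)
}
"
  draws <- sample_posterior(code, list(), "mu",
    n_chains = 2, n_iter = 4000, warmup = 200, seed = 5, check = "none"
  )
  qs <- quantile(draws$mu, seq(0.1, 0.9, 0.1))
  expect_equal(unname(qs), qnorm(seq(0.1, 0.9, 0.1), 1, 2), tolerance = 0.08)
})

test_that("sampling is deterministic given the seed and gates on diagnostics", {
  code <- "
model {
  y ~ dbin(p, n)
  p ~ dbeta(1, 1)
}
"
  d1 <- sample_posterior(code, list(y = 3, n = 10), "p",
    n_chains = 2, n_iter = 500, warmup = 100, seed = 33, check = "none"
  )
  d2 <- sample_posterior(code, list(y = 3, n = 10), "p",
    n_chains = 2, n_iter = 500, warmup = 100, seed = 33, check = "none"
  )
  expect_identical(d1, d2)

  expect_error(
    sample_posterior(code, list(y = 3, n = 10), "p",
      n_chains = 2, n_iter = 500, warmup = 100, seed = 33,
      check = "error", ess_min = 1e9
    ),
    class = "acwrbayes_error_diagnostics"
  )
  cond <- rlang::catch_cnd(
    sample_posterior(code, list(y = 3, n = 10), "p",
      n_chains = 2, n_iter = 500, warmup = 100, seed = 33,
      check = "error", ess_min = 1e9
    ),
    class = "acwrbayes_error_diagnostics"
  )
  expect_s3_class(cond$result, "posterior_draws")
  expect_true(is.data.frame(cond$report))
})

test_that("a model with an impossible likelihood signals initialization failure", {
  code <- "
model {
  y ~ dbin(p, n)
  p ~ dbeta(1, 1)
}
"
  expect_error(
    sample_posterior(code, list(y = 20, n = 10), "p",
      n_chains = 2, n_iter = 200, warmup = 50, seed = 1, check = "none"
    ),
    class = "acwrbayes_error_initialization"
  )
})

test_that("posterior summaries report mean, HDI, ESS and Rhat per parameter", {
  set.seed(10)
  draws <- posterior_draws(tibble::tibble(
    .chain = rep(1:2, each = 1000), .iteration = rep(1:1000, 2),
    theta = rnorm(2000, 3, 0.5), lambda = rexp(2000)
  ))
  s <- summarise_posterior(draws)
  expect_equal(s$term, c("theta", "lambda"))
  expect_equal(s$mean[1], 3, tolerance = 0.05)
  expect_true(all(s$hdi_low < s$mean & s$mean < s$hdi_high))
  expect_true(all(s$ess > 100))
  expect_true(all(abs(s$psrf - 1) < 0.02))

  long <- draws_long(draws)
  expect_equal(nrow(long), 4000)
  expect_setequal(unique(long$parameter), c("theta", "lambda"))
})
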