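test_that("correlation filter drops derived and dispreferred variables", {
  set.seed(91)
  x <- rnorm(60)
  env <- data.frame(a = x, b = rnorm(60), dup = x,
                    c = 0.9 * x + 0.1 * rnorm(60))
  # duplicate column: one dropped (derived vs primary)
  keep <- correlation_filter(env[c("a", "dup")], primary = "a")
  expect_equal(keep, "a")
  # r just below the threshold: both kept
  y2 <- 0.3 * x + rnorm(60)
  stopifnot(abs(cor(x, y2)) < 0.69)
  expect_setequal(correlation_filter(data.frame(a = x, b = y2)),
                  c("a", "b"))
  # three mutually correlated primaries with a stated preference
  env3 <- data.frame(u = x, v = x + 0.05 * rnorm(60),
                     w = x + 0.05 * rnorm(60))
  expect_equal(correlation_filter(env3, preferences = c("w", "u", "v")), "w")
})

test_that("beta regression is exact on closed-form pieces and errors", {
  set.seed(92)
  y <- rbeta(50, 2, 5)
  expect_error(fit_beta(rep(0.4, 50)), "constant")
  expect_error(fit_beta(c(y, 0)), "squeeze")
  f <- fit_beta(c(y, 0), squeeze = TRUE)  # squeeze admits the boundary
  expect_true(f$converged)
  # AIC identity: -2 logLik + 2 (#parameters)
  expect_equal(f$aic, -2 * f$loglik + 2 * 2)
})

test_that("planted coefficients are recovered within 10%", {
  # beta = (-0.8, +0.4), precision 30, n = 100, averaged over seeds
  est <- t(vapply(1:12, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("x1", "x2")))
    mu <- plogis(-1 + X %*% c(-0.8, 0.4))
    y <- rbeta(100, mu * 30, (1 - mu) * 30)
    f <- fit_beta(y, X)
    f$coefficients$estimate[match(c("x1", "x2"), f$coefficients$term)]
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - (-0.8)) / 0.8, 0.1)
  expect_lt(abs(mean(est[, 2]) - 0.4) / 0.4, 0.1)
})

test_that("Wald slope tests are calibrated under the null", {
  # scaled-down null calibration (the acceptance suite runs 400 replicates)
  rej <- vapply(1:60, function(s) {
    set.seed(7000 + s)
    x <- rnorm(200)
    y <- rbeta(200, plogis(-1.5) * 30, (1 - plogis(-1.5)) * 30)
    f <- fit_beta(y, data.frame(x = x))
    f$coefficients$p_value[f$coefficients$term == "x"] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("stepwise AIC search behaves", {
  set.seed(93)
  x <- rnorm(80)
  env <- data.frame(strong = x, n1 = rnorm(80), n2 = rnorm(80))
  mu <- plogis(-1 + 0.9 * x)
  y <- rbeta(80, mu * 25, (1 - mu) * 25)
  sel <- stepwise_aic(env, y, scope = names(env))
  expect_true("strong" %in% sel$fit$terms)
  # accepted AIC trace never increases
  expect_true(all(diff(sel$trace$aic) < 0))
  # selected model cannot beat the full model's AIC the wrong way
  full <- fit_beta(y, env)
  expect_lte(sel$fit$aic, full$aic)

  # only-noise scope lands on the intercept-only model in most seeds
  none <- vapply(1:20, function(s) {
    set.seed(1200 + s)
    envn <- data.frame(n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
    yn <- rbeta(60, 0.3 * 20, 0.7 * 20)
    length(stepwise_aic(envn, yn, scope = names(envn))$fit$terms) == 0
  }, logical(1))
  expect_gte(sum(none), 8)
})

test_that("VIF matches closed forms and the loop prunes", {
  # orthogonal (and centred) design: all VIF exactly 1
  X <- poly(1:10, 4)
  colnames(X) <- paste0("o", 1:4)
  expect_equal(unname(vif(X)), rep(1, 4), tolerance = 1e-10)

  # duplicated covariate: infinite VIF, exactly one dropped
  set.seed(94)
  x <- rnorm(30); z <- rnorm(30)
  Xd <- data.frame(a = x, b = x, c = z)
  expect_true(any(is.infinite(vif(Xd))))
  lv <- vif_loop(Xd)
  expect_length(lv$dropped, 1)
  expect_true(all(c("c") %in% lv$retained))

  # two correlated covariates: VIF = 1/(1 - r^2) exactly
  r <- cor(x, z)
  expect_equal(unname(vif(data.frame(x = x, z = z))),
               rep(1 / (1 - r^2), 2), tolerance = 1e-10)
})

test_that("generalized R2 follows the Cox-Snell form", {
  m0 <- list(loglik = -40, n = 30)
  expect_equal(generalized_r2(m0, m0), 0)
  m1 <- list(loglik = -40 + 15, n = 30)   # gain n/2 -> 1 - exp(-1)
  expect_equal(generalized_r2(m1, m0), 1 - exp(-1))
  m2 <- list(loglik = -40 + 20, n = 30)
  expect_gt(generalized_r2(m2, m0), generalized_r2(m1, m0))
  expect_error(generalized_r2(list(loglik = 0, n = 10), m0), "different n")
})

test_that("the end-to-end workflow runs on a synthetic table", {
  cfg <- sim_config(pops = default_populations(13, 12, seed = 95), seed = 96)
  env <- simulate_environment(cfg)
  env$slope_derived <- env$wetness_index * 0.95 +
    0.05 * rnorm(nrow(env))   # a derived near-duplicate
  wf <- env_model_workflow(env[, c("pop_id", cfg$env_covariates,
                                   "slope_derived", "introgression_index")],
                           primary = cfg$env_covariates, squeeze = TRUE)
  expect_false("slope_derived" %in% wf$retained_after_cor)
  expect_gte(wf$r2, 0)
  expect_lt(wf$r2, 1)
  expect_lte(wf$fit$aic, fit_beta(env$introgression_index,
                                  env[wf$retained_after_vif],
                                  squeeze = TRUE)$aic + 1e-8)
})
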