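# brute-force partial-likelihood oracle for a single covariate, Breslow ties
pl_oracle <- function(time, event, x, beta) {
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

toy_records <- function() {
  data.frame(seedling_id = paste0("s", 1:5),
             time = c(2L, 4L, 5L, 7L, 9L),
             event = c(1L, 1L, 0L, 1L, 0L))
}

toy_covariates <- function() {
  data.frame(seedling_id = paste0("s", 1:5),
             w = c(0.2, -0.1, 0.5, -0.4, 0.3),
             r = c(0, 0.25, 0.5, 0, 0.1),
             qdis = c(0.8, 0.1, 0.4, 0.9, 0.2),
             fdis = c(0.05, 0.01, 0.03, 0.06, 0.02))
}

test_that("census statuses code into event times with censoring", {
  statuses <- data.frame(seedling_id = c("a", "b"),
                         s1 = c(0L, 0L), s2 = c(0L, 0L), s3 = c(1L, 0L),
                         s4 = c(1L, 0L), s5 = c(1L, 0L))
  rec <- code_survival(statuses)
  expect_equal(rec$time, c(3L, 5L))
  expect_equal(rec$event, c(1L, 0L))
  bad <- data.frame(seedling_id = "z", s1 = 0L, s2 = 1L, s3 = 0L)
  expect_error(code_survival(bad), "dead-then-alive.*z")
})

test_that("empirical survival tracks the generator's discrete-time hazard", {
  cfg <- sim_config(beta = c(w = 0, r = 0, stat = 0), baseline_hazard = 0.05,
                    n_censuses = 10L, rng_seed = 3L, n_adults = 50L,
                    seeds_per_mother = 60L)
  sim <- simulate_study(cfg)
  rec <- code_survival(sim$fitness$survival)
  n <- nrow(rec)
  for (t in c(3L, 10L)) {
    p_surv <- exp(-0.05 * t)             # null-covariate survival to census t
    obs <- mean(rec$time > t | (rec$time == t & rec$event == 0L))
    ci <- 3 * sqrt(p_surv * (1 - p_surv) / n)
    expect_lt(abs(obs - p_surv), ci)
  }
})

test_that("the null Cox model has AIC equal to its deviance", {
  fit <- fit_cox(toy_records(), toy_covariates(), character())
  expect_equal(fit$df, 0L)
  expect_equal(fit$AIC, fit$deviance)
  expect_equal(fit$deviance, -2 * fit$loglik)
})

test_that("fit_cox matches a grid-search partial-likelihood oracle", {
  rec <- toy_records(); cov <- toy_covariates()
  fit <- fit_cox(rec, cov, "qdis")   # no tied event times: efron == breslow
  df <- merge(rec, cov, by = "seedling_id")
  grid <- seq(-6, 2, by = 1e-4)
  ll <- vapply(grid, function(b) pl_oracle(df$time, df$event, df$qdis, b), 0)
  b_star <- grid[which.max(ll)]
  expect_equal(unname(fit$coefficients["qdis"]), b_star, tolerance = 1e-3)
  # the partial-likelihood gradient vanishes at the reported optimum
  eps <- 1e-5
  b <- unname(fit$coefficients["qdis"])
  grad <- (pl_oracle(df$time, df$event, df$qdis, b + eps) -
           pl_oracle(df$time, df$event, df$qdis, b - eps)) / (2 * eps)
  expect_lt(abs(grad), 1e-4)
  # deviance and loglik bookkeeping
  expect_equal(fit$deviance, -2 * max(ll), tolerance = 1e-6)
  expect_equal(fit$AIC, fit$deviance + 2)
  expect_equal(fit$BIC, fit$deviance + log(sum(df$event)))
})

test_that("tie handling choices coincide when no event times are tied", {
  rec <- toy_records(); cov <- toy_covariates()
  fe <- fit_cox(rec, cov, c("w", "qdis"), ties = "efron")
  fb <- fit_cox(rec, cov, c("w", "qdis"), ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
})

test_that("covariate naming carries no positional leakage", {
  rec <- toy_records(); cov <- toy_covariates()
  f1 <- fit_cox(rec, cov, c("w", "qdis"))
  f2 <- fit_cox(rec, cov, c("qdis", "w"))
  expect_equal(f1$coefficients[c("w", "qdis")], f2$coefficients[c("w", "qdis")],
               tolerance = 1e-10)
})

test_that("qdis and fdis are refused in one formula", {
  expect_error(fit_cox(toy_records(), toy_covariates(), c("qdis", "fdis")),
               "separately")
})

test_that("model_table compares nested fits and flags the AIC winner", {
  rec <- toy_records(); cov <- toy_covariates()
  f0 <- fit_cox(rec, cov, character())
  f1 <- fit_cox(rec, cov, "qdis")
  f2 <- fit_cox(rec, cov, c("w", "qdis"))
  tab <- model_table(list(null = f0, qdis = f1, wqdis = f2))
  expect_equal(nrow(tab), 3L)
  expect_gte(f0$deviance, f1$deviance)     # likelihood grows with nesting
  expect_gte(f1$deviance, f2$deviance)
  expect_equal(sum(tab$best_aic), 1L)
  one <- model_table(list(only = f1))
  expect_true(one$best_aic)
  # fits on different record subsets are rejected
  f3 <- fit_cox(rec[1:4, ], cov, "qdis")
  expect_error(model_table(list(f1, f3)), "different record sets")
})

test_that("Kaplan-Meier estimates match the textbook step function", {
  rec <- data.frame(seedling_id = paste0("s", 1:4),
                    time = c(1L, 2L, 3L, 4L), event = c(1L, 1L, 1L, 1L))
  cov <- data.frame(seedling_id = paste0("s", 1:4), qdis = rep(0.5, 4),
                    fdis = rep(0.01, 4))
  km <- suppressWarnings(km_by_group(rec, cov, "qdis"))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # no events: flat at 1
  rec0 <- transform(rec, event = 0L)
  km0 <- suppressWarnings(km_by_group(rec0, cov, "qdis"))
  expect_true(all(km0$surv == 1))
  # empty groups warn
  expect_warning(km_by_group(rec, cov, "qdis"), "empty group")
  expect_error(km_by_group(rec, cov, "qdis", cuts = c(0.5, 0.2)), "increasing")
})

test_that("simulated negative qdis effect is recovered within 2 SE", {
  cfg <- sim_config(rng_seed = 17L)
  sim <- simulate_study(cfg)
  rec <- code_survival(sim$fitness$survival)
  tr <- sim$fitness$covariates_true
  cov <- data.frame(seedling_id = tr$seedling_id, w = tr$w, r = tr$r,
                    qdis = tr$qdis, fdis = tr$fdis)
  fit <- fit_cox(rec, cov, c("w", "qdis"))
  b <- unname(fit$coefficients["qdis"]); se <- unname(fit$se["qdis"])
  expect_lt(b, 0)
  expect_lt(abs(b - (-3.4)), 2 * se)
})
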