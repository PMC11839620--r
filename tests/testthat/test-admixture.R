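# two clusters with disjoint allele sets: the perfectly separable case
separable_table <- function(n_per = 6L, n_loci = 5L) {
  n <- 2L * n_per
  alleles <- array(NA_integer_, dim = c(n, n_loci, 2L))
  for (i in seq_len(n_per)) alleles[i, , ] <- sample(c(102L, 104L), n_loci * 2L, TRUE)
  for (i in (n_per + 1L):n) alleles[i, , ] <- sample(c(120L, 122L), n_loci * 2L, TRUE)
  genotype_table(sprintf("i%02d", seq_len(n)), "p",
                 sprintf("loc%02d", seq_len(n_loci)), alleles)
}

test_that("mean_ln_prob implements the harmonic-approximation estimator", {
  expect_equal(mean_ln_prob(rep(-50, 20)), -50)       # zero variance: L = c
  # ten draws alternating -100/-102: mean -101, sample variance 10/9
  tr10 <- rep(c(-100, -102), 5)
  expect_equal(mean_ln_prob(tr10), -101 - (10 / 9) / 2)
  expect_error(mean_ln_prob(c(-1, -2)), "shorter than 10")
  # a wider trace of the same mean is strictly penalized
  wide <- rep(c(-95, -107), 5)
  expect_lt(mean_ln_prob(wide), mean_ln_prob(tr10))
})

test_that("K = 1 degenerates to all-ones ancestry", {
  set.seed(20)
  g <- separable_table()
  fit <- fit_admixture(g, K = 1, burnin = 100, iters = 500, thin = 5, seed = 1)
  expect_true(all(fit$Q == 1))
  expect_equal(ncol(fit$Q), 1L)
  expect_length(fit$loglik_trace, 100L)
})

test_that("perfectly separable clusters are recovered as near-pure ancestry", {
  set.seed(21)
  g <- separable_table()
  fit <- fit_admixture(g, K = 2, burnin = 500, iters = 2000, thin = 5, seed = 2)
  top_a <- apply(fit$Q[1:6, ], 1, max)
  top_b <- apply(fit$Q[7:12, ], 1, max)
  expect_true(all(top_a > 0.9))
  expect_true(all(top_b > 0.9))
  # the two halves load on different columns
  expect_false(which.max(fit$Q[1, ]) == which.max(fit$Q[12, ]))
})

test_that("Q rows and P slices are simplex-normalized in the posterior means", {
  set.seed(22)
  g <- separable_table(n_per = 4L, n_loci = 3L)
  fit <- fit_admixture(g, K = 2, burnin = 200, iters = 1000, thin = 5, seed = 3)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 8), tolerance = 1e-6)
  for (k in 1:2) {
    rs <- rowSums(fit$P[[k]])
    expect_equal(rs, rep(1, 3), tolerance = 1e-6)
  }
  expect_true(all(fit$F > 0 & fit$F < 1))
})

test_that("evanno_delta_k reproduces the hand-computed table", {
  # craft a run set with deterministic per-replicate L values
  mk_fit <- function(L) {
    # a constant trace has zero variance, so mean_ln_prob returns exactly L
    structure(list(loglik_trace = rep(L, 20), K = 1L), class = "admixture_fit")
  }
  Ls <- list(`1` = c(-5010, -4990), `2` = c(-4010, -3990),
             `3` = c(-3910, -3890), `4` = c(-3900, -3880))
  runs <- lapply(Ls, function(v) lapply(v, mk_fit))
  rs <- structure(list(runs = runs, k_range = 1:4, reps = 2L), class = "run_set")
  ev <- evanno_delta_k(rs)
  # sd of two replicates 20 apart is 14.142; second difference means are 900, 90
  expect_true(all(is.na(ev$delta_K[c(1, 4)])))
  expect_equal(ev$delta_K[2], 900 / sd(c(-4010, -3990)))
  expect_equal(ev$delta_K[3], 90 / sd(c(-3910, -3890)))
  expect_equal(attr(ev, "best_K"), 2L)

  # perfectly linear L in K has zero curvature at the interior points
  runs_lin <- lapply(list(c(-500, -510), c(-400, -410), c(-300, -310),
                          c(-200, -210)), function(v) lapply(v, mk_fit))
  names(runs_lin) <- 1:4
  rs_lin <- structure(list(runs = runs_lin, k_range = 1:4, reps = 2L),
                      class = "run_set")
  expect_equal(evanno_delta_k(rs_lin)$delta_K[2:3], c(0, 0))
})

test_that("evanno_delta_k validates its inputs and flags zero spread", {
  mk_fit <- function(L) structure(list(loglik_trace = rep(L, 20), K = 1L),
                                  class = "admixture_fit")
  runs <- lapply(list(c(-5, -5), c(-4, -4), c(-3, -3)),
                 function(v) lapply(v, mk_fit))
  names(runs) <- 1:3
  rs <- structure(list(runs = runs, k_range = 1:3, reps = 2L), class = "run_set")
  expect_warning(ev <- evanno_delta_k(rs), "Inf")
  expect_equal(ev$delta_K[2], Inf)
  rs$k_range <- c(1L, 3L, 5L)
  expect_error(evanno_delta_k(rs), "contiguous")
})

test_that("align_runs inverts a column permutation exactly", {
  set.seed(23)
  Q <- matrix(rgamma(30, 1), 10); Q <- Q / rowSums(Q)
  fit <- structure(list(Q = Q, F = c(0.1, 0.2, 0.3),
                        P = list("a", "b", "c"), K = 3L),
                   class = "admixture_fit")
  perm <- c(3L, 1L, 2L)
  fit_perm <- fit
  fit_perm$Q <- Q[, perm]; fit_perm$F <- fit$F[perm]; fit_perm$P <- fit$P[perm]
  al <- align_runs(list(fit, fit_perm), reference = 1L)
  expect_equal(al[[2]]$Q, fit$Q)
  expect_equal(al[[2]]$F, fit$F)
  expect_identical(al[[2]]$P, fit$P)
  # K = 1 is the identity
  f1 <- structure(list(Q = matrix(1, 5), F = 0.1, P = list("a"), K = 1L),
                  class = "admixture_fit")
  expect_identical(align_runs(list(f1, f1))[[2]], f1)
  # K mismatch is an error
  expect_error(align_runs(list(fit, f1)), "mismatched K")
})

test_that("replicate runs of the separable case agree after alignment", {
  set.seed(24)
  g <- separable_table()
  fits <- lapply(1:3, function(j)
    fit_admixture(g, K = 2, burnin = 300, iters = 1500, thin = 5, seed = 30 + j))
  al <- align_runs(fits)
  for (j in 2:3)
    expect_lt(mean(abs(al[[j]]$Q - al[[1]]$Q)), 0.05)
})

test_that("estimated drift increases with simulated drift and Q is recovered", {
  # monotonicity of F-hat over generating F, plus ancestry recovery at the
  # study design (182 adults, 10 loci); the Q error bound reflects the
  # posterior uncertainty achievable at this marker informativeness
  fbar <- numeric(3)
  fvals <- c(0.02, 0.1, 0.3)
  for (v in seq_along(fvals)) {
    set.seed(40 + v)
    cfg <- sim_config(K = 2L, F_drift = rep(fvals[v], 2), n_adults = 80L,
                      n_mothers = 2L, admix_alpha = 0.1)
    ad <- simulate_adults(cfg)
    fit <- fit_admixture(ad$genotypes, K = 2, burnin = 500, iters = 3000,
                         thin = 5, seed = 50 + v)
    fbar[v] <- mean(cluster_fst(fit))
  }
  expect_true(fbar[1] < fbar[2] && fbar[2] < fbar[3])

  set.seed(46)
  sim <- simulate_study(sim_config())
  fit <- fit_admixture(sim$adults$genotypes, K = 3, burnin = 2000,
                       iters = 8000, seed = 60)
  perm <- heterofit:::match_columns(fit$Q, sim$adults$truth$Q)
  mae <- mean(abs(fit$Q[, perm] - sim$adults$truth$Q))
  expect_lt(mae, 0.25)
  # loglik trace is stationary after burn-in: no systematic drift
  tr <- fit$loglik_trace
  idx <- seq_along(tr)
  sl <- summary(stats::lm(tr ~ idx))$coefficients
  drift_per_sweep <- abs(sl["idx", "Estimate"]) * length(tr)
  expect_lt(drift_per_sweep, 3 * sd(tr))
})
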