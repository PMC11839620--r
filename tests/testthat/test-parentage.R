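# independent trio-likelihood oracle: enumerate the four meiosis combinations
# (and, for the unrelated-male denominator, every population allele) directly
oracle_lod <- function(off, mom, cand, freqs) {
  total <- 0
  for (l in seq_len(nrow(off))) {
    f <- freqs$freqs[[rownames(off)[l]]]
    same <- function(pair) setequal(paste(sort(pair)), paste(sort(off[l, ])))
    eqpair <- function(a, b) all(sort(a) == sort(b))
    num <- 0
    for (am in mom[l, ]) for (ap in cand[l, ])
      num <- num + 0.25 * eqpair(c(am, ap), off[l, ])
    den <- 0
    for (am in mom[l, ]) for (x in as.integer(names(f)))
      den <- den + 0.5 * f[[as.character(x)]] * eqpair(c(am, x), off[l, ])
    total <- total + log(num) - log(den)
  }
  total
}

test_that("lod_score matches the hand-worked single-locus ratio", {
  # mother A/A, offspring A/B, candidate B/B, freq(B) = 0.1: LOD = ln(1/0.1)
  fr <- list(loc01 = stats::setNames(c(0.9, 0.1), c(102L, 104L)))
  freqs <- structure(list(freqs = fr, n_typed = c(loc01 = 10L)),
                     class = "allele_freq_table")
  off <- gmat(c(102L, 104L)); mom <- gmat(c(102L, 102L)); cand <- gmat(c(104L, 104L))
  expect_equal(lod_score(off, mom, cand, freqs, error_rate = 0), log(1 / 0.1),
               tolerance = 1e-12)
  # an incompatible candidate at e = 0 is excluded with -Inf
  cand2 <- gmat(c(102L, 102L))
  off2 <- gmat(c(104L, 104L))
  mom2 <- gmat(c(104L, 104L))
  expect_equal(lod_score(off2, mom2, cand2, freqs, error_rate = 0), -Inf)
})

test_that("lod_score equals the enumeration oracle on random trios", {
  set.seed(30)
  freqs <- make_freqs(n_loci = 3L, n_alleles = 4L,
                      probs = c(0.4, 0.3, 0.2, 0.1))
  for (i in 1:25) {
    mom <- draw_hw_matrix(freqs); dad <- draw_hw_matrix(freqs)
    off <- mendel_offspring(mom, dad)
    cand <- if (i %% 2) dad else draw_hw_matrix(freqs)
    ours <- lod_score(off, mom, cand, freqs, error_rate = 0)
    orc <- oracle_lod(off, mom, cand, freqs)
    expect_equal(ours, orc, tolerance = 1e-10)
  }
})

test_that("the best candidate agrees with exhaustive enumeration on small problems", {
  set.seed(31)
  freqs <- make_freqs(n_loci = 3L, n_alleles = 4L, probs = c(0.4, 0.3, 0.2, 0.1))
  for (rep in 1:10) {
    cands <- lapply(1:5, function(i) draw_hw_matrix(freqs))
    mom <- draw_hw_matrix(freqs)
    off <- mendel_offspring(mom, cands[[sample(5, 1)]])
    lods <- vapply(cands, function(cc)
      lod_score(off, mom, cc, freqs, error_rate = 0.001), 0)
    orc <- vapply(cands, function(cc) {
      # same enumeration oracle with the error mixture applied per locus
      tot <- 0
      for (l in 1:3) {
        f <- freqs$freqs[[l]]
        eqpair <- function(a, b) all(sort(a) == sort(b))
        num <- 0
        for (am in mom[l, ]) for (ap in cc[l, ])
          num <- num + 0.25 * eqpair(c(am, ap), off[l, ])
        den <- 0
        for (am in mom[l, ]) for (x in as.integer(names(f)))
          den <- den + 0.5 * f[[as.character(x)]] * eqpair(c(am, x), off[l, ])
        pa <- f[[as.character(off[l, 1])]]; pb <- f[[as.character(off[l, 2])]]
        phw <- if (off[l, 1] == off[l, 2]) pa^2 else 2 * pa * pb
        tot <- tot + log(0.999 * num + 0.001 * phw) - log(0.999 * den + 0.001 * phw)
      }
      tot
    }, 0)
    expect_equal(lods, orc, tolerance = 1e-10)
    expect_equal(which.max(lods), which.max(orc))
  }
})

test_that("random unrelated candidates average a negative LOD", {
  set.seed(32)
  freqs <- make_freqs()
  lods <- replicate(200, {
    mom <- draw_hw_matrix(freqs); dad <- draw_hw_matrix(freqs)
    off <- mendel_offspring(mom, dad)
    lod_score(off, mom, draw_hw_matrix(freqs), freqs, error_rate = 0.001)
  })
  expect_lt(mean(lods), 0)
})

test_that("mismatch_count detects trio incompatibilities", {
  freqs <- make_freqs(n_loci = 2L, n_alleles = 4L)
  mom <- gmat(c(102L, 104L), c(102L, 102L))
  dad <- gmat(c(106L, 108L), c(104L, 106L))
  set.seed(33)
  off <- mendel_offspring(mom, dad)
  expect_equal(mismatch_count(off, mom, dad), 0L)
  # candidate homozygous for an allele absent from the offspring, and the
  # mother cannot supply both offspring alleles: one mismatch
  off2 <- gmat(c(102L, 106L), c(102L, 104L))
  cand <- gmat(c(108L, 108L), c(104L, 104L))
  expect_equal(mismatch_count(off2, mom, cand), 1L)
})

test_that("unrelated candidates typically mismatch at several of 10 loci", {
  set.seed(34)
  freqs <- make_freqs()
  mms <- replicate(200, {
    mom <- draw_hw_matrix(freqs); dad <- draw_hw_matrix(freqs)
    off <- mendel_offspring(mom, dad)
    mismatch_count(off, mom, draw_hw_matrix(freqs))
  })
  expect_gte(stats::median(mms), 2)
})

test_that("delta calibration hits the exclusive-marker and monotonicity limits", {
  set.seed(35)
  # highly exclusive markers: 40 equifrequent alleles per locus
  freqs_strong <- make_freqs(n_loci = 10L, n_alleles = 40L)
  cal <- calibrate_delta(freqs_strong, n_sim = 1000L, n_candidates = 30L,
                         error_rate = 0, seed = 36)
  expect_equal(cal$delta_crit, 0)
  # default-informativeness panel: finite, and more candidates never easier
  freqs10 <- make_freqs()
  cal_small <- calibrate_delta(freqs10, n_sim = 2000L, n_candidates = 50L,
                               error_rate = 0.001, seed = 37)
  cal_big <- calibrate_delta(freqs10, n_sim = 2000L, n_candidates = 100L,
                             error_rate = 0.001, seed = 37)
  expect_true(is.finite(cal_small$delta_crit))
  expect_gte(cal_big$delta_crit, cal_small$delta_crit)
  expect_error(calibrate_delta(freqs10, n_sim = 10L), "at least 1000")
})

test_that("paternity categories follow the decision rules and sum to cohort size", {
  set.seed(38)
  cfg <- sim_config(n_adults = 60L, n_mothers = 4L, seeds_per_mother = 30L,
                    rng_seed = 11L)
  sim <- simulate_study(cfg)
  adults <- sim$adults$genotypes; seedlings <- sim$seedlings$genotypes
  freqs <- allele_frequencies(list(adults, seedlings))
  calib <- calibrate_delta(freqs, n_sim = 2000L, n_candidates = 60L,
                           error_rate = 0.001, seed = 39)
  mothers <- stats::setNames(sim$seedlings$truth$mother_id, seedlings$ids)
  rec <- assign_paternity(seedlings, mothers, adults, freqs, calib)
  expect_equal(nrow(rec), n_individuals(seedlings))
  expect_true(all(rec$category %in% c("selfing", "immigrant",
                                      "ambiguous_multiple", "single_donor")))
  expect_true(all(rec$delta >= 0))
  # Table-2-style bookkeeping: per-mother counts sum to the cohort
  ps <- parentage_summary(rec)
  tot <- ps[ps$mother_id == "Total", ]
  expect_equal(as.integer(tot$n_seedlings), n_individuals(seedlings))
  expect_equal(as.integer(tot$selfing) + as.integer(tot$immigrant) +
                 as.integer(tot$ambiguous_multiple) + as.integer(tot$single_donor),
               n_individuals(seedlings))
  # recovery against the generator truth
  tr <- sim$seedlings$truth
  oc <- tr$category == "outcross"
  hit <- rec$category[oc] == "single_donor" & rec$best_father_id[oc] == tr$father_id[oc]
  expect_gte(mean(hit), 0.95)
  selfed <- tr$category == "selfing"
  expect_gte(mean(rec$category[selfed] == "selfing"), 0.90)
  # immigrants are flagged exactly when the best candidate over-mismatches
  # (the selfing rule fires first, so exclude mother-as-best cases)
  imm <- which(tr$category == "immigrant" & rec$category != "selfing")
  expect_equal(rec$category[imm] == "immigrant", rec$mismatches[imm] > 2)
  expect_true(all(rec$mismatches[rec$category == "immigrant"] > 2))
})

test_that("a seedling with an unknown mother is rejected", {
  set.seed(40)
  cfg <- sim_config(n_adults = 20L, n_mothers = 2L, seeds_per_mother = 5L)
  sim <- simulate_study(cfg)
  freqs <- allele_frequencies(sim$adults$genotypes)
  calib <- structure(list(delta_crit = 0, confidence = 0.95),
                     class = "delta_calibration")
  mothers <- stats::setNames(sim$seedlings$truth$mother_id,
                             sim$seedlings$genotypes$ids)
  mothers <- mothers[-1]
  expect_error(assign_paternity(sim$seedlings$genotypes, mothers,
                                sim$adults$genotypes, freqs, calib),
               "unknown mother")
})
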