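#' Configuration for the forward simulator
#'
#' Defaults emulate the study system the package targets: a ~6 ha dipterocarp
#' plot with 182 reproductive adults structured into three admixed clusters
#' (two well differentiated, one close to the ancestral admixed pool), ten
#' microsatellite loci, six mother trees each contributing ~98 seeds, with
#' realized selfing and immigrant-pollen fractions of about 9% and 10% of
#' seedlings, monthly survival censuses and 6-month height censuses.
#'
#' @param K number of ancestral clusters.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param F_drift per-cluster drift from the ancestral admixed population
#'   (the F of the correlated-frequency model), all in (0,1).
#' @param n_adults number of candidate adults in the plot.
#' @param n_mothers number of mother trees (chosen among the adults).
#' @param seeds_per_mother seeds collected per mother.
#' @param selfing_rate probability a seed is selfed.
#' @param immigrant_rate probability the father is outside the plot.
#' @param mistyping_rate per-allele probability that a recorded allele is
#'   replaced by a random allele of the locus.
#' @param admix_alpha Dirichlet concentration used to draw adult ancestry
#'   vectors; 0.2 gives many near-pure individuals plus a tail of admixed
#'   ones, the pattern seen in tropical-tree admixture bar plots.
#' @param fst_signed signed per-cluster differentiation vector used for the
#'   fdis covariate (two opposed differentiated poles and a near-zero
#'   undifferentiated cluster).
#' @param beta named survival log-hazard coefficients (w, r, stat).
#' @param survival_stat which ancestry statistic drives the hazard,
#'   "qdis" or "fdis".
#' @param baseline_hazard per-census baseline hazard of the discrete-time
#'   proportional-hazards process.
#' @param n_censuses number of (monthly) survival censuses.
#' @param census_days days between survival censuses.
#' @param growth named growth-model parameters: intercept, b_stat, b_r, b_w
#'   (per-day RGR scale), tau (sd of the mother-level random intercept) and
#'   sigma (residual sd, recycled over periods).
#' @param growth_stat ancestry statistic entering the growth mean, "qdis" or
#'   "fdis".
#' @param n_periods number of 6-month growth periods.
#' @param period_days days per growth period.
#' @param seed_weight_meanlog,seed_weight_sdlog lognormal seed weight (g).
#' @param couple_weight_to_mother if TRUE, seed weight gets a mother-specific
#'   lognormal shift (sensitivity switch; off by default).
#' @param rng_seed integer seed for the single global RNG used by
#'   \code{\link{simulate_study}}.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(K = 3L,
                       n_loci = 10L,
                       alleles_per_locus = 8L,
                       F_drift = c(0.10, 0.01, 0.10),
                       n_adults = 182L,
                       n_mothers = 6L,
                       seeds_per_mother = 98L,
                       selfing_rate = 0.09,
                       immigrant_rate = 0.10,
                       mistyping_rate = 0,
                       admix_alpha = 0.2,
                       fst_signed = c(0.10552, 0.00044, -0.10342),
                       beta = c(w = 0, r = 0, stat = -3.4),
                       survival_stat = "qdis",
                       baseline_hazard = 0.03,
                       n_censuses = 30L,
                       census_days = 30L,
                       growth = list(intercept = 0.004, b_stat = 0.002,
                                     b_r = 0, b_w = 0, tau = 5e-4,
                                     sigma = 1e-3),
                       growth_stat = "qdis",
                       n_periods = 5L,
                       period_days = 182L,
                       seed_weight_meanlog = 0,
                       seed_weight_sdlog = 0.25,
                       couple_weight_to_mother = FALSE,
                       rng_seed = 1L) {
  if (length(F_drift) != K) stop("F_drift must have length K")
  if (any(F_drift <= 0 | F_drift >= 1)) stop("F_drift values must lie in (0,1)")
  if (selfing_rate < 0 || immigrant_rate < 0 || selfing_rate + immigrant_rate > 1)
    stop("config error: selfing_rate + immigrant_rate must lie in [0,1]")
  if (n_mothers > n_adults) stop("n_mothers cannot exceed n_adults")
  if (baseline_hazard < 0) stop("config error: baseline hazard must be non-negative")
  if (!survival_stat %in% c("qdis", "fdis")) stop("survival_stat must be qdis or fdis")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  # guard against all-zero rows at tiny alpha
  x[x == 0] <- .Machine$double.xmin
  x / rowSums(x)
}

allele_code <- function(idx) 100L + 2L * as.integer(idx)

#' Simulate adult genotypes under the admixture F-model
#'
#' Ancestral allele frequencies are symmetric-Dirichlet(1); cluster
#' frequencies drift from them as Dirichlet(p_anc (1-F_k)/F_k); each
#' individual's ancestry vector Q is Dirichlet(admix_alpha); every allele
#' copy picks a cluster from Q and then an allele from that cluster's
#' frequencies. Draws come from the current RNG state (seed once, upstream).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (a \code{genotype_table}) and
#'   \code{truth} (ancestry matrix Q, cluster frequencies P, ancestral
#'   frequencies, mother ids).
#' @export
simulate_adults <- function(cfg) {
  K <- cfg$K; L <- cfg$n_loci; A <- cfg$alleles_per_locus; n <- cfg$n_adults
  p_anc <- rdirichlet(L, rep(1, A))                       # L x A
  P <- array(NA_real_, dim = c(K, L, A))
  for (k in seq_len(K)) {
    scale <- (1 - cfg$F_drift[k]) / cfg$F_drift[k]
    for (l in seq_len(L)) P[k, l, ] <- rdirichlet(1, p_anc[l, ] * scale)
  }
  Q <- if (K == 1L) matrix(1, n, 1L) else rdirichlet(n, rep(cfg$admix_alpha, K))
  ids <- sprintf("adult%03d", seq_len(n))
  alleles <- array(NA_integer_, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    for (s in 1:2) {
      z <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
      # per-locus allele draw from the chosen cluster's frequencies
      idx <- vapply(seq_len(L),
                    function(l) sample.int(A, 1L, prob = P[z[l], l, ]), 0L)
      alleles[i, , s] <- allele_code(idx)
    }
  }
  loci <- sprintf("loc%02d", seq_len(L))
  g <- genotype_table(ids, "plot", loci, alleles)
  mothers <- sort(sample(ids, cfg$n_mothers))
  rownames(Q) <- ids
  list(genotypes = g,
       truth = list(Q = Q, P = P, p_anc = p_anc, mothers = mothers))
}

draw_hw_genotype <- function(p_anc) {
  L <- nrow(p_anc); A <- ncol(p_anc)
  a <- matrix(NA_integer_, L, 2L)
  for (s in 1:2)
    a[, s] <- allele_code(vapply(seq_len(L),
                                 function(l) sample.int(A, 1L, prob = p_anc[l, ]), 0L))
  a
}

#' Simulate matings and seedling genotypes
#'
#' Each seed is selfed with probability \code{selfing_rate}, sired by an
#' immigrant (a fresh genotype drawn from the ancestral frequencies, absent
#' from the candidate list) with probability \code{immigrant_rate}, and
#' otherwise by a father drawn uniformly from the plot adults. Offspring
#' inherit one Mendelian allele per parent per locus; an optional per-allele
#' mistyping replaces a recorded allele with a random allele of the locus.
#'
#' @param adults result of \code{\link{simulate_adults}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (seedling \code{genotype_table}) and
#'   \code{truth} (data.frame: seedling_id, mother_id, father_id, category;
#'   plus the father ancestry matrix \code{Q_father} with immigrant rows at
#'   the flat ancestral ancestry 1/K).
#' @export
simulate_matings <- function(adults, cfg) {
  g <- adults$genotypes
  tr <- adults$truth
  K <- cfg$K; L <- cfg$n_loci; A <- cfg$alleles_per_locus
  mothers <- tr$mothers
  n_seed <- cfg$n_mothers * cfg$seeds_per_mother
  sid <- character(n_seed); mid <- character(n_seed); fid <- character(n_seed)
  category <- character(n_seed)
  alleles <- array(NA_integer_, dim = c(n_seed, L, 2L))
  Qf <- matrix(NA_real_, n_seed, K)
  imm_count <- 0L
  s <- 0L
  for (m in mothers) {
    gm <- extract_genotype(g, m)
    for (r in seq_len(cfg$seeds_per_mother)) {
      s <- s + 1L
      sid[s] <- sprintf("seedling%04d", s)
      mid[s] <- m
      u <- stats::runif(1)
      if (u < cfg$selfing_rate) {
        category[s] <- "selfing"; fid[s] <- m; gf <- gm
        Qf[s, ] <- tr$Q[m, ]
      } else if (u < cfg$selfing_rate + cfg$immigrant_rate) {
        category[s] <- "immigrant"
        imm_count <- imm_count + 1L
        fid[s] <- sprintf("immigrant%03d", imm_count)
        gf <- draw_hw_genotype(tr$p_anc)
        Qf[s, ] <- rep(1 / K, K)   # ancestral admixed pollen pool
      } else {
        category[s] <- "outcross"
        f <- sample(setdiff(g$ids, m), 1L)
        fid[s] <- f; gf <- extract_genotype(g, f)
        Qf[s, ] <- tr$Q[f, ]
      }
      pick <- function(gp) gp[cbind(seq_len(L), sample(c(1L, 2L), L, replace = TRUE))]
      a <- cbind(pick(gm), pick(gf))
      if (cfg$mistyping_rate > 0) {
        err <- matrix(stats::runif(2L * L) < cfg$mistyping_rate, L, 2L)
        if (any(err)) a[err] <- allele_code(sample.int(A, sum(err), replace = TRUE))
      }
      alleles[s, , ] <- a
    }
  }
  gs <- genotype_table(sid, "nursery", g$loci, alleles)
  rownames(Qf) <- sid
  list(genotypes = gs,
       truth = data.frame(seedling_id = sid, mother_id = mid, father_id = fid,
                          category = category, stringsAsFactors = FALSE),
       Q_father = Qf)
}

#' Simulate seedling fitness (survival and growth) from the true pedigree
#'
#' Computes the true per-seedling covariates — seed weight (lognormal),
#' pedigree relatedness of the parent pair (1 selfed, 0 otherwise), and
#' qdis/fdis from the true ancestry vectors — then runs a discrete-time
#' proportional-hazards survival process (per census, death probability
#' 1 - exp(-h0 exp(x'beta))) and a log-linear growth process with a
#' mother-level random intercept and per-period Gaussian RGR noise.
#'
#' @param matings result of \code{\link{simulate_matings}}.
#' @param adults result of \code{\link{simulate_adults}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{phenotypes} (seedling_id, mother_id, w),
#'   \code{survival} (wide 0/1 status matrix, one column per census),
#'   \code{heights} (long seedling_id, date, height_cm),
#'   \code{covariates_true} (w, r, qdis, fdis and the survival linear
#'   predictor per seedling).
#' @export
simulate_fitness <- function(matings, adults, cfg) {
  tr <- matings$truth
  n <- nrow(tr)
  Qm <- adults$truth$Q[tr$mother_id, , drop = FALSE]
  Qf <- matings$Q_father
  w <- stats::rlnorm(n, cfg$seed_weight_meanlog, cfg$seed_weight_sdlog)
  if (isTRUE(cfg$couple_weight_to_mother)) {
    shift <- stats::rnorm(cfg$n_mothers, 0, 0.2)
    names(shift) <- adults$truth$mothers
    w <- w * exp(shift[tr$mother_id])
  }
  r_true <- ifelse(tr$category == "selfing", 1, 0)
  qd <- vapply(seq_len(n), function(i) qdis(Qm[i, ], Qf[i, ]), 0)
  fd <- vapply(seq_len(n), function(i) fdis(Qm[i, ], Qf[i, ], cfg$fst_signed), 0)
  stat <- if (cfg$survival_stat == "qdis") qd else fd
  eta <- cfg$beta[["w"]] * w + cfg$beta[["r"]] * r_true + cfg$beta[["stat"]] * stat

  # discrete-time proportional hazards
  p_die <- 1 - exp(-cfg$baseline_hazard * exp(eta))
  status <- matrix(0L, n, cfg$n_censuses)
  death_census <- rep(NA_integer_, n)
  for (t in seq_len(cfg$n_censuses)) {
    alive <- is.na(death_census)
    dies <- alive & (stats::runif(n) < p_die)
    death_census[dies] <- t
    status[!is.na(death_census) & death_census <= t, t] <- 1L
  }
  survival <- data.frame(seedling_id = tr$seedling_id, status,
                         stringsAsFactors = FALSE)
  names(survival) <- c("seedling_id", sprintf("status_%02d", seq_len(cfg$n_censuses)))

  # growth: lognormal initial height, per-period RGR with family random effect
  gw <- cfg$growth
  sigma <- rep(gw$sigma, length.out = cfg$n_periods)
  u <- stats::rnorm(cfg$n_mothers, 0, gw$tau)
  names(u) <- adults$truth$mothers
  gstat <- if (cfg$growth_stat == "qdis") qd else fd
  H <- matrix(NA_real_, n, cfg$n_periods + 1L)
  H[, 1L] <- stats::rlnorm(n, log(15), 0.2)
  death_day <- ifelse(is.na(death_census), Inf, death_census * cfg$census_days)
  for (p in seq_len(cfg$n_periods)) {
    mu <- gw$intercept + gw$b_stat * gstat + gw$b_r * r_true + gw$b_w * w +
      u[tr$mother_id]
    rgr <- mu + stats::rnorm(n, 0, sigma[p])
    H[, p + 1L] <- H[, p] * exp(rgr * cfg$period_days)
    H[p * cfg$period_days > death_day, p + 1L] <- NA_real_
  }
  dates <- (0:cfg$n_periods) * cfg$period_days
  heights <- data.frame(
    seedling_id = rep(tr$seedling_id, cfg$n_periods + 1L),
    date = rep(dates, each = n),
    height_cm = as.vector(H), stringsAsFactors = FALSE)
  heights <- heights[!is.na(heights$height_cm), ]
  heights <- heights[order(heights$seedling_id, heights$date), ]
  rownames(heights) <- NULL

  list(phenotypes = data.frame(seedling_id = tr$seedling_id,
                               mother_id = tr$mother_id, w = w,
                               stringsAsFactors = FALSE),
       survival = survival,
       heights = heights,
       covariates_true = data.frame(seedling_id = tr$seedling_id, w = w,
                                    r = r_true, qdis = qd, fdis = fd,
                                    eta = as.numeric(eta),
                                    stringsAsFactors = FALSE))
}

#' Run the full forward simulation under one global RNG seed
#'
#' @param cfg a \code{\link{sim_config}}; \code{cfg$rng_seed} seeds the
#'   single global RNG from which every draw flows.
#' @return list with \code{adults}, \code{seedlings} (matings result) and
#'   \code{fitness}, plus \code{cfg}.
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  adults <- simulate_adults(cfg)
  seedlings <- simulate_matings(adults, cfg)
  fitness <- simulate_fitness(seedlings, adults, cfg)
  list(adults = adults, seedlings = seedlings, fitness = fitness, cfg = cfg)
}
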