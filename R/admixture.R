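# Index-code a genotype table: per locus, alleles are mapped to 1..A in
# sorted-code order; 0 marks missing. Used by the admixture sampler and the
# paternity engine, which both work on dense integer indices.
encode_genotypes <- function(g, allele_codes = NULL) {
  L <- length(g$loci)
  n <- length(g$ids)
  if (is.null(allele_codes)) {
    allele_codes <- lapply(seq_len(L), function(j)
      sort(unique(as.vector(g$alleles[, j, ]))))
    names(allele_codes) <- g$loci
  }
  geno <- matrix(0L, n, 2L * L)
  for (j in seq_len(L)) {
    for (s in 1:2) {
      idx <- match(g$alleles[, j, s], allele_codes[[j]])
      idx[is.na(idx) & !is.na(g$alleles[, j, s])] <- 0L  # unseen allele -> missing
      idx[is.na(idx)] <- 0L
      geno[, 2L * (j - 1L) + s] <- idx
    }
  }
  list(geno = geno, n_alleles = vapply(allele_codes, length, 0L),
       allele_codes = allele_codes)
}

#' Fit the admixture model with correlated allele frequencies
#'
#' A Gibbs sampler for the Bayesian clustering model in which each
#' individual's genome is a mixture over K clusters and cluster allele
#' frequencies drift from a shared ancestral frequency vector with
#' per-cluster drift parameter F_k (interpretable as that cluster's Fst from
#' the ancestral admixed population). Latent per-allele-copy origins, Q and
#' the cluster frequencies get conjugate updates; the ancestral frequencies,
#' F_k and the shared admixture concentration alpha get Metropolis updates
#' (truncated-normal(0.01, 0.05) prior on F_k, uniform(0, 10) prior on
#' alpha, ancestral-frequency Dirichlet parameter lambda fixed at 1).
#'
#' @param g a \code{genotype_table}.
#' @param K number of clusters (>= 1).
#' @param burnin discarded sweeps.
#' @param iters retained sweeps after burn-in.
#' @param thin record every \code{thin}-th retained sweep.
#' @param seed optional integer; if given, seeds the RNG before sampling.
#' @param f_prior_mean,f_prior_sd truncated-normal prior for F_k.
#' @param f_prop_sd Metropolis proposal sd for F_k.
#' @param alpha_prop_sd Metropolis proposal sd for alpha.
#' @return an \code{admixture_fit}: list with \code{Q} (n x K posterior mean
#'   ancestry), \code{P} (per-cluster locus x allele frequencies), \code{F}
#'   (per-cluster drift), \code{alpha}, \code{loglik_trace}, \code{K},
#'   \code{ids}, \code{loci}, \code{allele_codes}.
#' @export
fit_admixture <- function(g, K, burnin = 2000L, iters = 10000L, thin = 10L,
                          seed = NULL, f_prior_mean = 0.01, f_prior_sd = 0.05,
                          f_prop_sd = 0.02, alpha_prop_sd = 0.025) {
  if (K < 1L) stop("K must be >= 1")
  if (iters <= 0L || burnin < 0L) stop("iters must be positive")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_genotypes(g)
  if (K > 1L && all(enc$n_alleles == 1L))
    warning("all loci monomorphic: F_k unidentifiable with K > 1")
  res <- admixture_gibbs(enc$geno, enc$n_alleles, as.integer(K),
                         as.integer(burnin), as.integer(iters),
                         as.integer(thin), 1.0, f_prior_mean, f_prior_sd,
                         f_prop_sd, 1.0, 10.0, alpha_prop_sd)
  rownames(res$Q) <- g$ids
  fit <- list(Q = res$Q, P = res$P, F = as.numeric(res$F),
              alpha = res$alpha, loglik_trace = as.numeric(res$loglik_trace),
              K = as.integer(K), ids = g$ids, loci = g$loci,
              allele_codes = enc$allele_codes)
  class(fit) <- "admixture_fit"
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ",", length(x$ids), "individuals\n")
  cat("F_k:", paste(sprintf("%.4f", x$F), collapse = " "),
      " alpha:", sprintf("%.3f", x$alpha), "\n")
  cat("mean ln P(X|K):", sprintf("%.2f", mean_ln_prob(x)), "\n")
  invisible(x)
}

#' Model log-probability estimate from the likelihood trace
#'
#' The harmonic-approximation estimator \code{mean(trace) - var(trace)/2}
#' used to score K in the clustering literature; larger is better, and the
#' variance term penalises poorly mixing runs.
#'
#' @param fit an \code{admixture_fit} (or a bare numeric trace).
#' @return scalar estimate of ln P(X | K).
#' @export
mean_ln_prob <- function(fit) {
  trace <- if (inherits(fit, "admixture_fit")) fit$loglik_trace else fit
  if (length(trace) < 10L) stop("likelihood trace shorter than 10 recorded samples")
  mean(trace) - stats::var(trace) / 2
}

#' Replicate admixture runs over a range of K
#'
#' @param g a \code{genotype_table}.
#' @param k_range integer vector of K values (contiguous for delta-K).
#' @param reps replicates per K.
#' @param seed integer; replicate j of K value k runs with seed
#'   \code{seed + 1000*k + j} so the set is reproducible and runs are
#'   independent.
#' @param ... passed to \code{\link{fit_admixture}}.
#' @return a \code{run_set}: list of lists of fits, indexed
#'   \code{runs[[as.character(K)]][[rep]]}.
#' @export
run_admixture_set <- function(g, k_range = 1:6, reps = 5L, seed = 1L, ...) {
  runs <- lapply(k_range, function(k) {
    lapply(seq_len(reps), function(j)
      fit_admixture(g, K = k, seed = seed + 1000L * k + j, ...))
  })
  names(runs) <- as.character(k_range)
  structure(list(runs = runs, k_range = k_range, reps = reps),
            class = "run_set")
}

#' Evanno delta-K table for selecting the number of clusters
#'
#' For each interior K, \code{deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))}
#' with L the per-replicate model log-probability. Endpoints are reported as
#' NA and are never candidates.
#'
#' @param runset a \code{run_set} from \code{\link{run_admixture_set}}.
#' @return data.frame with columns K, mean_L, sd_L, delta_K, and attribute
#'   \code{"best_K"} (argmax of delta_K over interior K).
#' @export
evanno_delta_k <- function(runset) {
  ks <- runset$k_range
  if (length(ks) < 3L) stop("delta-K needs at least 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K range must be contiguous")
  if (runset$reps < 2L) stop("delta-K needs >= 2 replicates per K")
  Lmat <- sapply(runset$runs, function(fits) vapply(fits, mean_ln_prob, 0))
  Lmat <- matrix(Lmat, nrow = runset$reps)   # reps x K
  mean_L <- colMeans(Lmat)
  sd_L <- apply(Lmat, 2L, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))]) {
    # mean over replicates of |L''(K)|, scaled by the replicate sd at K
    second <- abs(Lmat[, i + 1L] - 2 * Lmat[, i] + Lmat[, i - 1L])
    if (sd_L[i] == 0) {
      warning("sd(L) = 0 at K = ", ks[i], "; delta-K reported as Inf")
      dk[i] <- Inf
    } else dk[i] <- mean(second) / sd_L[i]
  }
  out <- data.frame(K = ks, mean_L = mean_L, sd_L = sd_L, delta_K = dk)
  rownames(out) <- NULL
  attr(out, "best_K") <- ks[which.max(ifelse(is.na(dk), -Inf, dk))]
  out
}

# greedy column matching of Q against a reference Q; returns the permutation
# perm with aligned = Q[, perm]
match_columns <- function(Q, ref) {
  K <- ncol(Q)
  perm <- integer(K)
  used <- rep(FALSE, K)
  score <- crossprod(ref, Q)   # score[r, c] = ref col r . Q col c
  for (step in seq_len(K)) {
    # best remaining (reference column, run column) pair; ties break to the
    # lowest column index by the order of which.max over the flattened matrix
    masked <- score
    masked[, used] <- -Inf
    best <- which(masked == max(masked), arr.ind = TRUE)[1L, ]
    perm[best[1L]] <- best[2L]
    used[best[2L]] <- TRUE
    score[best[1L], ] <- -Inf
  }
  perm
}

#' Align replicate runs by greedy label matching
#'
#' Cluster labels are arbitrary across MCMC replicates. This permutes each
#' run's Q columns (and F, P) to maximise the summed dot-product with a
#' reference replicate's Q, greedily and with deterministic lowest-index
#' tie-breaks; an exact inverse for column-permuted copies of a run.
#'
#' @param fits list of \code{admixture_fit}s sharing K and individual order.
#' @param reference index of the reference replicate.
#' @return list of fits with columns aligned to the reference.
#' @export
align_runs <- function(fits, reference = 1L) {
  K <- unique(vapply(fits, function(f) f$K, 0L))
  if (length(K) != 1L) stop("runs have mismatched K")
  if (K == 1L) return(fits)
  ref <- fits[[reference]]$Q
  lapply(fits, function(f) {
    perm <- match_columns(f$Q, ref)
    f$Q <- f$Q[, perm, drop = FALSE]
    f$F <- f$F[perm]
    f$P <- f$P[perm]
    f
  })
}

#' Per-cluster drift (Fst from the ancestral admixed population)
#'
#' @param fit an \code{admixture_fit} (aligned if comparing across runs).
#' @return numeric vector of posterior-mean F_k in cluster (Q column) order.
#' @export
cluster_fst <- function(fit) fit$F

#' Average aligned replicate runs into one consensus fit
#'
#' @param fits list of \code{admixture_fit}s (same K, same individuals).
#' @param reference replicate used as the alignment reference.
#' @return an \code{admixture_fit} whose Q and F are the across-replicate
#'   means of the aligned runs.
#' @export
consensus_fit <- function(fits, reference = 1L) {
  al <- align_runs(fits, reference)
  out <- al[[1L]]
  out$Q <- Reduce(`+`, lapply(al, function(f) f$Q)) / length(al)
  out$Q <- out$Q / rowSums(out$Q)
  out$F <- Reduce(`+`, lapply(al, function(f) f$F)) / length(al)
  out$alpha <- mean(vapply(al, function(f) f$alpha, 0))
  out
}

#' Write a Q matrix as CSV (individual, Q1..QK)
#' @param fit an \code{admixture_fit}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_q_matrix <- function(fit, path) {
  df <- data.frame(individual = fit$ids, fit$Q, stringsAsFactors = FALSE)
  names(df) <- c("individual", paste0("Q", seq_len(fit$K)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
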