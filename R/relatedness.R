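# Per-locus probabilities of an unordered genotype pair given m = 0, 1, 2
# alleles shared identical by descent (outbred pairs, no inbreeding).
# Returns a 3 x L matrix (rows S0, S1, S2); untyped loci are dropped.
pair_locus_probs <- function(g_i, g_j, freqs) {
  loci <- names(freqs$freqs)
  if (is.null(rownames(g_i))) rownames(g_i) <- loci
  if (is.null(rownames(g_j))) rownames(g_j) <- loci
  S <- matrix(NA_real_, 3L, length(loci))
  for (l in seq_along(loci)) {
    gi <- g_i[loci[l], ]; gj <- g_j[loci[l], ]
    if (anyNA(gi) || anyNA(gj)) next
    f <- freqs$freqs[[l]]
    p <- function(x) {
      v <- f[as.character(x)]
      if (anyNA(v)) stop("allele ", x[is.na(v)][1L], " absent from frequency table at ",
                         loci[l])
      as.numeric(v)
    }
    a <- gi[1L]; b <- gi[2L]; cc <- gj[1L]; d <- gj[2L]
    pg <- function(x, y) if (x == y) p(x)^2 else 2 * p(x) * p(y)
    s0 <- pg(a, b) * pg(cc, d)
    s2 <- if ((a == cc && b == d) || (a == d && b == cc)) pg(a, b) else 0
    # one IBD allele t: i = {t, x}, j = {t, y}, x and y independent draws
    s1 <- 0
    for (t in unique(c(a, b))) {
      x <- if (a == t) b else a              # i's non-IBD allele
      share_j <- (cc == t) + (d == t)
      if (share_j == 0) next
      if (cc == t && d == t) {
        s1 <- s1 + p(t) * p(x) * p(t)        # y must equal t
      } else {
        y <- if (cc == t) d else cc
        s1 <- s1 + p(t) * p(x) * p(y)
      }
    }
    S[, l] <- c(s0, s1, s2)
  }
  S[, !is.na(S[1L, ]), drop = FALSE]
}

#' Pairwise-relatedness log-likelihood at fixed IBD coefficients
#'
#' Multi-locus log-likelihood of an unordered genotype pair given
#' k = (k0, k1, k2), the probabilities of sharing 0, 1 or 2 alleles
#' identical by descent: \code{sum_l ln(k0 S0 + k1 S1 + k2 S2)} with S_m the
#' per-locus genotype-pair probabilities (outbred model).
#'
#' @param g_i,g_j loci x 2 integer genotype matrices with locus rownames.
#' @param freqs an \code{allele_freq_table}.
#' @param k numeric length-3 vector (k0, k1, k2) on the simplex.
#' @return scalar log-likelihood.
#' @export
pair_loglik <- function(g_i, g_j, freqs, k) {
  if (length(k) != 3L || any(k < 0) || abs(sum(k) - 1) > 1e-9)
    stop("k must be a length-3 probability vector summing to 1")
  S <- pair_locus_probs(g_i, g_j, freqs)
  if (ncol(S) == 0L) stop("no shared typed loci for the pair")
  sum(log(pmax(as.numeric(k %*% S), 1e-300)))
}

# all (k0, k1) grid points with k0 + k1 <= 1, as a G x 3 simplex matrix
simplex_grid <- function(step, k0_range = c(0, 1), k1_range = c(0, 1)) {
  k0 <- seq(max(0, k0_range[1L]), min(1, k0_range[2L]), by = step)
  k1 <- seq(max(0, k1_range[1L]), min(1, k1_range[2L]), by = step)
  gr <- expand.grid(k0 = k0, k1 = k1)
  gr <- gr[gr$k0 + gr$k1 <= 1 + 1e-12, ]
  cbind(gr$k0, gr$k1, pmax(0, 1 - gr$k0 - gr$k1))
}

#' Maximum-likelihood pairwise relatedness
#'
#' Maximises the pair log-likelihood over the (k0, k1, k2) simplex by grid
#' search plus a local refinement pass at one tenth of the grid step, and
#' reports r = k1/2 + k2, the expected fraction of alleles shared identical
#' by descent. The likelihood assumes outbred individuals.
#'
#' @param g_i,g_j loci x 2 integer genotype matrices.
#' @param freqs an \code{allele_freq_table}.
#' @param grid_step coarse grid spacing on the simplex.
#' @param constrain if TRUE, restrict to pedigree-feasible coefficients
#'   (k1^2 >= 4 k0 k2).
#' @return list of class \code{pair_relatedness}: k0, k1, k2, r, loglik.
#' @export
ml_relatedness <- function(g_i, g_j, freqs, grid_step = 0.01,
                           constrain = FALSE) {
  S <- pair_locus_probs(g_i, g_j, freqs)
  if (ncol(S) == 0L) stop("no shared typed loci for the pair")
  best <- NULL
  score <- function(K) {
    if (constrain) {
      keep <- K[, 2L]^2 >= 4 * K[, 1L] * K[, 3L] - 1e-12
      K <- K[keep, , drop = FALSE]
    }
    ll <- rowSums(log(pmax(K %*% S, 1e-300)))
    i <- which.max(ll)
    list(k = K[i, ], ll = ll[i])
  }
  best <- score(simplex_grid(grid_step))
  fine <- grid_step / 10
  best <- score(simplex_grid(fine,
                             k0_range = best$k[1L] + c(-1, 1) * grid_step,
                             k1_range = best$k[2L] + c(-1, 1) * grid_step))
  k <- best$k / sum(best$k)
  structure(list(k0 = k[1L], k1 = k[2L], k2 = k[3L],
                 r = k[2L] / 2 + k[3L], loglik = best$ll),
            class = "pair_relatedness")
}

#' @export
print.pair_relatedness <- function(x, ...) {
  cat(sprintf("pair_relatedness: r = %.3f (k = %.2f/%.2f/%.2f, loglik %.2f)\n",
              x$r, x$k0, x$k1, x$k2, x$loglik))
  invisible(x)
}

#' Relatedness for a set of individual pairs
#'
#' @param g a \code{genotype_table} containing every referenced individual.
#' @param pairs data.frame with columns id_i, id_j.
#' @param freqs an \code{allele_freq_table}.
#' @param ... passed to \code{\link{ml_relatedness}}.
#' @return data.frame (id_i, id_j, k0, k1, k2, r, loglik); an identical pair
#'   (id_i == id_j) is reported as r = 1 without optimisation.
#' @export
relatedness_pairs <- function(g, pairs, freqs, ...) {
  pairs <- unique(pairs[, c("id_i", "id_j")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_i[i]; b <- pairs$id_j[i]
    if (a == b)
      return(data.frame(id_i = a, id_j = b, k0 = 0, k1 = 0, k2 = 1, r = 1,
                        loglik = NA_real_, stringsAsFactors = FALSE))
    fit <- ml_relatedness(extract_genotype(g, a), extract_genotype(g, b),
                          freqs, ...)
    data.frame(id_i = a, id_j = b, k0 = fit$k0, k1 = fit$k1, k2 = fit$k2,
               r = fit$r, loglik = fit$loglik, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
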