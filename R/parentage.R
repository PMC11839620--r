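# freq table -> per-locus frequency vectors indexed 1..A plus the code maps
freq_index <- function(freqs) {
  codes <- lapply(freqs$freqs, function(f) as.integer(names(f)))
  fvec <- lapply(freqs$freqs, function(f) as.numeric(f))
  list(codes = codes, fvec = fvec, loci = names(freqs$freqs))
}

# encode a loci x 2 genotype matrix as a 1 x 2L index row (0 = missing)
encode_one <- function(gm, fi) {
  L <- length(fi$loci)
  if (is.null(rownames(gm))) rownames(gm) <- fi$loci
  out <- integer(2L * L)
  for (l in seq_len(L)) {
    row <- gm[fi$loci[l], ]
    for (s in 1:2) {
      idx <- match(row[s], fi$codes[[l]])
      out[2L * (l - 1L) + s] <- if (is.na(idx)) 0L else idx
    }
  }
  matrix(out, nrow = 1L)
}

# encode a whole genotype_table against the frequency table's allele codes
encode_table <- function(g, fi) {
  L <- length(fi$loci)
  jmap <- match(fi$loci, g$loci)
  if (anyNA(jmap)) stop("genotype table lacks loci: ",
                        paste(fi$loci[is.na(jmap)], collapse = ", "))
  out <- matrix(0L, length(g$ids), 2L * L)
  for (l in seq_len(L)) {
    for (s in 1:2) {
      idx <- match(g$alleles[, jmap[l], s], fi$codes[[l]])
      idx[is.na(idx)] <- 0L
      out[, 2L * (l - 1L) + s] <- idx
    }
  }
  rownames(out) <- g$ids
  out
}

#' Paternity LOD score for one offspring-mother-candidate trio
#'
#' Log-likelihood ratio that the candidate is the father versus a random
#' male drawn from the allele frequencies, given the known mother. Per typed
#' locus the term is \code{ln[(1-e) T(go|gm,gc) + e P(go)] -
#' ln[(1-e) T(go|gm) + e P(go)]} with T the Mendelian transition probability
#' and P(go) the Hardy-Weinberg genotype probability; e is the mistyping
#' rate. Loci untyped in any of the three individuals are skipped. With
#' e = 0, a Mendelian-incompatible candidate yields -Inf.
#'
#' @param offspring,mother,candidate loci x 2 integer genotype matrices with
#'   locus rownames (as from \code{\link{extract_genotype}}).
#' @param freqs an \code{allele_freq_table}.
#' @param error_rate per-genotype mistyping rate e.
#' @return scalar LOD.
#' @export
lod_score <- function(offspring, mother, candidate, freqs, error_rate = 0) {
  fi <- freq_index(freqs)
  res <- lod_mismatch_matrix(encode_one(offspring, fi), encode_one(mother, fi),
                             encode_one(candidate, fi), fi$fvec, error_rate)
  if (is.na(res$lod[1L, 1L])) stop("no shared typed loci in trio")
  res$lod[1L, 1L]
}

#' Mendelian mismatch count for a trio
#'
#' Number of loci at which no assignment of one maternal and one paternal
#' allele can explain the offspring genotype.
#'
#' @inheritParams lod_score
#' @return integer mismatch count over the shared typed loci.
#' @export
mismatch_count <- function(offspring, mother, candidate, freqs = NULL) {
  if (is.null(freqs)) {
    # synthesise a frequency table covering the observed alleles; the counts
    # do not affect the mismatch logic
    loci <- rownames(offspring)
    codes <- lapply(seq_along(loci), function(l)
      sort(unique(stats::na.omit(c(offspring[l, ], mother[l, ], candidate[l, ])))))
    fr <- lapply(codes, function(cc) stats::setNames(rep(1 / length(cc), length(cc)), cc))
    names(fr) <- loci
    freqs <- structure(list(freqs = fr,
                            n_typed = stats::setNames(rep(3L, length(loci)), loci)),
                       class = "allele_freq_table")
  }
  fi <- freq_index(freqs)
  res <- lod_mismatch_matrix(encode_one(offspring, fi), encode_one(mother, fi),
                             encode_one(candidate, fi), fi$fvec, 0)
  if (is.na(res$mismatch[1L, 1L])) stop("no shared typed loci in trio")
  res$mismatch[1L, 1L]
}

# draw n Hardy-Weinberg genotypes (index-coded, n x 2L) from frequency vectors
sample_hw_indexed <- function(n, fvec) {
  L <- length(fvec)
  out <- matrix(0L, n, 2L * L)
  for (l in seq_len(L)) {
    A <- length(fvec[[l]])
    out[, 2L * l - 1L] <- sample.int(A, n, replace = TRUE, prob = fvec[[l]])
    out[, 2L * l] <- sample.int(A, n, replace = TRUE, prob = fvec[[l]])
  }
  out
}

#' Calibrate the critical delta for 95% paternity confidence
#'
#' Simulates offspring of known fathers drawn from a candidate pool, scores
#' every candidate by LOD, and finds the smallest threshold on
#' delta = LOD1 - LOD2 at which at least 95% of the assignments exceeding it
#' name the true father. Mirrors the simulation approach of likelihood-based
#' parentage software: the threshold absorbs marker informativeness,
#' candidate number, the sampled fraction of fathers, missing data and the
#' mistyping rate.
#'
#' @param freqs an \code{allele_freq_table} describing the marker panel.
#' @param n_sim number of simulated offspring (>= 1000).
#' @param n_candidates size of the candidate pool.
#' @param sampled_fraction probability the true father is in the pool.
#' @param typed_fraction per-locus probability that a simulated individual
#'   is typed at a locus.
#' @param error_rate per-allele mistyping rate used both to corrupt the
#'   simulated genotypes and in the LOD model.
#' @param seed optional RNG seed.
#' @param confidence target confidence level.
#' @return a \code{delta_calibration}: list with \code{delta_crit},
#'   \code{confidence}, the simulation parameters, and the achieved
#'   assignment rate at the threshold.
#' @export
calibrate_delta <- function(freqs, n_sim = 10000L, n_candidates = 182L,
                            sampled_fraction = 1.0, typed_fraction = 1.0,
                            error_rate = 0.001, seed = NULL,
                            confidence = 0.95) {
  if (n_sim < 1000L) stop("n_sim must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  fi <- freq_index(freqs)
  L <- length(fi$fvec)

  cand <- sample_hw_indexed(n_candidates, fi$fvec)
  mom <- sample_hw_indexed(n_sim, fi$fvec)
  true_f <- sample.int(n_candidates, n_sim, replace = TRUE)
  sampled <- stats::runif(n_sim) < sampled_fraction
  unsampled_f <- sample_hw_indexed(n_sim, fi$fvec)

  off <- matrix(0L, n_sim, 2L * L)
  for (l in seq_len(L)) {
    pickm <- sample(c(0L, 1L), n_sim, replace = TRUE)
    off[, 2L * l - 1L] <- mom[cbind(seq_len(n_sim), 2L * l - 1L + pickm)]
    pickf <- sample(c(0L, 1L), n_sim, replace = TRUE)
    fa <- ifelse(sampled,
                 cand[cbind(true_f, 2L * l - 1L + pickf)],
                 unsampled_f[cbind(seq_len(n_sim), 2L * l - 1L + pickf)])
    off[, 2L * l] <- fa
    if (error_rate > 0) {
      A <- length(fi$fvec[[l]])
      for (col in c(2L * l - 1L, 2L * l)) {
        err <- stats::runif(n_sim) < error_rate
        if (any(err)) off[err, col] <- sample.int(A, sum(err), replace = TRUE,
                                                  prob = fi$fvec[[l]])
      }
    }
    if (typed_fraction < 1) {
      untyped <- stats::runif(n_sim) >= typed_fraction
      off[untyped, c(2L * l - 1L, 2L * l)] <- 0L
    }
  }

  sc <- lod_mismatch_matrix(off, mom, cand, fi$fvec, error_rate)
  lod <- sc$lod
  top1 <- max.col(lod, ties.method = "first")
  lod1 <- lod[cbind(seq_len(n_sim), top1)]
  lod2 <- apply(lod, 1L, function(x) -sort(-x, partial = 2L)[2L])
  delta <- lod1 - lod2
  delta[is.nan(delta)] <- 0   # both top LODs -Inf (only possible at e = 0)
  correct <- sampled & (top1 == true_f)

  ord <- order(delta, decreasing = TRUE)
  frac <- cumsum(correct[ord]) / seq_len(n_sim)
  ok <- which(frac >= confidence)
  if (length(ok) == 0L) {
    warning("requested confidence unattainable with these markers; delta_crit = Inf")
    dcrit <- Inf
    achieved <- 0
  } else {
    m <- max(ok)
    dcrit <- if (m == n_sim) 0 else max(0, delta[ord][m])
    achieved <- frac[m]
  }
  structure(list(delta_crit = dcrit, confidence = confidence,
                 achieved = achieved, n_sim = n_sim,
                 n_candidates = n_candidates,
                 sampled_fraction = sampled_fraction,
                 typed_fraction = typed_fraction, error_rate = error_rate),
            class = "delta_calibration")
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat(sprintf("delta_calibration: delta_crit = %.3f at %.0f%% confidence (%d sims, %d candidates)\n",
              x$delta_crit, 100 * x$confidence, x$n_sim, x$n_candidates))
  invisible(x)
}

#' Categorical paternity assignment with exclusion override
#'
#' For every seedling, scores all plot adults (the mother included, so
#' selfing is detected as the mother out-competing all other males) by
#' paternity LOD, then applies, in order: (1) best candidate is the mother
#' and the delta passes the calibrated threshold -> selfing; (2) best
#' candidate has Mendelian mismatches above \code{max_mismatch} -> the
#' father is outside the plot (immigrant); (3) delta below threshold, or an
#' exact tie between the top two candidates -> ambiguous_multiple; (4)
#' otherwise -> single_donor.
#'
#' @param seedlings \code{genotype_table} of offspring.
#' @param mothers named character vector mapping seedling id to mother id
#'   (or a data.frame with columns seedling_id, mother_id).
#' @param adults \code{genotype_table} of candidate fathers (must contain
#'   every mother).
#' @param freqs an \code{allele_freq_table}.
#' @param calib a \code{delta_calibration}.
#' @param max_mismatch mismatch tolerance; "more than \code{max_mismatch}
#'   loci" triggers the immigrant call.
#' @param error_rate mistyping rate for the LOD model.
#' @return data.frame with one row per seedling: offspring_id, mother_id,
#'   best_father_id, lod1, lod2, delta, mismatches, category.
#' @export
assign_paternity <- function(seedlings, mothers, adults, freqs, calib,
                             max_mismatch = 2L, error_rate = 0.001) {
  if (is.data.frame(mothers))
    mothers <- stats::setNames(mothers$mother_id, mothers$seedling_id)
  mom_of <- mothers[seedlings$ids]
  if (anyNA(mom_of)) stop("seedlings with unknown mother: ",
                          paste(seedlings$ids[is.na(mom_of)], collapse = ", "))
  if (!all(mom_of %in% adults$ids))
    stop("mothers missing from the candidate list: ",
         paste(setdiff(mom_of, adults$ids), collapse = ", "))
  fi <- freq_index(freqs)
  off <- encode_table(seedlings, fi)
  cand <- encode_table(adults, fi)
  momg <- cand[match(mom_of, adults$ids), , drop = FALSE]

  sc <- lod_mismatch_matrix(off, momg, cand, fi$fvec, error_rate)
  n <- nrow(off)
  top1 <- max.col(sc$lod, ties.method = "first")
  lod1 <- sc$lod[cbind(seq_len(n), top1)]
  lod2 <- apply(sc$lod, 1L, function(x) -sort(-x, partial = 2L)[2L])
  delta <- lod1 - lod2
  delta[is.nan(delta)] <- 0   # two -Inf top LODs: an exact tie
  mm <- sc$mismatch[cbind(seq_len(n), top1)]
  best_id <- adults$ids[top1]

  tie <- delta <= 0
  category <- character(n)
  father <- best_id
  for (i in seq_len(n)) {
    if (best_id[i] == mom_of[i] && !tie[i] && delta[i] >= calib$delta_crit) {
      category[i] <- "selfing"
    } else if (mm[i] > max_mismatch) {
      category[i] <- "immigrant"; father[i] <- NA_character_
    } else if (tie[i] || delta[i] < calib$delta_crit) {
      category[i] <- "ambiguous_multiple"; father[i] <- NA_character_
    } else {
      category[i] <- "single_donor"
    }
  }
  data.frame(offspring_id = seedlings$ids, mother_id = unname(mom_of),
             best_father_id = father, lod1 = lod1, lod2 = lod2,
             delta = delta, mismatches = as.integer(mm),
             category = category, stringsAsFactors = FALSE)
}

#' Tabulate parentage categories per mother
#'
#' The bookkeeping table of a paternity run: per mother, counts of selfed,
#' immigrant-sired, ambiguous and single-donor seedlings, summing to the
#' number of seedlings analysed.
#'
#' @param records data.frame from \code{\link{assign_paternity}}.
#' @return data.frame with one row per mother plus a Total row.
#' @export
parentage_summary <- function(records) {
  lev <- c("selfing", "immigrant", "ambiguous_multiple", "single_donor")
  tab <- table(records$mother_id, factor(records$category, levels = lev))
  out <- data.frame(mother_id = rownames(tab), as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE)
  out$n_seedlings <- rowSums(tab)
  tot <- c(mother_id = "Total", as.list(colSums(tab)),
           n_seedlings = sum(tab))
  out <- rbind(out, as.data.frame(tot, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
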