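# Shared fixture builders: everything is generated in code at test time.

# uniform-frequency marker panel: n_loci loci, n_alleles alleles each
make_freqs <- function(n_loci = 10L, n_alleles = 8L, probs = NULL) {
  codes <- 100L + 2L * seq_len(n_alleles)
  loci <- sprintf("loc%02d", seq_len(n_loci))
  fr <- lapply(loci, function(l) {
    p <- if (is.null(probs)) rep(1 / n_alleles, n_alleles) else probs
    stats::setNames(p / sum(p), codes)
  })
  names(fr) <- loci
  structure(list(freqs = fr,
                 n_typed = stats::setNames(rep(100L, n_loci), loci)),
            class = "allele_freq_table")
}

# one Hardy-Weinberg genotype (loci x 2 matrix) drawn from a frequency table
draw_hw_matrix <- function(freqs) {
  m <- t(vapply(freqs$freqs, function(f)
    sample(as.integer(names(f)), 2L, replace = TRUE, prob = f), c(0L, 0L)))
  rownames(m) <- names(freqs$freqs)
  m
}

# Mendelian offspring of two loci x 2 genotype matrices
mendel_offspring <- function(gm, gf) {
  L <- nrow(gm)
  off <- cbind(gm[cbind(seq_len(L), sample(c(1L, 2L), L, replace = TRUE))],
               gf[cbind(seq_len(L), sample(c(1L, 2L), L, replace = TRUE))])
  rownames(off) <- rownames(gm)
  off
}

# a small random genotype table for IO round-trips
random_genotype_table <- function(n = 8L, n_loci = 4L, n_alleles = 5L,
                                  missing_rate = 0.1) {
  codes <- 100L + 2L * seq_len(n_alleles)
  alleles <- array(sample(codes, n * n_loci * 2L, replace = TRUE),
                   dim = c(n, n_loci, 2L))
  miss <- matrix(stats::runif(n * n_loci) < missing_rate, n, n_loci)
  for (s in 1:2) alleles[, , s][miss] <- NA_integer_
  genotype_table(sprintf("ind%02d", seq_len(n)),
                 rep(c("popA", "popB"), length.out = n),
                 sprintf("loc%02d", seq_len(n_loci)), alleles)
}

# genotype matrix from explicit allele pairs, loci named loc01..
gmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("loc%02d", seq_len(nrow(m)))
  m
}
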