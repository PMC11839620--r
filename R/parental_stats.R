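#' Rogers-distance between two ancestry vectors (qdis)
#'
#' The attributional difference of cluster membership between two parents:
#' Rogers' genetic distance applied to their ancestry (Q) vectors,
#' \code{sqrt(sum((Q_i - Q_j)^2) / 2)}. It is 0 for identical ancestry, 1
#' for pure membership in two different clusters, and a metric on the
#' ancestry simplex.
#'
#' @param q_i,q_j numeric ancestry vectors of equal length, each summing
#'   to 1 (tolerance 1e-6).
#' @param squared if TRUE, return the no-square-root reading
#'   \code{sum((Q_i - Q_j)^2)/2} instead (sensitivity switch).
#' @return a scalar in [0, 1].
#' @export
qdis <- function(q_i, q_j, squared = FALSE) {
  if (length(q_i) != length(q_j)) stop("ancestry vectors differ in length")
  if (abs(sum(q_i) - 1) > 1e-6 || abs(sum(q_j) - 1) > 1e-6)
    stop("ancestry vectors must sum to 1")
  d2 <- sum((q_i - q_j)^2) / 2
  if (squared) d2 else sqrt(d2)
}

#' Fst-weighted joint cluster membership of a parent pair (fdis)
#'
#' \code{sum_k (Q_ik + Q_jk) * fst_k / 2}: the mean of the two parents'
#' ancestry vectors weighted by a signed per-cluster differentiation vector.
#' With two opposed differentiated clusters (fst_1 = +c, fst_3 = -c) and a
#' near-zero middle cluster, fdis is large only when both parents sit in the
#' same differentiated pole; membership in opposing poles offsets to ~0 and
#' the undifferentiated cluster is masked.
#'
#' @param q_i,q_j numeric ancestry vectors of equal length.
#' @param fst signed per-cluster differentiation vector, same length.
#' @return a scalar (may be negative).
#' @export
fdis <- function(q_i, q_j, fst) {
  if (length(q_i) != length(q_j) || length(q_i) != length(fst))
    stop("Q vectors and fst must share one length")
  sum((q_i + q_j) * fst) / 2
}

#' Map estimated drift parameters to a signed differentiation vector
#'
#' The drift parameters of the correlated-frequency admixture model are
#' strictly positive; the fdis statistic instead needs a signed vector with
#' two opposing differentiated poles. This helper negates the cluster chosen
#' as the opposing pole and leaves the rest unchanged.
#'
#' @param F_hat positive per-cluster drift estimates.
#' @param opposing index of the cluster to negate.
#' @return signed numeric vector of the same length.
#' @export
signed_fst <- function(F_hat, opposing) {
  if (opposing < 1 || opposing > length(F_hat)) stop("opposing index out of range")
  out <- F_hat
  out[opposing] <- -out[opposing]
  out
}

#' Assemble the per-seedling covariate table for the fitness models
#'
#' Keeps only seedlings assigned a single in-plot paternal donor, then joins
#' seed weight from the phenotype table, maximum-likelihood relatedness of
#' the parent pair, and qdis/fdis computed from the parents' ancestry
#' vectors. Counts of excluded seedlings per category are reported via
#' \code{message} and attached as the \code{"excluded"} attribute.
#'
#' @param records parentage data.frame from \code{\link{assign_paternity}}.
#' @param Q ancestry matrix with adult ids as rownames.
#' @param fst signed per-cluster differentiation vector.
#' @param relatedness data.frame (id_i, id_j, r) covering every retained
#'   mother-father pair, as from \code{\link{relatedness_pairs}}.
#' @param phenotypes data.frame with seedling_id and w (seed weight, g).
#' @return data.frame (seedling_id, mother_id, father_id, w, r, qdis, fdis).
#' @export
assemble_covariates <- function(records, Q, fst, relatedness, phenotypes) {
  excl <- table(factor(records$category,
                       levels = c("selfing", "immigrant", "ambiguous_multiple",
                                  "single_donor")))
  keep <- records[records$category == "single_donor", , drop = FALSE]
  message(sprintf("retained %d single-donor seedlings; excluded %d selfing, %d immigrant, %d ambiguous",
                  nrow(keep), excl[["selfing"]], excl[["immigrant"]],
                  excl[["ambiguous_multiple"]]))
  missQ <- setdiff(unique(c(keep$mother_id, keep$best_father_id)), rownames(Q))
  if (length(missQ) > 0L)
    stop("no ancestry vector for: ", paste(missQ, collapse = ", "))

  rkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  rmap <- stats::setNames(relatedness$r, rkey(relatedness$id_i, relatedness$id_j))
  r <- rmap[rkey(keep$mother_id, keep$best_father_id)]
  if (anyNA(r)) stop("relatedness missing for some parent pairs")

  wmap <- stats::setNames(phenotypes$w, phenotypes$seedling_id)
  w <- wmap[keep$offspring_id]
  drop_w <- is.na(w)
  if (any(drop_w)) {
    warning(sum(drop_w), " seedlings dropped for missing seed weight")
    keep <- keep[!drop_w, , drop = FALSE]; r <- r[!drop_w]; w <- w[!drop_w]
  }
  qd <- vapply(seq_len(nrow(keep)), function(i)
    qdis(Q[keep$mother_id[i], ], Q[keep$best_father_id[i], ]), 0)
  fd <- vapply(seq_len(nrow(keep)), function(i)
    fdis(Q[keep$mother_id[i], ], Q[keep$best_father_id[i], ], fst), 0)
  out <- data.frame(seedling_id = keep$offspring_id,
                    mother_id = keep$mother_id,
                    father_id = keep$best_father_id,
                    w = as.numeric(w), r = as.numeric(r),
                    qdis = qd, fdis = fd, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- as.list(excl[c("selfing", "immigrant",
                                          "ambiguous_multiple")])
  out
}
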