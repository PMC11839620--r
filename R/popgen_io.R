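#' Construct a diploid genotype table
#'
#' The central container for codominant multi-locus genotypes. Alleles are
#' opaque positive integer codes (typically fragment sizes); no size binning
#' or mutation model is ever applied to them. A locus is either fully typed
#' (both allele slots present) or fully missing for an individual: a
#' half-missing locus is coerced to fully missing with a warning, because the
#' parentage and relatedness likelihoods assume per-locus both-or-neither.
#'
#' @param ids character vector of unique individual identifiers.
#' @param groups character vector of group labels (population or plot),
#'   recycled if length 1.
#' @param loci character vector of locus names.
#' @param alleles integer array of dimension \code{n x n_loci x 2} holding
#'   allele codes, \code{NA} for missing.
#' @return An object of class \code{genotype_table}: a list with elements
#'   \code{ids}, \code{groups}, \code{loci} and \code{alleles}.
#' @export
genotype_table <- function(ids, groups, loci, alleles) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(groups) == 1L) groups <- rep(groups, length(ids))
  groups <- as.character(groups)
  if (length(groups) != length(ids)) stop("groups must match ids in length")
  loci <- as.character(loci)
  alleles <- array(as.integer(alleles),
                   dim = c(length(ids), length(loci), 2L),
                   dimnames = list(ids, loci, NULL))
  if (any(alleles <= 0L, na.rm = TRUE)) stop("allele codes must be positive integers")
  # both-or-neither: one recorded allele at a locus cannot be used downstream
  half <- xor(is.na(alleles[, , 1L, drop = FALSE]), is.na(alleles[, , 2L, drop = FALSE]))
  if (any(half)) {
    warning(sum(half), " half-missing locus entries coerced to fully missing")
    half2 <- array(FALSE, dim = dim(alleles))
    half2[, , 1L] <- half
    half2[, , 2L] <- half
    alleles[half2] <- NA_integer_
  }
  structure(list(ids = ids, groups = groups, loci = loci, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals,", length(x$loci),
      "loci,", length(unique(x$groups)), "group(s)\n")
  miss <- mean(is.na(x$alleles[, , 1L]))
  cat(sprintf("missing data: %.1f%% of individual x locus entries\n", 100 * miss))
  invisible(x)
}

#' Number of individuals in a genotype table
#' @param g a \code{genotype_table}.
#' @return integer count.
#' @export
n_individuals <- function(g) length(g$ids)

#' Subset a genotype table by individual id
#' @param g a \code{genotype_table}.
#' @param ids character vector of ids to keep, in the requested order.
#' @return a \code{genotype_table} with the selected rows.
#' @export
subset_individuals <- function(g, ids) {
  idx <- match(ids, g$ids)
  if (anyNA(idx)) stop("unknown ids: ", paste(ids[is.na(idx)], collapse = ", "))
  genotype_table(g$ids[idx], g$groups[idx], g$loci,
                 g$alleles[idx, , , drop = FALSE])
}

#' Extract one individual's genotype as a loci x 2 matrix
#' @param g a \code{genotype_table}.
#' @param id individual identifier.
#' @return integer matrix with one row per locus and two allele columns;
#'   rownames are locus names, \code{NA} marks missing loci.
#' @export
extract_genotype <- function(g, id) {
  i <- match(id, g$ids)
  if (is.na(i)) stop("unknown id: ", id)
  m <- matrix(g$alleles[i, , ], ncol = 2L, dimnames = list(g$loci, NULL))
  m
}

#' Read a GenePop genotype file
#'
#' Supports the classic 2- and 3-digit diploid allele coding; \code{"0"},
#' \code{"00"} or \code{"000"} in an allele slot marks a missing allele.
#' Group labels are \code{pop1}, \code{pop2}, ... in POP-block order.
#'
#' @param path path to a GenePop file.
#' @return a \code{genotype_table}.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("malformed GenePop file: fewer than 3 non-blank lines")
  # line 1 is a free title; locus names follow, one per line or comma-separated
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("malformed GenePop file: no POP line found")
  if (pop_idx[1L] < 3L)
    stop("malformed GenePop header: no locus names before first POP")
  locus_lines <- lines[2:(pop_idx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("malformed GenePop header: no locus names before first POP")

  ids <- character(); groups <- character()
  rows <- list()
  pop <- 0L
  for (li in seq(pop_idx[1L], length(lines))) {
    line <- lines[li]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop <- pop + 1L
      next
    }
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) != 2L)
      stop("GenePop parse error at line ", li, ": expected 'id , genotypes'")
    id <- trimws(parts[1L])
    fields <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    if (length(fields) != length(loci))
      stop("GenePop parse error at line ", li, ": ", length(fields),
           " genotype fields for ", length(loci), " loci")
    nc <- unique(nchar(fields))
    if (length(nc) != 1L || !(nc %in% c(4L, 6L)))
      stop("GenePop parse error at line ", li,
           ": genotype fields must be uniformly 4 (2-digit) or 6 (3-digit) characters")
    d <- nc / 2L
    a1 <- as.integer(substr(fields, 1L, d))
    a2 <- as.integer(substr(fields, d + 1L, nc))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id)
    groups <- c(groups, paste0("pop", pop))
    rows[[length(rows) + 1L]] <- cbind(a1, a2)
  }
  n <- length(ids)
  alleles <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (i in seq_len(n)) alleles[i, , ] <- rows[[i]]
  genotype_table(ids, groups, loci, alleles)
}

#' Write a genotype table in GenePop format
#'
#' @param g a \code{genotype_table}.
#' @param path output path.
#' @param digits 2 or 3, the per-allele field width. Allele codes must fit.
#' @return invisibly, \code{path}.
#' @export
write_genepop <- function(g, path, digits = 3L) {
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  if (any(g$alleles >= 10^digits, na.rm = TRUE))
    stop("allele codes do not fit in ", digits, " digits")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("genotype table export", con)
  writeLines(g$loci, con)
  fmt <- paste0("%0", digits, "d")
  for (grp in unique(g$groups)) {
    writeLines("POP", con)
    for (i in which(g$groups == grp)) {
      a <- g$alleles[i, , , drop = TRUE]
      a <- matrix(a, ncol = 2L)
      a[is.na(a)] <- 0L
      fields <- paste0(sprintf(fmt, a[, 1L]), sprintf(fmt, a[, 2L]))
      writeLines(paste0(g$ids[i], " , ", paste(fields, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a wide-format genotype CSV
#'
#' Expects columns \code{id}, \code{group}, then two columns per locus named
#' \code{<locus>_1} and \code{<locus>_2}. Empty cells, \code{NA} and
#' \code{-9} mark missing alleles.
#'
#' @param path path to the CSV file.
#' @return a \code{genotype_table}.
#' @export
read_wide_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "group") %in% names(df)))
    stop("wide genotype CSV must have 'id' and 'group' columns")
  acols <- setdiff(names(df), c("id", "group"))
  if (length(acols) %% 2L != 0L)
    stop("schema error: odd number of allele columns (", length(acols), ")")
  base <- sub("_[12]$", "", acols)
  loci <- unique(base)
  for (loc in loci) {
    if (!all(paste0(loc, c("_1", "_2")) %in% acols))
      stop("schema error: locus ", loc, " lacks paired _1/_2 columns")
  }
  n <- nrow(df)
  alleles <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (j in seq_along(loci)) {
    for (s in 1:2) {
      v <- df[[paste0(loci[j], "_", s)]]
      v <- suppressWarnings(as.integer(v))
      v[!is.na(v) & v <= 0L] <- NA_integer_   # -9 and 0 conventions
      alleles[, j, s] <- v
    }
  }
  genotype_table(df$id, df$group, loci, alleles)
}

#' Write a genotype table as a wide CSV
#' @param g a \code{genotype_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_wide_csv <- function(g, path) {
  out <- data.frame(id = g$ids, group = g$groups, stringsAsFactors = FALSE)
  for (j in seq_along(g$loci)) {
    out[[paste0(g$loci[j], "_1")]] <- g$alleles[, j, 1L]
    out[[paste0(g$loci[j], "_2")]] <- g$alleles[, j, 2L]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate per-locus allele frequencies
#'
#' Counts alleles over typed individuals and adds a pseudo-count to every
#' observed allele before renormalising. The default pseudo-count of 0.5
#' keeps every observed allele at positive frequency, so no paternity LOD or
#' relatedness likelihood can hit an exact zero for an allele seen only in
#' offspring.
#'
#' @param g a \code{genotype_table} (or several, supplied as a list, pooled).
#' @param smoothing pseudo-count added per observed allele per locus.
#' @return an \code{allele_freq_table}: a list with \code{freqs} (per locus,
#'   a named numeric vector of frequencies keyed by allele code) and
#'   \code{n_typed} (typed individuals per locus).
#' @export
allele_frequencies <- function(g, smoothing = 0.5) {
  gl <- if (inherits(g, "genotype_table")) list(g) else g
  loci <- gl[[1L]]$loci
  for (gg in gl) if (!identical(gg$loci, loci)) stop("loci differ between pooled tables")
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  n_typed <- integer(length(loci))
  for (j in seq_along(loci)) {
    obs <- unlist(lapply(gl, function(gg) as.vector(gg$alleles[, j, ])))
    typed <- sum(vapply(gl, function(gg) sum(!is.na(gg$alleles[, j, 1L])), 0L))
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L)
      stop("locus with zero typed individuals: ", loci[j])
    tab <- table(obs)
    cnt <- as.numeric(tab) + smoothing
    f <- cnt / sum(cnt)
    names(f) <- names(tab)
    freqs[[j]] <- f
    n_typed[j] <- typed
  }
  structure(list(freqs = freqs, n_typed = stats::setNames(n_typed, loci)),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x$freqs), "loci;",
      "alleles per locus:", paste(vapply(x$freqs, length, 0L), collapse = " "), "\n")
  invisible(x)
}

#' Write allele frequencies as a long CSV (locus, allele, freq, n_typed)
#' @param af an \code{allele_freq_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_allele_frequencies <- function(af, path) {
  rows <- do.call(rbind, lapply(names(af$freqs), function(loc) {
    f <- af$freqs[[loc]]
    data.frame(locus = loc, allele = as.integer(names(f)), freq = as.numeric(f),
               n_typed = af$n_typed[[loc]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise missing data per locus
#'
#' A lightweight data-quality report: per locus, the number and fraction of
#' individuals with the locus untyped.
#'
#' @param g a \code{genotype_table}.
#' @return data.frame with columns locus, n_missing, frac_missing.
#' @export
missing_data_report <- function(g) {
  nm <- colSums(is.na(g$alleles[, , 1L, drop = FALSE]))
  data.frame(locus = g$loci, n_missing = as.integer(nm),
             frac_missing = as.numeric(nm) / length(g$ids),
             stringsAsFactors = FALSE)
}
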