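#' Relative growth rate per seedling per period
#'
#' RGR between consecutive height censuses: \code{ln(H_t / H_{t-1}) /
#' (T_t - T_{t-1})}, in day^-1. Periods are indexed by the position of the
#' later census among the sorted unique census dates, so the labels agree
#' across seedlings; a seedling missing a height (dead or unmeasured)
#' contributes no record for that period.
#'
#' @param heights long data.frame with columns seedling_id, date (days,
#'   numeric) and height_cm.
#' @return data.frame (seedling_id, period, H_prev, H_curr, T_prev, T_curr,
#'   RGR).
#' @export
compute_rgr <- function(heights) {
  if (any(heights$height_cm <= 0)) stop("non-positive height")
  dates <- sort(unique(heights$date))
  heights <- heights[order(heights$seedling_id, heights$date), ]
  out <- lapply(split(heights, heights$seedling_id), function(h) {
    if (nrow(h) < 2L) return(NULL)
    dt <- diff(h$date)
    if (any(dt == 0)) stop("zero-length census interval for ", h$seedling_id[1L])
    data.frame(seedling_id = h$seedling_id[-1L],
               period = match(h$date[-1L], dates) - 1L,
               H_prev = h$height_cm[-nrow(h)], H_curr = h$height_cm[-1L],
               T_prev = h$date[-nrow(h)], T_curr = h$date[-1L],
               RGR = log(h$height_cm[-1L] / h$height_cm[-nrow(h)]) / dt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half, then \code{sqrt(((n-1)/n W + B/n) / W)} with
#' W the mean within-half variance and B the between-half variance of the
#' half means.
#'
#' @param chains a list of equal-length numeric vectors (>= 2 chains of
#'   >= 10 draws) or an iterations x chains matrix.
#' @return scalar Rhat; 1.0 with a warning when every chain is constant.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2L) stop("need at least 2 chains")
  len <- unique(vapply(chains, length, 0L))
  if (length(len) != 1L || len < 10L) stop("chains must share one length >= 10")
  half <- floor(len / 2)
  splits <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(len - half + 1L):len])), recursive = FALSE)
  m <- length(splits); n <- half
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    if (B > 0) return(Inf)   # frozen chains at different values never mix
    warning("zero within-chain variance; Rhat reported as 1")
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian normal mixed model for relative growth rate
#'
#' Fits, for one growth period, RGR = b0 + b_stat stat + b_r r + b_w w +
#' u_group + eps with eps ~ N(0, sigma^2) and u ~ N(0, tau^2), by Gibbs
#' sampling with conjugate updates (coefficients N(0, 10^2) a priori;
#' sigma^2 and tau^2 Inverse-Gamma(1e-8, 1e-8), effectively flat on the
#' tiny day^-1 scale of RGR variances). qdis and fdis enter one
#' at a time. The random intercept groups seedlings by mother tree (family)
#' by default; \code{group = "seedling_id"} reproduces a per-individual
#' effect under the proper prior instead.
#'
#' @param records RGR records for one period, from \code{\link{compute_rgr}}.
#' @param covariates per-seedling covariate table (w, r, qdis, fdis,
#'   mother_id).
#' @param statistic "qdis" or "fdis".
#' @param chains number of MCMC chains (>= 2).
#' @param iters post-burn-in draws per chain.
#' @param burnin discarded draws per chain.
#' @param seed optional RNG seed.
#' @param group grouping column for the random intercept.
#' @return a \code{growth_fit}: list with \code{summary} (data.frame: mean,
#'   sd, 2.5%, 97.5%, Rhat per parameter: intercept, statistic, r, w,
#'   sigma, tau), \code{draws} (iters x chains x params array), \code{n},
#'   \code{n_groups}. Rhat above 1.1 on any parameter triggers a warning.
#' @export
fit_growth_model <- function(records, covariates, statistic = c("qdis", "fdis"),
                             chains = 3L, iters = 4000L, burnin = 1000L,
                             seed = NULL, group = "mother_id") {
  statistic <- match.arg(statistic)
  if (chains < 2L) stop("need at least 2 chains")
  if (burnin < 0L || iters < 10L) stop("iters must exceed burnin meaningfully")
  if (!is.null(seed)) set.seed(seed)
  df <- merge(records, covariates, by = "seedling_id")
  if (nrow(df) == 0L) stop("no records joined to covariates")
  y <- df$RGR
  X <- cbind(intercept = 1, stat = df[[statistic]], r = df$r, w = df$w)
  gidx <- as.integer(factor(df[[group]]))
  G <- max(gidx)
  single_group <- G < 2L
  if (single_group) warning("a single grouping level: tau fixed at 0")
  n <- length(y); p <- ncol(X)
  a0 <- 1e-8; b0 <- 1e-8; prior_prec <- diag(1 / 100, p)
  XtX <- crossprod(X)

  params <- c("intercept", statistic, "r", "w", "sigma", "tau")
  draws <- array(NA_real_, dim = c(iters, chains, length(params)),
                 dimnames = list(NULL, NULL, params))
  ng <- tabulate(gidx, G)
  Xg <- rowsum(X, gidx)                       # group-wise column sums of X
  yg <- rowsum(y, gidx)
  for (ch in seq_len(chains)) {
    beta <- rep(0, p); u <- rep(0, G); sigma2 <- stats::var(y) + 1e-12; tau2 <- 1e-4
    for (it in seq_len(burnin + iters)) {
      # beta | sigma2, tau2 with u integrated out: the marginal covariance is
      # block-compound-symmetric, so X' V^-1 X has a rank-G Woodbury correction
      if (single_group) {
        Vb <- chol2inv(chol(XtX / sigma2 + prior_prec))
        m <- Vb %*% (crossprod(X, y) / sigma2)
      } else {
        cg <- tau2 / (sigma2 + ng * tau2)
        XtVX <- (XtX - crossprod(Xg * sqrt(cg))) / sigma2
        XtVy <- (crossprod(X, y) - crossprod(Xg * cg, yg)) / sigma2
        Vb <- chol2inv(chol(XtVX + prior_prec))
        m <- Vb %*% XtVy
      }
      beta <- as.numeric(m + t(chol(Vb)) %*% stats::rnorm(p))
      fitted_fx <- as.numeric(X %*% beta)
      # u | beta, sigma2, tau2
      if (!single_group) {
        sg <- rowsum(y - fitted_fx, gidx)
        vg <- 1 / (ng / sigma2 + 1 / tau2)
        u <- stats::rnorm(G, vg * sg / sigma2, sqrt(vg))
        tau2 <- 1 / stats::rgamma(1, a0 + G / 2, b0 + sum(u^2) / 2)
      }
      # sigma2 | beta, u
      ssr <- sum((y - fitted_fx - u[gidx])^2)
      sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + ssr / 2)
      if (it > burnin)
        draws[it - burnin, ch, ] <- c(beta, sqrt(sigma2),
                                      if (single_group) 0 else sqrt(tau2))
    }
  }

  summ <- do.call(rbind, lapply(params, function(pn) {
    d <- draws[, , pn]
    rh <- if (stats::sd(d) == 0) 1 else rhat(d)
    data.frame(parameter = pn, mean = mean(d), sd = stats::sd(d),
               q2.5 = as.numeric(stats::quantile(d, 0.025)),
               q97.5 = as.numeric(stats::quantile(d, 0.975)),
               Rhat = rh, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (any(summ$Rhat > 1.1))
    warning("possible non-convergence: Rhat > 1.1 for ",
            paste(summ$parameter[summ$Rhat > 1.1], collapse = ", "))
  structure(list(summary = summ, draws = draws, n = n, n_groups = G,
                 statistic = statistic),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("growth_fit:", x$statistic, "model, n =", x$n, "(", x$n_groups,
      "groups )\n")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4),
                  q2.5 = signif(q2.5, 4), q97.5 = signif(q97.5, 4),
                  Rhat = round(Rhat, 3)))
  invisible(x)
}

#' Fit the growth model for every period
#'
#' @param rgr full RGR table from \code{\link{compute_rgr}}.
#' @param covariates per-seedling covariate table.
#' @param statistic "qdis" or "fdis".
#' @param ... passed to \code{\link{fit_growth_model}}.
#' @return data.frame stacking each period's posterior summary with a
#'   leading \code{period} column.
#' @export
fit_growth_by_period <- function(rgr, covariates, statistic = "qdis", ...) {
  out <- lapply(sort(unique(rgr$period)), function(p) {
    fit <- fit_growth_model(rgr[rgr$period == p, , drop = FALSE],
                            covariates, statistic, ...)
    cbind(period = p, fit$summary)
  })
  do.call(rbind, out)
}
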