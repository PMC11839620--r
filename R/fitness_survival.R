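#' Code census statuses into survival records
#'
#' Statuses are 0 (alive) / 1 (dead) per census, in time order. The event
#' time is the first census at which the seedling is recorded dead; later
#' statuses are ignored once dead. A seedling alive at the last census is
#' censored there. A dead-then-alive sequence is an error.
#'
#' @param statuses data.frame with a \code{seedling_id} column followed by
#'   one 0/1 status column per census, in census order.
#' @return data.frame (seedling_id, time, event) with time the census index
#'   and event 1 = died, 0 = censored.
#' @export
code_survival <- function(statuses) {
  scols <- setdiff(names(statuses), "seedling_id")
  m <- as.matrix(statuses[, scols, drop = FALSE])
  if (!all(m %in% c(0L, 1L))) stop("statuses must be 0 (alive) or 1 (dead)")
  resurrect <- apply(m, 1L, function(x) any(diff(x) < 0))
  if (any(resurrect))
    stop("dead-then-alive status sequence for: ",
         paste(statuses$seedling_id[resurrect], collapse = ", "))
  time <- apply(m, 1L, function(x) if (any(x == 1L)) which.max(x == 1L) else length(x))
  event <- as.integer(apply(m, 1L, function(x) any(x == 1L)))
  data.frame(seedling_id = statuses$seedling_id, time = as.integer(time),
             event = event, stringsAsFactors = FALSE)
}

#' Fit a Cox proportional-hazards model of seedling mortality
#'
#' Partial-likelihood fit (via \code{survival::coxph}) of the hazard of
#' seedling death on any subset of the covariates \code{w} (seed weight),
#' \code{r} (parental relatedness), \code{qdis} and \code{fdis} (the two
#' ancestry-difference statistics). qdis and fdis measure the same contrast
#' on different scales and are never fitted jointly. Reports AIC = -2 pl +
#' 2p, BIC = -2 pl + p ln(events) and deviance = -2 pl, with pl the log
#' partial likelihood at the optimum and p the number of covariates.
#'
#' @param records survival records from \code{\link{code_survival}}.
#' @param covariates data.frame with seedling_id and the covariate columns.
#' @param formula character vector naming the covariates to fit (possibly
#'   empty for the null model).
#' @param ties "efron" (default) or "breslow".
#' @return a \code{cox_fit}: list with coefficients, se, p_values, loglik,
#'   df, AIC, BIC, deviance, n, n_events, formula, ties and the underlying
#'   \code{coxph} object.
#' @export
fit_cox <- function(records, covariates, formula = character(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (all(c("qdis", "fdis") %in% formula))
    stop("qdis and fdis measure the same contrast; fit them separately")
  df <- merge(records, covariates, by = "seedling_id")
  if (nrow(df) < nrow(records))
    warning(nrow(records) - nrow(df), " records dropped: no covariates")
  if (sum(df$event) < 1L) stop("no death events in the records")
  bad <- formula[!formula %in% names(df)]
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  rhs <- if (length(formula) == 0L) "1" else paste(formula, collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p <- length(formula)
  if (p > 0L && (diverged || any(!is.finite(sqrt(diag(as.matrix(fit$var)))))))
    stop("partial likelihood appears monotone (perfect separation); consider penalization")
  pl <- if (p == 0L) fit$loglik[1L] else fit$loglik[2L]
  nev <- sum(df$event)
  co <- if (p == 0L) numeric(0) else stats::coef(fit)
  se <- if (p == 0L) numeric(0) else sqrt(diag(fit$var))
  pv <- if (p == 0L) numeric(0) else 2 * stats::pnorm(-abs(co / se))
  structure(list(coefficients = co, se = stats::setNames(se, names(co)),
                 p_values = stats::setNames(pv, names(co)),
                 loglik = pl, df = p,
                 AIC = -2 * pl + 2 * p,
                 BIC = -2 * pl + p * log(nev),
                 deviance = -2 * pl, n = nrow(df), n_events = nev,
                 formula = formula, ties = ties, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  rhs <- if (length(x$formula) == 0L) "(null)" else paste(x$formula, collapse = " + ")
  cat("cox_fit:", rhs, " n =", x$n, " events =", x$n_events, "\n")
  if (x$df > 0L) {
    tab <- data.frame(coef = x$coefficients, se = x$se, p = x$p_values)
    print(round(tab, 4))
  }
  cat(sprintf("AIC %.2f  BIC %.2f  deviance %.2f\n", x$AIC, x$BIC, x$deviance))
  invisible(x)
}

#' Compare a set of Cox fits
#'
#' @param fits named (or unnamed) list of \code{cox_fit}s on identical
#'   records.
#' @return data.frame: one row per model with coefficient (se) strings per
#'   covariate, df, AIC, BIC, deviance and a \code{best_aic} flag.
#' @export
model_table <- function(fits) {
  key <- vapply(fits, function(f) paste(f$n, f$n_events), "")
  if (length(unique(key)) != 1L)
    stop("fits were made on different record sets")
  covs <- unique(unlist(lapply(fits, function(f) f$formula)))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("Model ", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    row <- list(model = nm)
    for (cv in covs) {
      row[[cv]] <- if (cv %in% f$formula)
        sprintf("%.3g (%.3g)", f$coefficients[[cv]], f$se[[cv]]) else ""
    }
    row$df <- f$df; row$AIC <- f$AIC; row$BIC <- f$BIC
    row$deviance <- f$deviance
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best_aic <- out$AIC == min(out$AIC)
  out
}

#' Fit the standard model family of seed-weight, relatedness and
#' ancestry-difference effects
#'
#' The eleven fixed-effects combinations of w, r and one of fdis/qdis:
#' each single covariate, each pair, and the two three-covariate models.
#'
#' @param records survival records.
#' @param covariates per-seedling covariate table.
#' @param ties tie handling, as in \code{\link{fit_cox}}.
#' @return named list of \code{cox_fit}s (Model 1 .. Model 11).
#' @export
cox_model_set <- function(records, covariates, ties = "efron") {
  formulas <- list(c("w"), c("r"), c("fdis"), c("qdis"),
                   c("w", "r"), c("w", "fdis"), c("w", "qdis"),
                   c("r", "fdis"), c("r", "qdis"),
                   c("w", "r", "fdis"), c("w", "r", "qdis"))
  fits <- lapply(formulas, function(f)
    tryCatch(fit_cox(records, covariates, f, ties), error = function(e) {
      warning("model {", paste(f, collapse = " + "), "} dropped: ",
              conditionMessage(e))
      NULL
    }))
  names(fits) <- paste0("Model ", seq_along(fits))
  Filter(Negate(is.null), fits)
}

#' Kaplan-Meier curves for seedlings grouped by an ancestry statistic
#'
#' Groups seedlings by thresholds on qdis or fdis (defaults: 0.1 and 0.35
#' for qdis; 0.02 and 0.035 for fdis) and estimates one Kaplan-Meier curve
#' per group.
#'
#' @param records survival records from \code{\link{code_survival}}.
#' @param covariates per-seedling covariate table.
#' @param statistic "qdis" or "fdis".
#' @param cuts strictly increasing thresholds; group g collects values in
#'   (cuts[g-1], cuts[g]].
#' @return data.frame (group, time, n_risk, n_event, surv); empty groups
#'   are omitted with a warning.
#' @export
km_by_group <- function(records, covariates, statistic = c("qdis", "fdis"),
                        cuts = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(cuts)) cuts <- if (statistic == "qdis") c(0.1, 0.35) else c(0.02, 0.035)
  if (any(diff(cuts) <= 0)) stop("cuts must be strictly increasing")
  df <- merge(records, covariates, by = "seedling_id")
  grp <- cut(df[[statistic]], breaks = c(-Inf, cuts, Inf),
             labels = as.character(seq_len(length(cuts) + 1L)))
  empty <- setdiff(levels(grp), unique(as.character(grp)))
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  out <- lapply(levels(grp), function(g) {
    sub <- df[grp == g, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
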