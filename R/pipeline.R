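default_pipeline_config <- function() {
  list(
    rng_seed = 1L,
    simulate = list(),                    # sim_config() overrides; NULL = file mode
    files = NULL,                         # file mode: adults, seedlings, mothers,
                                          # phenotypes, survival, heights (CSV paths)
    admixture = list(k_range = 1:6, reps = 5L, burnin = 2000L, iters = 10000L,
                     thin = 10L, K = NULL),
    parentage = list(n_sim = 10000L, error_rate = 0.001, max_mismatch = 2L),
    fst_signed = c(0.10552, 0.00044, -0.10342),
    survival = list(ties = "efron"),
    growth = list(chains = 3L, iters = 4000L, burnin = 1000L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> admixture clustering with delta-K
#' model choice -> paternity assignment -> parent-pair relatedness ->
#' covariate assembly -> Cox survival model set and grouped Kaplan-Meier
#' curves -> per-period Bayesian growth models, writing every intermediate
#' artifact plus a JSON manifest of seeds and per-stage counts. Two runs
#' with the same config produce byte-identical outputs.
#'
#' @param config a nested list (see \code{default} entries in the package
#'   source) or the path of a YAML file with the same structure. With a
#'   \code{simulate} block the input data are generated; otherwise
#'   \code{files} must name the input CSVs.
#' @param outdir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$rng_seed)
  manifest <- list(package_version = as.character(utils::packageVersion("heterofit")),
                   rng_seed = seed, stages = list())
  pth <- function(f) file.path(outdir, f)

  # ---- stage 0: inputs -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    simcfg <- do.call(sim_config, c(cfg$simulate, list(rng_seed = seed)))
    sim <- simulate_study(simcfg)
    adults <- sim$adults$genotypes
    seedlings <- sim$seedlings$genotypes
    mothers <- stats::setNames(sim$seedlings$truth$mother_id,
                               sim$seedlings$truth$seedling_id)
    phenotypes <- sim$fitness$phenotypes
    surv_raw <- sim$fitness$survival
    heights <- sim$fitness$heights
    write_wide_csv(adults, pth("adults_genotypes.csv"))
    write_wide_csv(seedlings, pth("seedling_genotypes.csv"))
    utils::write.csv(phenotypes, pth("phenotypes.csv"), row.names = FALSE, quote = FALSE)
  } else {
    fl <- cfg$files
    need <- c("adults", "seedlings", "mothers", "phenotypes", "survival", "heights")
    missing_keys <- setdiff(need, names(fl))
    if (length(missing_keys))
      stop("config validation: file mode lacks ", paste(missing_keys, collapse = ", "))
    absent <- unlist(fl[need])[!file.exists(unlist(fl[need]))]
    if (length(absent))
      stop("config validation: missing input files: ", paste(absent, collapse = ", "))
    adults <- read_wide_csv(fl$adults)
    seedlings <- read_wide_csv(fl$seedlings)
    mtab <- utils::read.csv(fl$mothers, stringsAsFactors = FALSE)
    mothers <- stats::setNames(mtab$mother_id, mtab$seedling_id)
    phenotypes <- utils::read.csv(fl$phenotypes, stringsAsFactors = FALSE)
    surv_raw <- utils::read.csv(fl$survival, stringsAsFactors = FALSE)
    heights <- utils::read.csv(fl$heights, stringsAsFactors = FALSE)
  }
  manifest$stages$input <- list(n_adults = n_individuals(adults),
                                n_seedlings = n_individuals(seedlings))

  # ---- stage 1: allele frequencies ------------------------------------
  freqs <- allele_frequencies(list(adults, seedlings))
  write_allele_frequencies(freqs, pth("allele_frequencies.csv"))
  manifest$stages$frequencies <- list(n_loci = length(freqs$freqs))

  # ---- stage 2: admixture clustering ----------------------------------
  adm <- cfg$admixture
  runset <- run_admixture_set(adults, k_range = adm$k_range, reps = adm$reps,
                              seed = seed + 100L, burnin = adm$burnin,
                              iters = adm$iters, thin = adm$thin)
  ev <- evanno_delta_k(runset)
  utils::write.csv(ev, pth("evanno_delta_k.csv"), row.names = FALSE, quote = FALSE)
  K <- if (!is.null(adm$K)) as.integer(adm$K) else attr(ev, "best_K")
  fit <- consensus_fit(runset$runs[[as.character(K)]])
  write_q_matrix(fit, pth("q_matrix.csv"))
  utils::write.csv(data.frame(cluster = seq_len(K), F = fit$F),
                   pth("cluster_fst.csv"), row.names = FALSE, quote = FALSE)
  manifest$stages$admixture <- list(selected_K = K, reps = adm$reps,
                                    F = round(fit$F, 5))

  # ---- stage 3: paternity ---------------------------------------------
  par <- cfg$parentage
  calib <- calibrate_delta(freqs, n_sim = par$n_sim,
                           n_candidates = n_individuals(adults),
                           error_rate = par$error_rate, seed = seed + 200L)
  records <- assign_paternity(seedlings, mothers, adults, freqs, calib,
                              max_mismatch = par$max_mismatch,
                              error_rate = par$error_rate)
  utils::write.csv(records, pth("parentage.csv"), row.names = FALSE, quote = FALSE)
  psum <- parentage_summary(records)
  utils::write.csv(psum, pth("parentage_summary.csv"), row.names = FALSE, quote = FALSE)
  cat_counts <- as.list(table(records$category))
  manifest$stages$parentage <- c(list(delta_crit = round(calib$delta_crit, 4)),
                                 cat_counts)

  # ---- stage 4: relatedness -------------------------------------------
  keep <- records[records$category == "single_donor", ]
  pairs <- unique(data.frame(id_i = keep$mother_id, id_j = keep$best_father_id,
                             stringsAsFactors = FALSE))
  rel <- relatedness_pairs(adults, pairs, freqs)
  utils::write.csv(rel, pth("relatedness.csv"), row.names = FALSE, quote = FALSE)
  manifest$stages$relatedness <- list(n_pairs = nrow(rel))

  # ---- stage 5: covariates --------------------------------------------
  covariates <- assemble_covariates(records, fit$Q, cfg$fst_signed, rel, phenotypes)
  utils::write.csv(covariates, pth("covariates.csv"), row.names = FALSE, quote = FALSE)
  manifest$stages$covariates <- c(list(n = nrow(covariates)),
                                  attr(covariates, "excluded"))

  # ---- stage 6: survival ----------------------------------------------
  srec <- code_survival(surv_raw)
  srec <- srec[srec$seedling_id %in% covariates$seedling_id, ]
  fits <- cox_model_set(srec, covariates, ties = cfg$survival$ties)
  mt <- model_table(fits)
  utils::write.csv(mt, pth("cox_model_table.csv"), row.names = FALSE)
  for (st in c("qdis", "fdis")) {
    km <- km_by_group(srec, covariates, st)
    utils::write.csv(km, pth(paste0("km_", st, ".csv")), row.names = FALSE, quote = FALSE)
  }
  manifest$stages$survival <- list(n = nrow(srec), events = sum(srec$event),
                                   best_model = mt$model[mt$best_aic][1L])

  # ---- stage 7: growth -------------------------------------------------
  rgr <- compute_rgr(heights)
  rgr <- rgr[rgr$seedling_id %in% covariates$seedling_id, ]
  gw <- cfg$growth
  for (st in c("qdis", "fdis")) {
    set.seed(seed + 300L + (st == "fdis"))
    gs <- fit_growth_by_period(rgr, covariates, st, chains = gw$chains,
                               iters = gw$iters, burnin = gw$burnin)
    utils::write.csv(gs, pth(paste0("growth_", st, ".csv")), row.names = FALSE,
                     quote = FALSE)
    manifest$stages[[paste0("growth_", st)]] <-
      list(n_periods = length(unique(gs$period)),
           max_rhat = round(max(gs$Rhat), 4))
  }

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
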