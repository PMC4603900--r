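#' Default configuration of the synthetic-cohort generator
#'
#' The defaults emulate the statistical structure of an 814-patient
#' early-stage NSCLC surgical cohort genotyped on the eight-SNP panel:
#' genotypes in Hardy-Weinberg proportions at the panel's observed
#' variant-allele frequencies, clinical covariates at the study's marginal
#' prevalences (47% over 64 years, 73% male, 69% ever-smokers, histology
#' SCC/AC/LCC 45/51/4%, 60% stage I), proportional-hazards event times with
#' per-SNP effects equal to the reported adjusted hazard ratios on the log
#' scale under each SNP's genetic model, uniform-accrual administrative
#' censoring, and month-resolution follow-up. The baseline hazards and the
#' censoring window are calibrated so that the default cohort reproduces the
#' study's marginal outcome statistics: about 30% deaths, about 49% DFS
#' events and a Kaplan-Meier 5-year overall survival near 64%.
#'
#' @param n cohort size (default 814)
#' @param seed master seed; per-component substreams are derived from it
#' @param panel panel specification (default [default_panel()])
#' @return a list of class `generator_config`
#' @export
default_generator_config <- function(n = 814, seed = 1,
                                     panel = default_panel()) {
  ids <- names(panel$snps)
  # variant-allele frequencies back-calculated from the observed genotype counts
  maf <- c(rs967591 = 0.5056, rs1047266 = 0.2680, rs3803300 = 0.3761,
           rs2287845 = 0.1410, rs1256428 = 0.4479, rs3756585 = 0.3059,
           rs11259927 = 0.3887, rs3181259 = 0.5616)
  # per-SNP adjusted hazard ratios (log scale) under each SNP's genetic model
  snp_hr_os <- c(rs967591 = 1.68, rs1047266 = 1.77, rs3803300 = 1.35,
                 rs2287845 = 1.44, rs1256428 = 1.25, rs3756585 = 1.33,
                 rs11259927 = 1.52, rs3181259 = 1.45)
  snp_hr_dfs <- c(rs967591 = 1.32, rs1047266 = 1.62, rs3803300 = 1.17,
                  rs2287845 = 1.39, rs1256428 = 1.11, rs3756585 = 1.15,
                  rs11259927 = 1.35, rs3181259 = 1.24)
  # per-SNP genotyping failure rates matching the observed per-SNP totals
  missing_rate <- c(rs967591 = 7, rs1047266 = 10, rs3803300 = 7,
                    rs2287845 = 9, rs1256428 = 8, rs3756585 = 5,
                    rs11259927 = 10, rs3181259 = 10) / 814
  structure(list(
    n = n, seed = seed, panel = panel,
    maf = maf[ids],
    snp_effects_os = log(snp_hr_os[ids]),
    snp_effects_dfs = log(snp_hr_dfs[ids]),
    effect_mode = "model",
    missing_rate = missing_rate[ids],
    covariate_prevalence = list(
      age_gt64 = 0.468, male = 0.735, ever_smoker = 0.690,
      histology = c(SCC = 0.4533, AC = 0.5086, LCC = 0.0381),
      stage_II_IIIA = 0.399, adjuvant = 0.30),
    covariate_effects_os = c(
      age_gt64 = log(1.6), male = log(1.35), ever_smoker = log(1.25),
      histology_AC = 0, histology_LCC = log(1.5),
      stage_II_IIIA = log(1.9), adjuvant = 0),
    covariate_effects_dfs = c(
      age_gt64 = log(1.32), male = 0, ever_smoker = 0,
      histology_AC = log(1.35), histology_LCC = log(1.45),
      stage_II_IIIA = log(1.8), adjuvant = 0),
    # monthly hazards for a reference subject; calibrated to the marginal
    # death fraction (0.301), DFS-event fraction (0.494) and 5-year OS (0.64)
    baseline_rate_os = 0.00102,
    baseline_rate_recurrence = 0.00249,
    accrual = 80, cutoff = 90,
    round_months = TRUE
  ), class = "generator_config")
}

#' Reference hazard ratios of the combined risk-group analysis
#'
#' The packaged effect sizes used by the generator and the validation
#' simulations for the high-vs-low risk-group contrast: adjusted HR 2.21 for
#' overall survival and 1.58 for disease-free survival.
#'
#' @return named numeric vector `c(os = 2.21, dfs = 1.58)`
#' @export
default_combined_effects <- function() c(os = 2.21, dfs = 1.58)

#' Read a generator configuration from YAML
#'
#' Entries present in the file override the packaged defaults of
#' [default_generator_config()].
#'
#' @param path YAML file
#' @param panel panel specification used for defaults
#' @return a `generator_config`
#' @export
read_generator_config <- function(path, panel = default_panel()) {
  cfg <- yaml::read_yaml(path)
  base <- default_generator_config(n = cfg$n %||% 814,
                                   seed = cfg$seed %||% 1, panel = panel)
  for (nm in setdiff(names(cfg), c("n", "seed"))) {
    if (!nm %in% names(base)) stop_ctx("unknown config entry '", nm, "'")
    val <- cfg[[nm]]
    base[[nm]] <- if (is.list(val) && !is.list(base[[nm]])) unlist(val) else val
  }
  validate_generator_config(base)
  base
}

validate_generator_config <- function(config) {
  stopifnot(config$n >= 1)
  freqs <- c(config$maf, config$missing_rate,
             unlist(config$covariate_prevalence))
  if (any(freqs < 0 | freqs > 1)) stop_ctx("frequencies must lie in [0, 1]")
  if (config$baseline_rate_os < 0 || config$baseline_rate_recurrence < 0) {
    stop_ctx("baseline rates must be nonnegative")
  }
  if (config$accrual < 0 || config$cutoff <= 0) {
    stop_ctx("accrual must be >= 0 and cutoff > 0")
  }
  invisible(config)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws genotypes with probabilities `(1-q)^2`, `2q(1-q)`, `q^2` for the
#' wild homozygote, heterozygote and variant homozygote, where `q` is the
#' variant-allele frequency.
#'
#' @param n number of subjects
#' @param spec a [snp_spec()]
#' @param maf variant-allele frequency in `[0, 1]`
#' @param seed integer seed
#' @return character vector of canonical genotype strings
#' @export
simulate_genotypes <- function(n, spec, maf, seed) {
  if (maf < 0 || maf > 1) stop_ctx("maf must lie in [0, 1]")
  set.seed(seed)
  lv <- genotype_levels(spec)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample(lv, n, replace = TRUE, prob = p)
}

#' Simulate clinical covariates
#'
#' Independent Bernoulli draws per binary covariate at the configured
#' prevalence, a multinomial draw for histology (probabilities must sum to
#' one), and pack-years drawn for ever-smokers only.
#'
#' @param n number of subjects
#' @param config a `generator_config`
#' @param seed integer seed
#' @return data frame of clinical columns (without survival outcomes)
#' @export
simulate_covariates <- function(n, config, seed) {
  pv <- config$covariate_prevalence
  hp <- pv$histology
  if (abs(sum(hp) - 1) > 1e-6) {
    stop_ctx("histology prevalences must sum to 1")
  }
  set.seed(seed)
  smoking <- ifelse(stats::runif(n) < pv$ever_smoker, "ever", "never")
  pack_years <- ifelse(smoking == "ever",
                       round(pmax(1, stats::rlnorm(n, log(38), 0.5))),
                       NA_real_)
  data.frame(
    age_group = ifelse(stats::runif(n) < pv$age_gt64, ">64", "<=64"),
    sex = ifelse(stats::runif(n) < pv$male, "male", "female"),
    smoking = smoking,
    pack_years = pack_years,
    histology = sample(names(hp), n, replace = TRUE, prob = hp),
    stage = ifelse(stats::runif(n) < pv$stage_II_IIIA, "II-IIIA", "I"),
    adjuvant_chemo = ifelse(stats::runif(n) < pv$adjuvant, "yes", "no"),
    stringsAsFactors = FALSE)
}

# linear predictor of the genotype block under the configured effect mode
genotype_linear_predictor <- function(genotypes, config, effects) {
  if (is.null(genotypes) || length(effects) == 0) {
    return(rep(0, if (is.null(genotypes)) 0 else nrow(genotypes)))
  }
  lp <- rep(0, nrow(genotypes))
  for (id in intersect(names(effects), names(genotypes))) {
    spec <- config$panel$snps[[id]]
    if (config$effect_mode == "genotype") {
      # per-genotype effects: named c(het = ..., hom = ...) on the log scale
      e <- effects[[id]]
      lv <- genotype_levels(spec)
      lp <- lp + e[["het"]] * (genotypes[[id]] == lv[2L]) +
        e[["hom"]] * (genotypes[[id]] == lv[3L])
    } else {
      code <- genotype_code(genotypes[[id]], spec$genetic_model, spec)
      if (anyNA(code)) stop_ctx("missing genotype in survival simulation")
      lp <- lp + effects[[id]] * code
    }
  }
  lp
}

covariate_linear_predictor <- function(covariates, effects) {
  if (is.null(covariates) || length(effects) == 0) {
    return(rep(0, if (is.null(covariates)) 0 else nrow(covariates)))
  }
  lp <- rep(0, nrow(covariates))
  known <- names(covariate_levels())
  fac <- intersect(names(covariates), known)
  if (length(fac)) {
    D <- build_design(covariates, fac)
    for (nm in intersect(colnames(D), names(effects))) {
      lp <- lp + effects[[nm]] * D[, nm]
    }
  }
  for (nm in setdiff(names(covariates), c(fac, "pack_years"))) {
    if (nm %in% names(effects)) {
      lp <- lp + effects[[nm]] * as.numeric(covariates[[nm]])
    }
  }
  lp
}

#' Simulate proportional-hazards survival outcomes
#'
#' Latent death and recurrence times are drawn from exponential baseline
#' hazards scaled by `exp(linear predictor)`, where the linear predictor
#' sums the model-coded genotype effects and the covariate effects of the
#' configuration (the OS effect set drives the death hazard, the DFS set the
#' recurrence hazard). Censoring is administrative: cutoff minus a uniform
#' accrual offset. `os_time = min(death, censoring)` and
#' `dfs_time = min(recurrence, death, censoring)`, so DFS events dominate
#' deaths by construction. With `round_months` the observed times are
#' rounded up to whole months, producing the heavy ties of month-resolution
#' follow-up.
#'
#' @param genotypes data frame of genotype calls (one column per SNP), or
#'   `NULL` for no genotype effects
#' @param covariates data frame of clinical covariates and/or numeric
#'   columns named in the configured effect vectors, or `NULL`
#' @param config a `generator_config`
#' @param seed integer seed
#' @return data frame with `os_time`, `os_event`, `dfs_time`, `dfs_event`
#' @export
simulate_survival <- function(genotypes, covariates, config, seed) {
  validate_generator_config(config)
  n <- if (!is.null(genotypes)) nrow(genotypes) else nrow(covariates)
  if (is.null(n) || n < 1) stop_ctx("no subjects to simulate")
  pad <- function(x) if (length(x) == 0) rep(0, n) else x
  lp_os <- pad(genotype_linear_predictor(genotypes, config,
                                         config$snp_effects_os)) +
    pad(covariate_linear_predictor(covariates, config$covariate_effects_os))
  lp_dfs <- pad(genotype_linear_predictor(genotypes, config,
                                          config$snp_effects_dfs)) +
    pad(covariate_linear_predictor(covariates,
                                   config$covariate_effects_dfs))
  set.seed(seed)
  draw_time <- function(rate, lp) {
    if (rate == 0) rep(Inf, n) else stats::rexp(n) / (rate * exp(lp))
  }
  t_death <- draw_time(config$baseline_rate_os, lp_os)
  t_rec <- draw_time(config$baseline_rate_recurrence, lp_dfs)
  censor <- config$cutoff - stats::runif(n, 0, config$accrual)
  os_event <- as.numeric(t_death <= censor)
  t_first <- pmin(t_death, t_rec)
  dfs_event <- as.numeric(t_first <= censor)
  os_time <- pmin(t_death, censor)
  dfs_time <- pmin(t_first, censor)
  if (isTRUE(config$round_months)) {
    os_time <- ceiling(os_time)
    dfs_time <- ceiling(dfs_time)
  }
  data.frame(os_time = os_time, os_event = os_event,
             dfs_time = dfs_time, dfs_event = dfs_event)
}

#' Generate a full synthetic cohort
#'
#' Assembles genotypes, covariates and survival outcomes into a validated
#' [snp_cohort()], masks genotypes as missing at the configured per-SNP
#' rates (after the survival draw, so missingness is non-informative), and
#' returns the generating effect values for parameter-recovery studies. All
#' draws run under substreams derived from the master seed, one per
#' component, so the output is bit-reproducible and adding a SNP does not
#' perturb the covariate or survival draws.
#'
#' @param config a `generator_config`, e.g. [default_generator_config()]
#' @return list with elements `cohort` (a [snp_cohort()]) and `effects`
#'   (the generating log-hazard values per SNP and covariate, per endpoint)
#' @export
generate_cohort <- function(config = default_generator_config()) {
  validate_generator_config(config)
  n <- config$n; seed <- config$seed
  ids <- names(config$panel$snps)
  covs <- simulate_covariates(n, config, substream_seed(seed, "covariates"))
  geno <- as.data.frame(
    lapply(stats::setNames(ids, ids), function(id) {
      simulate_genotypes(n, config$panel$snps[[id]], config$maf[[id]],
                         substream_seed(seed, paste0("genotype:", id)))
    }), stringsAsFactors = FALSE)
  surv <- simulate_survival(geno, covs, config,
                            substream_seed(seed, "survival"))
  for (id in ids) {
    set.seed(substream_seed(seed, paste0("missing:", id)))
    geno[[id]][stats::runif(n) < config$missing_rate[[id]]] <- NA_character_
  }
  subjects <- cbind(
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               stringsAsFactors = FALSE),
    covs, surv, geno)
  effects <- list(
    snp_os = config$snp_effects_os, snp_dfs = config$snp_effects_dfs,
    covariate_os = config$covariate_effects_os,
    covariate_dfs = config$covariate_effects_dfs,
    baseline_rate_os = config$baseline_rate_os,
    baseline_rate_recurrence = config$baseline_rate_recurrence,
    seed = seed)
  list(cohort = snp_cohort(subjects, config$panel), effects = effects)
}
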