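#' Numeric genotype coding under a genetic model
#'
#' Collapses genotype calls to the numeric code of a genetic model:
#' additive counts risk alleles (0/1/2), dominant indicates carriage of at
#' least one risk allele, recessive indicates the risk-allele homozygote.
#' When `risk_direction = "wild"` the orientation is flipped (the wild
#' allele counts as the risk allele). Missing calls code as `NA`.
#'
#' @param calls character genotype calls (canonical or not; normalized
#'   internally)
#' @param model `"additive"`, `"dominant"` or `"recessive"`
#' @param spec the [snp_spec()] of the SNP
#' @param risk_direction `"variant"` or `"wild"`; defaults to the spec's
#'   orientation
#' @return numeric vector of codes with `NA` for missing calls
#' @export
genotype_code <- function(calls, model, spec, risk_direction = NULL) {
  model <- match.arg(model, c("additive", "dominant", "recessive"))
  risk_direction <- risk_direction %||% spec$risk_direction
  if (is.null(risk_direction) || is.na(risk_direction)) {
    stop_ctx("risk_direction not set for ", spec$snp_id)
  }
  calls <- normalize_genotype(calls, spec)
  vc <- match(calls, genotype_levels(spec)) - 1  # variant-allele count
  risk <- if (risk_direction == "variant") vc else 2 - vc
  switch(model,
    additive  = risk,
    dominant  = as.numeric(risk >= 1),
    recessive = as.numeric(risk == 2))
}

#' Genotype counts of one panel SNP in a cohort
#'
#' @param cohort a [snp_cohort()]
#' @param snp_id SNP identifier present in the panel
#' @return list with `n_wild_hom`, `n_het`, `n_var_hom`, `n_missing`
#' @export
genotype_counts <- function(cohort, snp_id) {
  spec <- cohort$panel$snps[[snp_id]]
  if (is.null(spec)) stop_ctx("SNP ", snp_id, " not in panel")
  g <- cohort$subjects[[snp_id]]
  lv <- genotype_levels(spec)
  list(n_wild_hom = sum(g == lv[1L], na.rm = TRUE),
       n_het      = sum(g == lv[2L], na.rm = TRUE),
       n_var_hom  = sum(g == lv[3L], na.rm = TRUE),
       n_missing  = sum(is.na(g)))
}

#' Minor allele frequency and Hardy-Weinberg test from genotype counts
#'
#' The variant-allele frequency is `(n_het + 2 n_var_hom) / (2 n)` over
#' non-missing genotypes; the reported MAF is folded to at most 0.5. The
#' Hardy-Weinberg p-value comes from the one-degree-of-freedom chi-square of
#' observed vs expected genotype counts at the estimated allele frequency.
#' A monomorphic SNP returns `maf = 0`, `hwe_p = 1`.
#'
#' @param counts a [genotype_counts()] result, or a numeric vector of length
#'   three `(n_wild_hom, n_het, n_var_hom)`
#' @return list with `maf`, `variant_freq`, `hwe_chisq`, `hwe_p`
#' @export
allele_stats <- function(counts) {
  if (is.list(counts)) {
    counts <- c(counts$n_wild_hom, counts$n_het, counts$n_var_hom)
  }
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop_ctx("no genotyped subjects")
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  maf <- min(q, 1 - q)
  if (q == 0 || q == 1) {
    return(list(maf = 0, variant_freq = q, hwe_chisq = 0, hwe_p = 1))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(maf = maf, variant_freq = q, hwe_chisq = chisq,
       hwe_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square test of genotype distribution by a clinical factor
#'
#' @param tab contingency table (matrix) of genotype by factor level, at
#'   least 2 x 2, with no zero row or column margin
#' @return list with `statistic`, `df`, `p_value`
#' @export
genotype_by_factor_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop_ctx("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_ctx("degenerate table: zero margin")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Adjusted survival association of one SNP
#'
#' The per-SNP analysis engine: genotype counts with column percentages,
#' minor-allele frequency and Hardy-Weinberg p, Kaplan-Meier 5-year rates
#' per genotype, log-rank p across genotypes, and covariate-adjusted Cox
#' fits at genotype level (heterozygote and variant-homozygote each
#' contrasted with the wild homozygote) and under the three collapsed
#' genetic models. Subjects missing this SNP's genotype (or any adjustment
#' covariate) are excluded from this SNP's analysis only, so each SNP keeps
#' its own denominator.
#'
#' A genotype stratum with zero events makes the corresponding contrast
#' non-estimable; its HR is reported as `NA`.
#'
#' @param cohort a [snp_cohort()]
#' @param snp_id SNP identifier in the panel
#' @param endpoint `"os"` or `"dfs"`
#' @param covariate_set covariates for adjustment; default the panel's set
#' @param ties passed to [cox_fit()]
#' @param horizon time at which per-genotype survival rates are reported
#'   (default 60 months, i.e. 5 years)
#' @return object of class `snp_association`
#' @export
per_snp_analysis <- function(cohort, snp_id, endpoint = c("os", "dfs"),
                             covariate_set = NULL, ties = "efron",
                             horizon = 60) {
  endpoint <- match.arg(endpoint)
  spec <- cohort$panel$snps[[snp_id]]
  if (is.null(spec)) stop_ctx("SNP ", snp_id, " not in panel")
  covariate_set <- covariate_set %||% cohort$panel$covariate_set
  counts <- genotype_counts(cohort, snp_id)
  stats_al <- allele_stats(counts)
  ep <- endpoint_data(cohort, endpoint)
  g <- cohort$subjects[[snp_id]]
  Z <- build_design(cohort$subjects, covariate_set)
  keep <- !is.na(g) & stats::complete.cases(Z)
  g <- g[keep]; Z <- Z[keep, , drop = FALSE]
  time <- ep$time[keep]; event <- ep$event[keep]
  lv <- genotype_levels(spec)
  n_geno <- sum(keep)
  pct <- 100 * c(counts$n_wild_hom, counts$n_het, counts$n_var_hom) /
    (counts$n_wild_hom + counts$n_het + counts$n_var_hom)

  five_year <- events_by_geno <- stats::setNames(rep(NA_real_, 3L), lv)
  for (i in seq_along(lv)) {
    sel <- g == lv[i]
    if (any(sel)) {
      five_year[i] <- survival_at(km_estimate(time[sel], event[sel]), horizon)
      events_by_geno[i] <- sum(event[sel])
    }
  }
  present <- lv[lv %in% unique(g)]
  logrank_p <- if (length(present) >= 2L) {
    logrank_test(time, event, factor(g, levels = present))$p_value
  } else NA_real_

  risk_dir <- if (is.na(spec$risk_direction)) "variant" else
    spec$risk_direction

  fit_safe <- function(design, labels) {
    tryCatch(cox_fit(time, event, design, labels = labels, ties = ties),
             error = function(e) NULL)
  }
  # genotype-level: het and variant-homozygote vs wild-homozygote
  het <- as.numeric(g == lv[2L]); hom <- as.numeric(g == lv[3L])
  geno_fit <- fit_safe(cbind(het = het, var_hom = hom, Z),
                       c("het", "var_hom", colnames(Z)))
  # a stratum with zero events gives a diverging contrast: mark non-estimable
  if (!is.null(geno_fit)) {
    for (i in 2:3) {
      if (!is.na(events_by_geno[i]) && events_by_geno[i] == 0) {
        k <- i - 1L
        geno_fit$hr[k] <- geno_fit$ci95[k, ] <- geno_fit$wald_p[k] <- NA
      }
    }
  }
  model_fits <- list()
  for (m in c("dominant", "recessive", "additive")) {
    code <- genotype_code(g, m, spec, risk_direction = risk_dir)
    model_fits[[m]] <- fit_safe(cbind(code, Z), c(m, colnames(Z)))
  }

  structure(list(
    snp_id = snp_id, gene = spec$gene, spec = spec, endpoint = endpoint,
    counts = counts, percent = stats::setNames(pct, lv),
    n_analyzed = n_geno,
    maf = stats_al$maf, variant_freq = stats_al$variant_freq,
    hwe_p = stats_al$hwe_p,
    five_year_rate = five_year, events_by_genotype = events_by_geno,
    logrank_p = logrank_p,
    genotype_fit = geno_fit, model_fits = model_fits,
    covariate_set = covariate_set, horizon = horizon
  ), class = "snp_association")
}

#' Wald p-value of the genotype term of a collapsed-model fit
#' @keywords internal
model_p <- function(assoc, model) {
  f <- assoc$model_fits[[model]]
  if (is.null(f) || !f$converged) NA_real_ else unname(f$wald_p[1L])
}

#' @export
print.snp_association <- function(x, ...) {
  cat(sprintf("%s (%s), endpoint %s: n = %d (%d missing), MAF = %.3f, HWE p = %.3g\n",
              x$snp_id, x$gene, toupper(x$endpoint), x$n_analyzed,
              x$counts$n_missing, x$maf, x$hwe_p))
  for (m in names(x$model_fits)) {
    f <- x$model_fits[[m]]
    if (is.null(f)) next
    cat(sprintf("  %-9s HR = %.2f (%.2f-%.2f), p = %.3g\n", m, f$hr[1L],
                f$ci95[1L, "lower"], f$ci95[1L, "upper"], f$wald_p[1L]))
  }
  invisible(x)
}
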