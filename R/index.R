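#' Select the genetic model for a SNP from its survival association
#'
#' Among the converged collapsed-model fits (dominant, recessive, additive),
#' returns the model with the smallest Wald p-value for the genotype term.
#' Ties at full numeric precision are broken by the preference order
#' additive > recessive > dominant. An explicit model in the SNP's
#' specification should override selection (handled by the caller).
#'
#' @param assoc a [per_snp_analysis()] result (conventionally for overall
#'   survival, since the score reflects relative risk of death)
#' @return model name
#' @export
select_genetic_model <- function(assoc) {
  stopifnot(inherits(assoc, "snp_association"))
  candidates <- c("additive", "recessive", "dominant")
  p <- vapply(candidates, function(m) model_p(assoc, m), numeric(1))
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    stop_ctx("no genetic model converged for ", assoc$snp_id)
  }
  names(p)[which.min(p)]
}

#' Genotype score map of a panel
#'
#' Assigns each genotype of each SNP a score in \{1, 2, 3\}: under the
#' additive model the three genotypes score 1 (low risk), 2 (intermediate)
#' and 3 (high risk) by risk-allele count; under the dominant model
#' risk-allele carriers score 3 and the others 1; under the recessive model
#' the risk-allele homozygote scores 3 and the others 1. The model comes
#' from the SNP specification when set, otherwise from [select_genetic_model()]
#' applied to the supplied associations; the risk orientation comes from the
#' specification when set, otherwise from the sign of the fitted model
#' coefficient (a zero coefficient with unset orientation is an error).
#'
#' @param panel a [panel_spec()]
#' @param associations named list of [per_snp_analysis()] results (by
#'   snp_id); required for any SNP whose model or orientation is unset
#' @return object of class `score_map`: a named list mapping each snp_id to
#'   a named numeric vector over its three genotypes, plus a `models`
#'   attribute recording the model used per SNP
#' @export
build_score_map <- function(panel, associations = NULL) {
  stopifnot(inherits(panel, "panel_spec"))
  maps <- list(); models <- character(0); directions <- character(0)
  for (id in names(panel$snps)) {
    spec <- panel$snps[[id]]
    model <- spec$genetic_model
    if (is.na(model)) {
      if (is.null(associations[[id]])) {
        stop_ctx("no association supplied for model selection of ", id)
      }
      model <- select_genetic_model(associations[[id]])
    }
    dir <- spec$risk_direction
    if (is.na(dir)) {
      f <- associations[[id]]$model_fits[[model]]
      if (is.null(f)) stop_ctx("no converged ", model, " fit for ", id)
      beta <- unname(f$coefficients[1L])
      if (beta == 0) {
        stop_ctx("orientation undecidable for ", id,
                 ": zero coefficient and no risk_direction")
      }
      # fits code the variant allele as risk; a negative coefficient means
      # the wild allele carries the risk
      dir <- if (beta > 0) "variant" else "wild"
    }
    lv <- genotype_levels(spec)
    risk_count <- if (dir == "variant") 0:2 else 2:0
    score <- switch(model,
      additive  = 1 + risk_count,
      dominant  = ifelse(risk_count >= 1, 3, 1),
      recessive = ifelse(risk_count == 2, 3, 1))
    maps[[id]] <- stats::setNames(as.numeric(score), lv)
    models[id] <- model; directions[id] <- dir
  }
  structure(maps, models = models, directions = directions,
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  models <- attr(x, "models")
  for (id in names(x)) {
    cat(sprintf("  %-11s (%-9s): %s\n", id, models[[id]],
                paste(names(x[[id]]), x[[id]], sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Per-subject prognostic index
#'
#' The index is the sum of the per-SNP genotype scores. A subject with any
#' missing genotype on the panel has an undefined index (`NA`) and is
#' excluded from combined analyses.
#'
#' @param cohort a [snp_cohort()], or its subject data frame
#' @param score_map a [build_score_map()] result covering the panel
#' @return integer vector of indices (with `NA` for undefined)
#' @export
compute_index <- function(cohort, score_map) {
  subjects <- if (inherits(cohort, "snp_cohort")) cohort$subjects else cohort
  idx <- rep(0, nrow(subjects))
  for (id in names(score_map)) {
    g <- subjects[[id]]
    if (is.null(g)) stop_ctx("cohort lacks genotype column ", id)
    idx <- idx + unname(score_map[[id]][g])
  }
  as.integer(idx)
}

#' Approximate-tertile integer cutoff of the prognostic index
#'
#' Scans all integer cutoffs and returns the one whose high-risk fraction
#' (subjects with index at or above the cutoff) is closest to the target
#' fraction (default one third); ties go to the smaller cutoff.
#'
#' @param indices integer indices (`NA` entries are ignored)
#' @param target_fraction desired high-risk fraction, default `1/3`
#' @return integer cutoff
#' @export
choose_cutoff <- function(indices, target_fraction = 1 / 3) {
  x <- indices[!is.na(indices)]
  if (length(x) == 0) stop_ctx("no defined indices")
  candidates <- seq(min(x), max(x) + 1L)
  frac <- vapply(candidates, function(c) mean(x >= c), numeric(1))
  candidates[which.min(abs(frac - target_fraction))]
}

#' Combined risk-group survival analysis
#'
#' Classifies subjects with a defined prognostic index into low
#' (`index < cutoff`) and high (`index >= cutoff`) risk groups and compares
#' their survival: group sizes and column percentages, event counts with row
#' percentages, Kaplan-Meier curves and 5-year rates per group, the log-rank
#' test, and a covariate-adjusted Cox model with the high-risk indicator.
#'
#' @param cohort a [snp_cohort()]
#' @param score_map a [build_score_map()] result
#' @param cutoff integer cutoff (e.g. from [choose_cutoff()])
#' @param endpoint `"os"` or `"dfs"`
#' @param covariate_set adjustment covariates; default the panel's set
#' @param ties passed to [cox_fit()]
#' @param horizon rate horizon in months (default 60)
#' @return object of class `risk_group_report`
#' @export
combined_analysis <- function(cohort, score_map, cutoff,
                              endpoint = c("os", "dfs"),
                              covariate_set = NULL, ties = "efron",
                              horizon = 60) {
  endpoint <- match.arg(endpoint)
  covariate_set <- covariate_set %||% cohort$panel$covariate_set
  idx <- compute_index(cohort, score_map)
  Z <- build_design(cohort$subjects, covariate_set)
  keep <- !is.na(idx) & stats::complete.cases(Z)
  if (!any(keep)) stop_ctx("no subjects with defined index")
  idx_k <- idx[keep]
  high <- as.numeric(idx_k >= cutoff)
  if (length(unique(high)) < 2L) {
    stop_ctx("degenerate classification: all subjects fall in one risk group")
  }
  ep <- endpoint_data(cohort, endpoint)
  time <- ep$time[keep]; event <- ep$event[keep]
  groups <- list(low = high == 0, high = high == 1)
  n_group <- vapply(groups, sum, numeric(1))
  events_group <- vapply(groups, function(s) sum(event[s]), numeric(1))
  curves <- lapply(groups, function(s) km_estimate(time[s], event[s]))
  rate5 <- vapply(curves, survival_at, numeric(1), t = horizon)
  lr <- logrank_test(time, event, factor(high, levels = c(0, 1),
                                         labels = c("low", "high")))
  fit <- cox_fit(time, event,
                 cbind(high_risk = high, Z[keep, , drop = FALSE]),
                 ties = ties)
  structure(list(
    endpoint = endpoint, cutoff = cutoff,
    n = sum(keep), n_excluded = sum(!keep),
    group_n = n_group, group_pct = 100 * n_group / sum(keep),
    group_events = events_group,
    group_event_pct = 100 * events_group / n_group,
    five_year_rate = rate5,
    curves = curves, logrank = lr, fit = fit,
    hr = unname(fit$hr[1L]),
    ci95 = fit$ci95[1L, ], p = unname(fit$wald_p[1L]),
    covariate_set = covariate_set, horizon = horizon
  ), class = "risk_group_report")
}

#' @export
print.risk_group_report <- function(x, ...) {
  cat(sprintf("Risk-group analysis (%s), cutoff %d: n = %d (%d excluded)\n",
              toupper(x$endpoint), x$cutoff, x$n, x$n_excluded))
  for (g in c("low", "high")) {
    cat(sprintf("  %-4s risk: %d (%.1f%%), events %d (%.1f%%), %d-month rate %.0f%%\n",
                g, x$group_n[[g]], x$group_pct[[g]], x$group_events[[g]],
                x$group_event_pct[[g]], x$horizon,
                100 * x$five_year_rate[[g]]))
  }
  cat(sprintf("  log-rank p = %.3g; adjusted HR %.2f (%.2f-%.2f), p = %.3g\n",
              x$logrank$p_value, x$hr, x$ci95[["lower"]], x$ci95[["upper"]],
              x$p))
  invisible(x)
}

#' Fit the SNP-panel prognostic index to a cohort
#'
#' The end-to-end modelling function. For each panel SNP it runs the
#' covariate-adjusted per-SNP association analysis for both endpoints;
#' selects a genetic model per SNP (overall-survival Wald p, unless the
#' panel fixes the model); assigns genotype scores 1/2/3; sums them into the
#' per-subject prognostic index; chooses the approximate-tertile integer
#' cutoff (or uses a fixed one); and compares the resulting high and low
#' risk groups with Kaplan-Meier, log-rank and adjusted Cox analyses for
#' overall and disease-free survival.
#'
#' @param cohort a [snp_cohort()]
#' @param cutoff `"auto"` for the approximate-tertile rule or an integer
#'   (e.g. 15 to reproduce a fixed published cutoff)
#' @param covariate_set adjustment covariates; default the panel's set
#' @param target_fraction high-risk target fraction for the automatic
#'   cutoff, default `1/3`
#' @param ties tie handling for all Cox fits, `"efron"` (default) or
#'   `"breslow"`
#' @return an object of class `prognostic_index` with components
#'   `associations` (per endpoint, per SNP), `models`, `score_map`, `index`
#'   (per subject, `NA` when undefined), `cutoff`, `risk_group`, and `combined`
#'   (per endpoint [combined_analysis()] reports)
#' @seealso [summary.prognostic_index()], [predict.prognostic_index()],
#'   [plot.prognostic_index()]
#' @export
prognostic_index <- function(cohort, cutoff = "auto", covariate_set = NULL,
                             target_fraction = 1 / 3, ties = "efron") {
  stopifnot(inherits(cohort, "snp_cohort"))
  covariate_set <- covariate_set %||% cohort$panel$covariate_set
  ids <- names(cohort$panel$snps)
  associations <- list(
    os = lapply(stats::setNames(ids, ids), per_snp_analysis,
                cohort = cohort, endpoint = "os",
                covariate_set = covariate_set, ties = ties),
    dfs = lapply(stats::setNames(ids, ids), per_snp_analysis,
                 cohort = cohort, endpoint = "dfs",
                 covariate_set = covariate_set, ties = ties))
  score_map <- build_score_map(cohort$panel, associations$os)
  idx <- compute_index(cohort, score_map)
  cut_val <- if (identical(cutoff, "auto")) {
    choose_cutoff(idx, target_fraction)
  } else {
    as.integer(cutoff)
  }
  risk_group <- ifelse(is.na(idx), NA_character_,
                       ifelse(idx >= cut_val, "high", "low"))
  combined <- list(
    os = combined_analysis(cohort, score_map, cut_val, "os",
                           covariate_set, ties),
    dfs = combined_analysis(cohort, score_map, cut_val, "dfs",
                            covariate_set, ties))
  structure(list(
    cohort = cohort, covariate_set = covariate_set, ties = ties,
    associations = associations,
    models = attr(score_map, "models"),
    score_map = score_map,
    index = idx, cutoff = cut_val, cutoff_mode = if (identical(cutoff, "auto")) "auto" else "fixed",
    risk_group = risk_group,
    combined = combined
  ), class = "prognostic_index")
}

#' @export
print.prognostic_index <- function(x, ...) {
  cat("Eight-SNP-style prognostic index fit\n")
  cat(sprintf("  subjects: %d (%d with defined index)\n",
              length(x$index), sum(!is.na(x$index))))
  cat(sprintf("  index range: %d-%d, cutoff: %d (%s)\n",
              min(x$index, na.rm = TRUE), max(x$index, na.rm = TRUE),
              x$cutoff, x$cutoff_mode))
  for (ep in names(x$combined)) {
    co <- x$combined[[ep]]
    cat(sprintf("  %s: high vs low risk aHR %.2f (%.2f-%.2f), p = %.3g\n",
                toupper(ep), co$hr, co$ci95[["lower"]], co$ci95[["upper"]],
                co$p))
  }
  invisible(x)
}

#' @export
summary.prognostic_index <- function(object, ...) {
  ids <- names(object$score_map)
  snp_tab <- data.frame(
    snp_id = ids,
    gene = vapply(ids, function(i) object$cohort$panel$snps[[i]]$gene,
                  character(1)),
    model = unname(object$models[ids]),
    maf = vapply(ids, function(i) object$associations$os[[i]]$maf,
                 numeric(1)),
    hwe_p = vapply(ids, function(i) object$associations$os[[i]]$hwe_p,
                   numeric(1)),
    hr_os = vapply(ids, function(i) {
      f <- object$associations$os[[i]]$model_fits[[object$models[[i]]]]
      unname(f$hr[1L])
    }, numeric(1)),
    p_os = vapply(ids, function(i) {
      model_p(object$associations$os[[i]], object$models[[i]])
    }, numeric(1)),
    row.names = NULL)
  out <- list(snps = snp_tab, cutoff = object$cutoff,
              index_table = table(index = object$index, useNA = "ifany"),
              combined = object$combined)
  class(out) <- "summary.prognostic_index"
  out
}

#' @export
print.summary.prognostic_index <- function(x, ...) {
  cat("Per-SNP association (selected model, OS):\n")
  tab <- x$snps
  tab$maf <- round(tab$maf, 3); tab$hwe_p <- round(tab$hwe_p, 3)
  tab$hr_os <- round(tab$hr_os, 2); tab$p_os <- signif(tab$p_os, 2)
  print(tab, row.names = FALSE)
  cat("\nPrognostic index distribution (cutoff ", x$cutoff, "):\n", sep = "")
  print(x$index_table)
  cat("\n")
  for (ep in names(x$combined)) print(x$combined[[ep]])
  invisible(x)
}

#' @describeIn prognostic_index log hazard ratios (high vs low risk) per
#'   endpoint
#' @param object,... method arguments
#' @export
coef.prognostic_index <- function(object, ...) {
  vapply(object$combined, function(co) unname(co$fit$coefficients[1L]),
         numeric(1))
}

#' Predict prognostic index and risk group for new subjects
#'
#' Applies the fitted score map and cutoff to new genotype data.
#'
#' @param object a [prognostic_index()] fit
#' @param newdata a [snp_cohort()] or a data frame with the panel's genotype
#'   columns (defaults to the training cohort)
#' @param ... unused
#' @return data frame with `subject_id` (when available), `index` and
#'   `risk_group`
#' @export
predict.prognostic_index <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$cohort
  subjects <- if (inherits(newdata, "snp_cohort")) newdata$subjects else
    as.data.frame(newdata)
  # normalize genotype strings against the panel before scoring
  for (id in names(object$score_map)) {
    if (is.null(subjects[[id]])) stop_ctx("newdata lacks column ", id)
    subjects[[id]] <- normalize_genotype(subjects[[id]],
                                         object$cohort$panel$snps[[id]])
  }
  idx <- compute_index(subjects, object$score_map)
  data.frame(
    subject_id = subjects$subject_id %||% seq_len(nrow(subjects)),
    index = idx,
    risk_group = ifelse(is.na(idx), NA_character_,
                        ifelse(idx >= object$cutoff, "high", "low")),
    stringsAsFactors = FALSE)
}

#' Kaplan-Meier plot of the risk groups
#'
#' @param x a [prognostic_index()] fit
#' @param endpoint `"os"` or `"dfs"`
#' @param ... passed to [graphics::plot()]
#' @export
plot.prognostic_index <- function(x, endpoint = c("os", "dfs"), ...) {
  endpoint <- match.arg(endpoint)
  co <- x$combined[[endpoint]]
  xmax <- max(vapply(co$curves,
                     function(cv) max(c(0, cv$event_times)), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Months after surgery",
                 ylab = if (endpoint == "os") "Overall survival" else
                   "Disease-free survival", ...)
  cols <- c(low = "navy", high = "firebrick")
  for (g in names(co$curves)) {
    cv <- co$curves[[g]]
    graphics::lines(stats::stepfun(cv$event_times, c(1, cv$survival)),
                    do.points = FALSE, col = cols[[g]], lwd = 2)
  }
  graphics::legend("bottomleft", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s risk (n=%d)", names(co$curves),
                                    co$group_n))
  graphics::mtext(sprintf("aHR %.2f (%.2f-%.2f), log-rank p = %.2g",
                          co$hr, co$ci95[["lower"]], co$ci95[["upper"]],
                          co$logrank$p_value), side = 3, line = 0.2,
                  cex = 0.9)
  invisible(x)
}

#' Univariate survival analysis of the clinical factors
#'
#' For each clinical factor, per-level subject and event counts,
#' Kaplan-Meier 5-year rates and the log-rank p-value across levels
#' (pack-years dichotomized at 40 among ever-smokers).
#'
#' @param cohort a [snp_cohort()]
#' @param endpoint `"os"` or `"dfs"`
#' @param horizon rate horizon in months
#' @return data frame with one row per factor level
#' @export
univariate_analysis <- function(cohort, endpoint = c("os", "dfs"),
                                horizon = 60) {
  endpoint <- match.arg(endpoint)
  ep <- endpoint_data(cohort, endpoint)
  s <- cohort$subjects
  factors <- list(
    age_group = s$age_group, sex = s$sex, smoking = s$smoking,
    pack_years = ifelse(s$smoking == "ever",
                        ifelse(s$pack_years >= 40, ">=40", "<40"), NA),
    histology = s$histology, stage = s$stage)
  rows <- list()
  overall_km <- km_estimate(ep$time, ep$event)
  rows[[1L]] <- data.frame(
    variable = "overall", level = "all", n = length(ep$time),
    events = sum(ep$event),
    event_pct = 100 * mean(ep$event),
    rate = 100 * survival_at(overall_km, horizon),
    logrank_p = NA_real_, stringsAsFactors = FALSE)
  for (v in names(factors)) {
    f <- factors[[v]]
    keep <- !is.na(f)
    lr <- logrank_test(ep$time[keep], ep$event[keep], f[keep])
    for (lvl in sort(unique(f[keep]))) {
      sel <- keep & f == lvl
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lvl, n = sum(sel),
        events = sum(ep$event[sel]),
        event_pct = 100 * mean(ep$event[sel]),
        rate = 100 * survival_at(km_estimate(ep$time[sel], ep$event[sel]),
                                 horizon),
        logrank_p = lr$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
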