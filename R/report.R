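#' Table-rendering conventions
#'
#' Counts are rendered with one-decimal percentages as `"304(39.4)"`;
#' hazard ratios and confidence limits to two decimals; p-values below
#' 0.001 in compact scientific notation (`"8.0x10-5"`), below 0.01 to three
#' decimals, otherwise to two.
#'
#' @param n,pct count and percentage
#' @return character
#' @export
fmt_count_pct <- function(n, pct) sprintf("%d(%.1f)", n, pct)

#' @rdname fmt_count_pct
#' @param hr,lo,hi hazard ratio and 95 percent confidence limits
#' @export
fmt_hr_ci <- function(hr, lo, hi) {
  ifelse(is.na(hr), "NE", sprintf("%.2f (%.2f-%.2f)", hr, lo, hi))
}

#' @rdname fmt_count_pct
#' @param p p-value
#' @export
fmt_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NE")
    if (x >= 0.01) return(sprintf("%.2f", x))
    if (x >= 0.001) return(sprintf("%.3f", x))
    e <- floor(log10(x))
    m <- x / 10^e
    if (round(m, 1) >= 10) { m <- m / 10; e <- e + 1 }
    sprintf("%.1fx10%d", m, e)
  }, character(1))
}

# Table-2-layout data frame for one endpoint
per_snp_table <- function(associations) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (a in associations) {
    lv <- names(a$percent)
    counts <- c(a$counts$n_wild_hom, a$counts$n_het, a$counts$n_var_hom)
    add(row = sprintf("%s %s", a$gene, a$snp_id), n = "", events = "",
        rate5 = "", hr_ci = "", p = "")
    gf <- a$genotype_fit
    for (i in 1:3) {
      hr_ci <- if (i == 1L) "1.00" else if (is.null(gf)) "NE" else {
        fmt_hr_ci(gf$hr[i - 1L], gf$ci95[i - 1L, "lower"],
                  gf$ci95[i - 1L, "upper"])
      }
      p <- if (i == 1L) "" else if (is.null(gf)) "NE" else
        fmt_p(gf$wald_p[i - 1L])
      ev <- a$events_by_genotype[i]
      add(row = lv[i],
          n = fmt_count_pct(counts[i], a$percent[i]),
          events = if (is.na(ev)) "NE" else
            fmt_count_pct(as.integer(ev), 100 * ev / counts[i]),
          rate5 = if (is.na(a$five_year_rate[i])) "NE" else
            sprintf("%.0f", 100 * a$five_year_rate[i]),
          hr_ci = hr_ci, p = p)
    }
    for (m in c("Dominant", "Recessive", "Additive")) {
      f <- a$model_fits[[tolower(m)]]
      add(row = m, n = "", events = "", rate5 = "",
          hr_ci = if (is.null(f)) "NE" else
            fmt_hr_ci(f$hr[1L], f$ci95[1L, "lower"], f$ci95[1L, "upper"]),
          p = if (is.null(f)) "NE" else fmt_p(f$wald_p[1L]))
    }
  }
  do.call(rbind, rows)
}

# Table-3-layout data frame across both endpoints
combined_table <- function(fit) {
  rows <- list()
  for (g in c("low", "high")) {
    row <- list(risk_group = sprintf("%s risk (%s%d)", tools::toTitleCase(g),
                                     if (g == "low") "<" else ">=",
                                     fit$cutoff))
    for (ep in names(fit$combined)) {
      co <- fit$combined[[ep]]
      row[[paste0(ep, "_n")]] <-
        fmt_count_pct(as.integer(co$group_n[[g]]), co$group_pct[[g]])
      row[[paste0(ep, "_events")]] <-
        fmt_count_pct(as.integer(co$group_events[[g]]),
                      co$group_event_pct[[g]])
      row[[paste0(ep, "_rate5")]] <-
        sprintf("%.0f", 100 * co$five_year_rate[[g]])
      row[[paste0(ep, "_logrank_p")]] <-
        if (g == "low") fmt_p(co$logrank$p_value) else ""
      row[[paste0(ep, "_hr_ci")]] <- if (g == "low") "1.00" else
        fmt_hr_ci(co$hr, co$ci95[["lower"]], co$ci95[["upper"]])
      row[[paste0(ep, "_p")]] <- if (g == "low") "" else fmt_p(co$p)
    }
    rows[[g]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

univariate_table <- function(tab) {
  data.frame(
    variable = tab$variable, level = tab$level, n = tab$n,
    events = fmt_count_pct(tab$events, tab$event_pct),
    rate5 = sprintf("%.0f", tab$rate),
    logrank_p = ifelse(is.na(tab$logrank_p), "", fmt_p(tab$logrank_p)),
    stringsAsFactors = FALSE)
}

km_points_table <- function(combined) {
  rows <- lapply(names(combined$curves), function(g) {
    cv <- combined$curves[[g]]
    data.frame(group = g, time = cv$event_times, survival = cv$survival,
               at_risk = cv$at_risk, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the analysis report tables
#'
#' Writes delimited-text tables mirroring the standard layout of a SNP
#' prognostic study: a univariate clinical table per endpoint, a per-SNP
#' association table per endpoint (genotype rows plus the three collapsed
#' genetic models), the combined risk-group table, per-subject indices, and
#' Kaplan-Meier curve points (time, survival, at-risk) per risk group.
#' Rounding is applied only here; all model objects keep full precision.
#'
#' @param fit a [prognostic_index()] fit
#' @param out_dir output directory (created if absent)
#' @return character vector of the files written, invisibly
#' @export
write_report_tables <- function(fit, out_dir) {
  stopifnot(inherits(fit, "prognostic_index"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_ctx("cannot create output directory ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop_ctx("output directory not writable: ", out_dir)
  }
  files <- character(0)
  put <- function(df, name, sep = "\t") {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (ep in c("os", "dfs")) {
    put(univariate_table(univariate_analysis(fit$cohort, ep)),
        sprintf("univariate_%s.tsv", ep))
    put(per_snp_table(fit$associations[[ep]]),
        sprintf("per_snp_%s.tsv", ep))
    put(km_points_table(fit$combined[[ep]]), sprintf("km_%s.csv", ep),
        sep = ",")
  }
  put(combined_table(fit), "combined.tsv")
  put(data.frame(subject_id = fit$cohort$subjects$subject_id,
                 index = fit$index, risk_group = fit$risk_group,
                 stringsAsFactors = FALSE), "index.tsv")
  invisible(files)
}
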