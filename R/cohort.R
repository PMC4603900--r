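#' Normalize genotype calls to canonical wild-first strings
#'
#' A genotype is an unordered allele pair; the canonical representation puts
#' the wild allele first (so `"GA"` and `"AG"` for an A>G SNP are the same
#' heterozygote, written wild-first). Unknown allele letters are an error.
#'
#' @param calls character vector of two-letter genotype strings (or `NA`)
#' @param spec the [snp_spec()] declaring the allele set
#' @return character vector of canonical genotype strings
#' @export
normalize_genotype <- function(calls, spec) {
  calls <- toupper(as.character(calls))
  out <- rep(NA_character_, length(calls))
  ok <- !is.na(calls)
  if (!any(ok)) return(out)
  lv <- genotype_levels(spec)
  het_rev <- paste0(spec$variant_allele, spec$wild_allele)
  x <- calls[ok]
  bad <- nchar(x) != 2L |
    !(substr(x, 1, 1) %in% c(spec$wild_allele, spec$variant_allele)) |
    !(substr(x, 2, 2) %in% c(spec$wild_allele, spec$variant_allele))
  if (any(bad)) {
    rows <- which(ok)[bad]
    stop_ctx("invalid genotype call(s) in column ", spec$snp_id,
             " (alleles ", spec$wild_allele, "/", spec$variant_allele,
             ") at row(s) ", paste(utils::head(rows, 5L), collapse = ", "),
             ": ", paste(unique(utils::head(x[bad], 5L)), collapse = ", "))
  }
  x[x == het_rev] <- lv[2L]
  out[ok] <- x
  out
}

cohort_clinical_cols <- c("subject_id", "age_group", "sex", "smoking",
                          "pack_years", "histology", "stage",
                          "adjuvant_chemo", "os_time", "os_event",
                          "dfs_time", "dfs_event")

#' Construct a validated cohort
#'
#' A cohort couples a subject table (clinical covariates, OS and DFS times
#' and event indicators, one genotype column per panel SNP) with its panel
#' specification. Validation enforces: unique subject ids; strictly positive
#' times; 0/1 event flags; `dfs_time <= os_time`; death implies a DFS event;
#' genotype calls drawn from each SNP's allele set (heterozygotes are
#' normalized to the canonical wild-first order); covariate levels from the
#' fixed level sets.
#'
#' @param subjects data frame with the clinical columns
#'   (`subject_id, age_group, sex, smoking, pack_years, histology, stage,
#'   adjuvant_chemo, os_time, os_event, dfs_time, dfs_event`) and one column
#'   per panel SNP id
#' @param panel a [panel_spec()]
#' @return object of class `snp_cohort` with elements `subjects` and `panel`
#' @export
snp_cohort <- function(subjects, panel) {
  stopifnot(is.data.frame(subjects), inherits(panel, "panel_spec"))
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_clinical_cols, names(subjects))
  if (length(miss)) {
    stop_ctx("subject table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ids <- names(panel$snps)
  miss <- setdiff(ids, names(subjects))
  if (length(miss)) {
    stop_ctx("subject table lacks genotype column(s): ",
             paste(miss, collapse = ", "))
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop_ctx("duplicate subject_id")
  }
  for (v in c("os_time", "dfs_time")) {
    x <- as.numeric(subjects[[v]])
    if (anyNA(x) || any(x <= 0)) {
      bad <- which(is.na(x) | x <= 0)[1L]
      stop_ctx("non-positive or missing ", v, " at row ", bad)
    }
    subjects[[v]] <- x
  }
  for (v in c("os_event", "dfs_event")) {
    x <- as.numeric(subjects[[v]])
    if (anyNA(x) || !is_binary(x)) {
      stop_ctx("event flag ", v, " must be 0/1")
    }
    subjects[[v]] <- x
  }
  bad <- which(subjects$dfs_time > subjects$os_time)
  if (length(bad)) {
    stop_ctx("dfs_time > os_time at row ", bad[1L])
  }
  bad <- which(subjects$os_event == 1 & subjects$dfs_event == 0)
  if (length(bad)) {
    stop_ctx("os_event = 1 but dfs_event = 0 at row ", bad[1L])
  }
  lv <- covariate_levels()
  for (v in names(lv)) {
    x <- as.character(subjects[[v]])
    bad <- which(!is.na(x) & !x %in% lv[[v]])
    if (length(bad)) {
      stop_ctx("invalid level '", x[bad[1L]], "' for ", v, " at row ",
               bad[1L])
    }
    subjects[[v]] <- x
  }
  for (id in ids) {
    subjects[[id]] <- normalize_genotype(subjects[[id]], panel$snps[[id]])
  }
  subjects$pack_years <- as.numeric(subjects$pack_years)
  if (any(!is.na(subjects$pack_years) & subjects$pack_years < 0)) {
    stop_ctx("negative pack_years")
  }
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, panel = panel), class = "snp_cohort")
}

#' Read a cohort table from delimited text
#'
#' The table must have a header row with the clinical columns and one
#' two-letter genotype column per panel SNP. The field separator is taken
#' from the file extension (`.csv` comma, otherwise tab). Missing genotypes
#' are given by `missing_token`.
#'
#' @param path file path
#' @param panel a [panel_spec()]
#' @param missing_token string marking a missing genotype (default `"NA"`)
#' @return a validated [snp_cohort()]
#' @export
read_cohort <- function(path, panel, missing_token = "NA") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = missing_token,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  snp_cohort(raw, panel)
}

#' Write a cohort table as tab-delimited text
#'
#' Inverse of [read_cohort()]: a write/read round trip reproduces times and
#' events exactly and genotypes canonically.
#'
#' @param cohort a [snp_cohort()]
#' @param path output file path
#' @param missing_token string used for missing genotypes
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path, missing_token = "NA") {
  stopifnot(inherits(cohort, "snp_cohort"))
  df <- cohort$subjects
  for (id in names(cohort$panel$snps)) {
    df[[id]][is.na(df[[id]])] <- missing_token
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
print.snp_cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  cat("snp_cohort:", n, "subjects,", length(x$panel$snps), "SNPs\n")
  cat(sprintf("  deaths: %d (%.1f%%), DFS events: %d (%.1f%%)\n",
              sum(x$subjects$os_event), 100 * mean(x$subjects$os_event),
              sum(x$subjects$dfs_event), 100 * mean(x$subjects$dfs_event)))
  invisible(x)
}

#' Endpoint accessor: observation times and event flags
#'
#' @param cohort a [snp_cohort()]
#' @param endpoint `"os"` (overall survival) or `"dfs"` (disease-free
#'   survival)
#' @return list with numeric `time` and 0/1 `event`
#' @export
endpoint_data <- function(cohort, endpoint = c("os", "dfs")) {
  endpoint <- match.arg(endpoint)
  s <- cohort$subjects
  if (endpoint == "os") {
    list(time = s$os_time, event = s$os_event)
  } else {
    list(time = s$dfs_time, event = s$dfs_event)
  }
}
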