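`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed from a master seed and a label
#'
#' Each random component of the cohort generator draws under its own seed,
#' derived from the master seed and a component label. Because the substream
#' depends only on (seed, label), adding a SNP to the panel does not perturb
#' the covariate or survival draws.
#'
#' @param seed integer master seed
#' @param label character label of the component (e.g. "covariates",
#'   "genotype:rs967591")
#' @return an integer seed in [0, 2^31 - 2]
#' @keywords internal
substream_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

stop_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

is_binary <- function(x) all(x %in% c(0, 1))

#' Reference levels used when expanding covariates to model indicators
#'
#' @keywords internal
covariate_levels <- function() {
  list(
    age_group      = c("<=64", ">64"),
    sex            = c("female", "male"),
    smoking        = c("never", "ever"),
    histology      = c("SCC", "AC", "LCC"),
    stage          = c("I", "II-IIIA"),
    adjuvant_chemo = c("no", "yes")
  )
}

#' Expand clinical covariates to a reference-coded design matrix
#'
#' Reference levels are fixed: age <=64 years, female, never-smoker, squamous
#' cell carcinoma, stage I, no adjuvant chemotherapy. Histology expands to two
#' indicator columns (AC, LCC vs the SCC reference); all other covariates to
#' one.
#'
#' @param subjects data frame with the clinical columns of a cohort
#' @param covariate_set character vector of covariate names (a subset of
#'   `names(covariate_levels())`), or a preset name accepted by
#'   [covariate_preset()]
#' @return numeric matrix with one row per subject
#' @export
build_design <- function(subjects, covariate_set) {
  if (length(covariate_set) == 1L &&
      covariate_set %in% c("table2", "methods")) {
    covariate_set <- covariate_preset(covariate_set)
  }
  lv <- covariate_levels()
  cols <- list()
  for (v in covariate_set) {
    if (!v %in% names(lv)) {
      stop_ctx("unknown covariate '", v, "'")
    }
    x <- as.character(subjects[[v]])
    bad <- !is.na(x) & !x %in% lv[[v]]
    if (any(bad)) {
      stop_ctx("covariate '", v, "' has invalid level(s): ",
               paste(unique(x[bad]), collapse = ", "))
    }
    if (v == "histology") {
      cols$histology_AC <- as.numeric(x == "AC")
      cols$histology_LCC <- as.numeric(x == "LCC")
    } else {
      nm <- switch(v,
        age_group = "age_gt64", sex = "male", smoking = "ever_smoker",
        stage = "stage_II_IIIA", adjuvant_chemo = "adjuvant")
      cols[[nm]] <- as.numeric(x == lv[[v]][2L])
      cols[[nm]][is.na(x)] <- NA_real_
    }
  }
  do.call(cbind, cols)
}

#' Adjustment covariate presets
#'
#' `"table2"` is the five-covariate set (age group, sex, smoking status,
#' histology, pathologic stage) used for the per-SNP and combined
#' adjusted models; `"methods"` additionally includes adjuvant chemotherapy.
#'
#' @param preset `"table2"` or `"methods"`
#' @return character vector of covariate names
#' @export
covariate_preset <- function(preset = c("table2", "methods")) {
  preset <- match.arg(preset)
  base <- c("age_group", "sex", "smoking", "histology", "stage")
  if (preset == "methods") c(base, "adjuvant_chemo") else base
}
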