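#' Declare one biallelic SNP of a prognostic panel
#'
#' A SNP is described by its two alleles (wild-type and variant), an optional
#' genetic model (how the three genotypes collapse to a numeric code) and an
#' optional risk orientation. When the model or orientation is left unset it
#' can be selected from the data by [select_genetic_model()] /
#' [build_score_map()].
#'
#' @param snp_id SNP identifier, e.g. `"rs967591"`
#' @param gene gene label, e.g. `"CD3EAP"`
#' @param wild_allele,variant_allele single-base alleles; must differ
#' @param genetic_model `"additive"`, `"dominant"`, `"recessive"` or `NA`
#'   (select from data)
#' @param risk_direction `"variant"`, `"wild"` or `NA` (infer from the fitted
#'   coefficient sign). Must be set whenever `genetic_model` is set.
#' @return an object of class `snp_spec`
#' @export
snp_spec <- function(snp_id, gene, wild_allele, variant_allele,
                     genetic_model = NA_character_,
                     risk_direction = NA_character_) {
  stopifnot(is.character(snp_id), nchar(snp_id) > 0)
  wild_allele <- toupper(wild_allele)
  variant_allele <- toupper(variant_allele)
  if (nchar(wild_allele) != 1L || nchar(variant_allele) != 1L) {
    stop_ctx("alleles must be single bases (SNP ", snp_id, ")")
  }
  if (wild_allele == variant_allele) {
    stop_ctx("wild and variant allele must differ (SNP ", snp_id, ")")
  }
  if (!is.na(genetic_model)) {
    genetic_model <- match.arg(genetic_model,
                               c("additive", "dominant", "recessive"))
    if (is.na(risk_direction)) {
      stop_ctx("risk_direction must be set when genetic_model is set (SNP ",
               snp_id, ")")
    }
  }
  if (!is.na(risk_direction)) {
    risk_direction <- match.arg(risk_direction, c("variant", "wild"))
  }
  structure(
    list(snp_id = snp_id, gene = gene,
         wild_allele = wild_allele, variant_allele = variant_allele,
         genetic_model = genetic_model, risk_direction = risk_direction),
    class = "snp_spec")
}

#' The three canonical genotype strings of a SNP
#'
#' Order: wild homozygote, heterozygote (wild allele first), variant
#' homozygote.
#'
#' @param spec a [snp_spec()]
#' @return character vector of length 3
#' @export
genotype_levels <- function(spec) {
  w <- spec$wild_allele; v <- spec$variant_allele
  c(paste0(w, w), paste0(w, v), paste0(v, v))
}

#' Assemble a SNP panel with its adjustment covariates
#'
#' @param snps list of [snp_spec()] objects with unique ids
#' @param covariate_set preset name (`"table2"`, `"methods"`) or explicit
#'   character vector of covariate names used for model adjustment
#' @return object of class `panel_spec`
#' @export
panel_spec <- function(snps, covariate_set = "table2") {
  stopifnot(is.list(snps), length(snps) >= 1)
  ok <- vapply(snps, inherits, logical(1), "snp_spec")
  if (!all(ok)) stop_ctx("all panel entries must be snp_spec objects")
  ids <- vapply(snps, `[[`, character(1), "snp_id")
  if (anyDuplicated(ids)) stop_ctx("duplicate snp_id in panel")
  names(snps) <- ids
  if (length(covariate_set) == 1L &&
      covariate_set %in% c("table2", "methods")) {
    covariate_set <- covariate_preset(covariate_set)
  }
  structure(list(snps = snps, covariate_set = covariate_set),
            class = "panel_spec")
}

#' The eight-SNP early-stage NSCLC prognostic panel
#'
#' The panel of eight germline polymorphisms associated with survival after
#' surgical resection of early-stage non-small cell lung cancer, with the
#' genetic model reported for each SNP (additive for C3 rs2287845, HOMER2
#' rs1256428 and GNB2L1 rs3756585; dominant for AKT1 rs3803300; recessive for
#' CD3EAP rs967591, TNFRSF10B rs1047266, ADAMTSL3 rs11259927 and CD3D
#' rs3181259). The variant allele is the risk allele for all eight.
#'
#' @param covariate_set adjustment preset, default `"table2"` (age group,
#'   sex, smoking, histology, stage)
#' @return a [panel_spec()]
#' @export
default_panel <- function(covariate_set = "table2") {
  panel_spec(list(
    snp_spec("rs967591",   "CD3EAP",    "G", "A", "recessive", "variant"),
    snp_spec("rs1047266",  "TNFRSF10B", "C", "T", "recessive", "variant"),
    snp_spec("rs3803300",  "AKT1",      "A", "G", "dominant",  "variant"),
    snp_spec("rs2287845",  "C3",        "T", "C", "additive",  "variant"),
    snp_spec("rs1256428",  "HOMER2",    "A", "G", "additive",  "variant"),
    snp_spec("rs3756585",  "GNB2L1",    "T", "G", "additive",  "variant"),
    snp_spec("rs11259927", "ADAMTSL3",  "C", "T", "recessive", "variant"),
    snp_spec("rs3181259",  "CD3D",      "T", "C", "recessive", "variant")
  ), covariate_set = covariate_set)
}

#' Read / write a panel configuration file
#'
#' The panel is stored as YAML with one block per SNP (`id`, `gene`,
#' `alleles` as `"W>V"`, optional `model` and `risk`) plus a `covariate_set`
#' entry (preset name or list of covariate names).
#'
#' @param path file path
#' @return `read_panel()` returns a [panel_spec()]; `write_panel()` returns
#'   `path` invisibly
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$snps)) stop_ctx("panel config has no 'snps' entry")
  snps <- lapply(cfg$snps, function(s) {
    al <- strsplit(s$alleles, ">", fixed = TRUE)[[1L]]
    if (length(al) != 2L) {
      stop_ctx("alleles must be given as 'W>V' (SNP ", s$id, ")")
    }
    snp_spec(s$id, s$gene %||% NA_character_, al[1L], al[2L],
             s$model %||% NA_character_, s$risk %||% NA_character_)
  })
  panel_spec(snps, covariate_set = unlist(cfg$covariate_set) %||% "table2")
}

#' @rdname read_panel
#' @param panel a [panel_spec()]
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_spec"))
  cfg <- list(
    covariate_set = panel$covariate_set,
    snps = lapply(unname(panel$snps), function(s) {
      out <- list(id = s$snp_id, gene = s$gene,
                  alleles = paste0(s$wild_allele, ">", s$variant_allele))
      if (!is.na(s$genetic_model)) out$model <- s$genetic_model
      if (!is.na(s$risk_direction)) out$risk <- s$risk_direction
      out
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("SNP panel:", length(x$snps), "SNPs\n")
  for (s in x$snps) {
    cat(sprintf("  %-11s %-10s %s>%s  model=%s risk=%s\n",
                s$snp_id, s$gene, s$wild_allele, s$variant_allele,
                s$genetic_model, s$risk_direction))
  }
  cat("adjustment covariates:", paste(x$covariate_set, collapse = ", "), "\n")
  invisible(x)
}
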