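# minimal snp_association stand-ins for exercising the model-selection rule
fake_fit <- function(p, beta = 0.5) {
  structure(list(coefficients = c(m = beta), wald_p = c(m = p),
                 converged = TRUE), class = "cox_fit")
}
fake_assoc <- function(p_dom = NULL, p_rec = NULL, p_add = NULL,
                       beta = 0.5) {
  mk <- function(p) if (is.null(p)) NULL else fake_fit(p, beta)
  structure(list(snp_id = "rsF",
                 model_fits = list(dominant = mk(p_dom),
                                   recessive = mk(p_rec),
                                   additive = mk(p_add))),
            class = "snp_association")
}

test_that("genetic-model selection takes the smallest OS Wald p", {
  # C3-like p-values: additive wins outright
  expect_equal(select_genetic_model(
    fake_assoc(p_dom = 0.02, p_rec = 0.007, p_add = 0.004)), "additive")
  # GNB2L1-like tie between dominant and additive: preference order breaks it
  expect_equal(select_genetic_model(
    fake_assoc(p_dom = 0.004, p_rec = 0.02, p_add = 0.004)), "additive")
  # recessive vs dominant tie resolves to recessive
  expect_equal(select_genetic_model(
    fake_assoc(p_dom = 0.01, p_rec = 0.01, p_add = 0.5)), "recessive")
  # single converged model
  expect_equal(select_genetic_model(fake_assoc(p_dom = 0.3)), "dominant")
  expect_error(select_genetic_model(fake_assoc()), "no genetic model")
})

test_that("score maps assign 1/2/3 by model and risk orientation", {
  sm <- build_score_map(default_panel())
  # recessive, variant risk: only the variant homozygote scores 3
  expect_equal(unname(sm$rs967591[c("GG", "GA", "AA")]), c(1, 1, 3))
  # additive, variant risk: 1/2/3 by risk-allele count
  expect_equal(unname(sm$rs2287845[c("TT", "TC", "CC")]), c(1, 2, 3))
  # dominant, variant risk: carriers score 3
  expect_equal(unname(sm$rs3803300[c("AA", "AG", "GG")]), c(1, 3, 3))
  # protective variant: wild allele carries the risk under a dominant model
  panel <- panel_spec(list(
    snp_spec("rsP", "P", "A", "G", "dominant", "wild")))
  smp <- build_score_map(panel)
  expect_equal(unname(smp$rsP[c("AA", "AG", "GG")]), c(3, 3, 1))
})

test_that("orientation falls back to the fitted coefficient sign", {
  panel <- panel_spec(list(snp_spec("rsF", "F", "A", "G")))
  protective <- list(rsF = fake_assoc(p_add = 0.01, beta = -0.4))
  sm <- build_score_map(panel, protective)
  expect_equal(unname(sm$rsF[c("AA", "AG", "GG")]), c(3, 2, 1))
  # zero coefficient with unset orientation is undecidable
  null_assoc <- list(rsF = fake_assoc(p_add = 0.01, beta = 0))
  expect_error(build_score_map(panel, null_assoc), "undecidable")
})

test_that("index enumeration over all 6561 genotype combinations is bounded", {
  panel <- default_panel()
  sm <- build_score_map(panel)
  ids <- names(sm)
  combos <- expand.grid(lapply(ids, function(id)
    genotype_levels(panel$snps[[id]])), stringsAsFactors = FALSE)
  names(combos) <- ids
  expect_equal(nrow(combos), 3^8)
  idx <- compute_index(combos, sm)
  # independent oracle: sum the mapped scores directly
  oracle <- rowSums(mapply(function(id) sm[[id]][combos[[id]]], ids))
  expect_equal(idx, as.integer(oracle))
  expect_equal(min(idx), 8L)   # all-low-risk combination
  expect_equal(max(idx), 24L)  # 3 additive SNPs at 3 plus 5 two-level at 3
  expect_true(all(idx >= 8L & idx <= 24L))
})

test_that("index is monotone in per-SNP score and undefined under missingness", {
  panel <- default_panel()
  sm <- build_score_map(panel)
  sub <- generate_cohort(default_generator_config(n = 50,
                                                  seed = 2))$cohort$subjects
  idx <- compute_index(sub, sm)
  set.seed(12)
  for (k in 1:20) {
    i <- sample(nrow(sub), 1)
    id <- sample(names(sm), 1)
    if (is.na(sub[[id]][i])) next
    higher <- names(sm[[id]])[sm[[id]] >= sm[[id]][[sub[[id]][i]]]]
    sub2 <- sub
    sub2[[id]][i] <- sample(higher, 1)
    idx2 <- compute_index(sub2, sm)
    if (!is.na(idx[i])) expect_gte(idx2[i], idx[i])
  }
  sub$rs967591[1] <- NA
  expect_true(is.na(compute_index(sub, sm)[1]))
})

test_that("approximate-tertile cutoff minimizes distance to the target", {
  # engineered distribution: 39.4% at or above 15, 25% at or above 16
  idx <- c(rep(14L, 606), rep(15L, 144), rep(16L, 250))
  expect_equal(choose_cutoff(idx), 15L)
  # degenerate: all indices equal -> empty high group preferred
  expect_equal(choose_cutoff(rep(11L, 40)), 12L)
  # exhaustive-scan oracle on a uniform distribution
  idx <- rep(8:20, each = 10)
  cand <- 8:21
  frac <- vapply(cand, function(c) mean(idx >= c), numeric(1))
  expect_equal(choose_cutoff(idx), cand[which.min(abs(frac - 1 / 3))])
  expect_error(choose_cutoff(NA_integer_), "no defined")
})

test_that("combined risk-group analysis keeps exclusion bookkeeping", {
  sim <- generate_cohort(default_generator_config(n = 814, seed = 5))
  fit <- prognostic_index(sim$cohort)
  n_def <- sum(!is.na(fit$index))
  expect_lt(n_def, 814)  # genotyping failures exclude some subjects
  for (ep in c("os", "dfs")) {
    co <- fit$combined[[ep]]
    expect_equal(unname(sum(co$group_n)), n_def)
    expect_equal(unname(sum(co$group_pct)), 100)
    expect_equal(co$n_excluded, 814 - n_def)
  }
  # classification consistency with the cutoff
  defined <- !is.na(fit$index)
  expect_equal(fit$risk_group[defined] == "high",
               fit$index[defined] >= fit$cutoff)
  # group percentage rendering convention
  expect_equal(fmt_count_pct(468L, 100 * 468 / 772), "468(60.6)")
  expect_equal(fmt_count_pct(304L, 100 * 304 / 772), "304(39.4)")
})

test_that("degenerate single-group classification is rejected", {
  sim <- generate_cohort(default_generator_config(n = 200, seed = 6))
  sm <- build_score_map(sim$cohort$panel)
  expect_error(combined_analysis(sim$cohort, sm, cutoff = 100L, "os"),
               "one risk group")
})

test_that("model selection from data produces a full fit", {
  sim <- generate_cohort(default_generator_config(n = 814, seed = 8))
  # strip the panel's fixed models so every SNP goes through selection
  open_snps <- lapply(sim$cohort$panel$snps, function(s)
    snp_spec(s$snp_id, s$gene, s$wild_allele, s$variant_allele))
  open_panel <- panel_spec(open_snps, covariate_set = "table2")
  cohort <- snp_cohort(sim$cohort$subjects, open_panel)
  fit <- prognostic_index(cohort)
  expect_true(all(fit$models %in% c("additive", "dominant", "recessive")))
  expect_length(fit$models, 8)
  expect_true(fit$cutoff >= 8 && fit$cutoff <= 25)
  expect_s3_class(fit$combined$os$fit, "cox_fit")
})

test_that("predict applies the fitted score map and cutoff to new data", {
  sim <- generate_cohort(default_generator_config(n = 400, seed = 9))
  fit <- prognostic_index(sim$cohort)
  pred <- predict(fit)
  expect_equal(pred$index, fit$index)
  expect_equal(pred$risk_group, fit$risk_group)
  new <- generate_cohort(default_generator_config(n = 50, seed = 10))$cohort
  pred2 <- predict(fit, new)
  expect_equal(nrow(pred2), 50)
  ok <- !is.na(pred2$index)
  expect_equal(pred2$risk_group[ok] == "high",
               pred2$index[ok] >= fit$cutoff)
  # coefficients are the high-vs-low log hazard ratios
  expect_equal(unname(coef(fit)["os"]),
               unname(fit$combined$os$fit$coefficients[1]))
})

test_that("nonzero generated effects yield a high-risk HR above 1", {
  above <- logical(10)
  for (i in 1:10) {
    sim <- generate_cohort(default_generator_config(n = 2000,
                                                    seed = 100 + i))
    fit <- prognostic_index(sim$cohort)
    above[i] <- fit$combined$os$hr > 1
  }
  expect_true(all(above))
})
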