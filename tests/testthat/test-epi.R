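test_that("exact test reproduces the published feeding-code association", {
  # 17 of 267 cases vs 4 of 267 controls carrying the feeding-difficulty
  # diagnosis code
  res <- fisher_exact(two_by_two(17, 4, 250, 263))
  expect_equal(round(res$or_cmle, 2), 4.46)
  expect_equal(round(res$ci_low, 2), 1.43)
  expect_equal(round(res$ci_high, 2), 18.46)
  expect_equal(res$p, 6.15e-3, tolerance = 1e-2)
})

test_that("symmetric tables give unit odds ratio and p of one", {
  res <- fisher_exact(two_by_two(5, 5, 12, 12))
  expect_equal(res$or_cmle, 1, tolerance = 1e-6)
  expect_equal(res$p, 1)
  expect_lt(res$ci_low, 1)
  expect_gt(res$ci_high, 1)
})

test_that("exact p equals brute-force enumeration over fixed margins", {
  res <- fisher_exact(two_by_two(3, 1, 7, 9))
  expect_equal(res$p, brute_fisher_p(3, 1, 7, 9), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (min(a + b, c_ + d, a + c_, b + d) == 0) next
    expect_equal(fisher_exact(two_by_two(a, b, c_, d))$p,
                 brute_fisher_p(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("conditional-MLE odds ratio is monotone in the exposed-case cell", {
  # shift mass along the diagonal, margins fixed
  ors <- sapply(2:8, function(a) {
    fisher_exact(two_by_two(a, 10 - a, 10 - a, a))$or_cmle
  })
  expect_false(is.unsorted(ors, strictly = TRUE))
})

test_that("CI endpoints invert the one-sided conditional tests at 2.5%", {
  res <- fisher_exact(two_by_two(17, 4, 250, 263))
  expect_equal(nchg_tail(17, 4, 250, 263, res$ci_low, upper = TRUE),
               0.025, tolerance = 5e-3)
  expect_equal(nchg_tail(17, 4, 250, 263, res$ci_high, upper = FALSE),
               0.025, tolerance = 5e-3)
})

test_that("degenerate and zero-cell tables are handled", {
  expect_error(fisher_exact(two_by_two(0, 0, 5, 5)), "margin")
  res <- fisher_exact(two_by_two(0, 4, 10, 6))
  expect_true(res$unbounded)
  expect_equal(res$ci_low, 0)
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
})

test_that("code tabulation counts carriers by group", {
  s <- data.frame(case = c(1L, 1L, 0L, 0L, 1L),
                  icd_code = c("P92.5", NA, "P92.5", NA, "Q40.0"))
  tab <- make_code_table(s, "P92.5")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 2, 1))
})

test_that("metabolite ratios flag non-positive denominators", {
  expect_equal(metabolite_ratio(c(10, 4), c(5, 4)), c(2, 1))
  expect_warning(r <- metabolite_ratio(c(1, 2, 3), c(2, 0, -1)),
                 "non-positive")
  expect_equal(r, c(0.5, NA, NA))
  # transformed ratio is invariant to common per-sample scaling
  set.seed(8)
  num <- rlnorm(50); den <- rlnorm(50); f <- rlnorm(50)
  expect_equal(
    inverse_normal_transform(metabolite_ratio(num * f, den * f)),
    inverse_normal_transform(metabolite_ratio(num, den)),
    tolerance = 1e-12)
})

test_that("dosage model reduces to the simple slope without covariates", {
  set.seed(9)
  n <- 60
  s <- data.frame(sample_id = sprintf("S%03d", 1:n),
                  case = rep(1L, n), sex = "M", year_of_birth = 2010L,
                  parity = 2L, gestational_age = 40,
                  stringsAsFactors = FALSE)
  dos <- rbinom(n, 2, 0.4)
  y <- 0.5 * dos + rnorm(n)
  r <- snp_trait_assoc(dos, y, s)
  ref <- summary(lm(y ~ dos))$coefficients
  expect_equal(r$beta, ref["dos", "Estimate"], tolerance = 1e-10)
  expect_equal(r$se, ref["dos", "Std. Error"], tolerance = 1e-10)
  expect_error(snp_trait_assoc(rep(1L, n), y, s), "monomorphic")
})

test_that("dosage model recovers a known per-allele effect", {
  cfg <- sim_config(seed = 51, genotype_beta_precursor = 0.35)
  coh <- simulate_cohort(cfg)
  set.seed(52)
  conc <- simulate_concentrations(coh$samples, small_panel(), cfg,
                                  bottle = coh$truth$bottle)
  y <- inverse_normal_transform(conc[, "PC(38:3)"])
  r <- snp_trait_assoc(coh$samples$rs174547, y, coh$samples,
                       snp = "rs174547", trait_name = "PC(38:3)")
  # the injected effect is 0.35 biological SDs; on the normal-score scale
  # it is mildly attenuated by the dosage variance share
  expect_lt(abs(r$beta - 0.35), 3.5 * r$se + 0.05)
  expect_lt(r$p, 1e-3)
})

test_that("permuted dosages give null p-values", {
  cfg <- sim_config(n_pairs = 80, seed = 53)
  coh <- simulate_cohort(cfg)
  set.seed(54)
  conc <- simulate_concentrations(coh$samples, mono_panel(), cfg)
  y <- inverse_normal_transform(conc[, 1])
  ps <- replicate(100, {
    snp_trait_assoc(sample(coh$samples$rs174547), y, coh$samples)$p
  })
  expect_lte(mean(ps < 0.05), 0.12)       # ~5% expected
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("genotype moves precursor and ratio but not disease status", {
  cfg <- sim_config(seed = 55)
  coh <- simulate_cohort(cfg)
  set.seed(56)
  conc <- simulate_concentrations(coh$samples, small_panel(), cfg,
                                  bottle = coh$truth$bottle)
  ratio <- metabolite_ratio(conc[, "PC(38:4)"], conc[, "PC(38:3)"])
  r <- snp_trait_assoc(coh$samples$rs174547,
                       inverse_normal_transform(ratio), coh$samples)
  expect_lt(r$p, 1e-4)
  expect_lt(r$beta, 0)  # allele raises the denominator
  # no dosage-disease association by construction
  p_dis <- summary(glm(case ~ rs174547, binomial,
                       data = coh$samples))$coefficients[2, 4]
  expect_gt(p_dis, 0.001)
})

test_that("era-stratified dosage models run per stratum", {
  cfg <- sim_config(seed = 57)
  coh <- simulate_cohort(cfg)
  set.seed(58)
  conc <- simulate_concentrations(coh$samples, small_panel(), cfg)
  y <- inverse_normal_transform(conc[, "PC(38:3)"])
  r_pre <- snp_trait_assoc(coh$samples$rs174547, y, coh$samples,
                           stratum = "pre_policy")
  r_post <- snp_trait_assoc(coh$samples$rs174547, y, coh$samples,
                            stratum = "post_policy")
  expect_equal(r_pre$n + r_post$n, nrow(coh$samples))
  expect_lt(r_pre$p, 0.05)
  expect_lt(r_post$p, 0.05)
})

test_that("SNP sweep applies the metabolite-count Bonferroni threshold", {
  cfg <- sim_config(n_pairs = 60, seed = 59)
  coh <- simulate_cohort(cfg)
  set.seed(60)
  conc <- simulate_concentrations(coh$samples, small_panel(), cfg)
  sw <- snp_metabolome_scan(coh$samples$rs174547, conc, coh$samples,
                            snp = "rs174547")
  expect_equal(attr(sw, "threshold"), 0.05 / ncol(conc))
  expect_equal(nrow(sw), ncol(conc))
  expect_false(is.unsorted(sw$p))
})

test_that("code-timing model detects lower levels in day-zero coded infants", {
  # day-0 codes preferentially mark bottle-fed newborns, whose affected
  # metabolites are lowered in proportion to age at sampling
  negs <- 0L
  for (i in 1:15) {
    cfg <- sim_config(n_pairs = 150, seed = 600 + i,
                      pre_policy_frac = 1,      # all sampled around day 6
                      feeding_effect_per_day = -0.3,
                      code_prob_bottle_case = 0.5,
                      code_prob_bottle_control = 0.5,
                      code_prob_base = 0.1)
    coh <- simulate_cohort(cfg)
    set.seed(700 + i)
    conc <- simulate_concentrations(coh$samples, mono_panel("PC(38:4)"),
                                    cfg, bottle = coh$truth$bottle)
    y <- inverse_normal_transform(conc[, 1])
    tm <- code_timing_model(y, coh$samples)
    if (tm$beta < 0) negs <- negs + 1L
  }
  expect_gte(negs, 12L)
})

test_that("timing model rejects degenerate and collinear designs", {
  s <- data.frame(sample_id = c("a", "b", "c"), case = c(1L, 1L, 0L),
                  sex = "M", year_of_birth = 2010L, parity = 1L,
                  gestational_age = 40,
                  icd_code = "P92.5", code_day = c(0L, 5L, 6L),
                  stringsAsFactors = FALSE)
  expect_error(code_timing_model(rnorm(3), s), "at least 2")
})
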