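# Synthetic cohort and plate-data generator.
#
# Emulates the matched-pair dried-blood-spot study design: pairs matched on
# sex and day of birth, a screening-policy change that moved the median age
# at sampling from 6 days to 2 days for births from 2009 onwards, a latent
# bottle-feeding exposure whose metabolite effect grows with age at
# sampling, a biallelic variant acting on a precursor phosphatidylcholine
# (and hence on the product/precursor ratio) but not on disease status,
# multiplicative per-plate batch factors, paper blanks and replicated QC
# reference wells. A ground-truth sidecar records every latent quantity so
# recovery and type-I-error tests can score the pipeline.

.DEFAULT_AFFECTED <- c("PC(38:4)", "PC(36:4)", "PC-O(36:4)", "PC(44:1)",
                       "PC(38:3)", "Histidine", "AC(2:0)")

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list.
#' Defaults reproduce the design facts of the emulated study: 267
#' case-control pairs on 8 x 96-well plates, each plate carrying 3 paper
#' blanks, 5 QC2 replicates and one QC1/QC3 well; sampling at a median of
#' 6 days before the 2009 screening-policy change and 2 days afterwards;
#' covariate moments near the published cohort table (87.3% boys,
#' gestational age ~40 +/- 1.5 weeks, parity ~1.7 +/- 0.9, maternal age
#' ~30 +/- 5 years).
#'
#' @param n_pairs Number of matched case-control pairs.
#' @param n_plates,wells_per_plate Plate layout.
#' @param blanks_per_plate,qc2_reps_per_plate Paper blanks and QC2
#'   replicate wells per plate (one QC1 and one QC3 well are always added).
#' @param policy_change_year First birth year of the early-sampling era.
#' @param age_sampling_pre,age_sampling_post Median age at sampling in
#'   days for births before / from `policy_change_year`.
#' @param birth_year_range Two integers, inclusive range of birth years.
#' @param pre_policy_frac Fraction of pairs born before
#'   `policy_change_year` (default 98/267, the emulated cohort's stratum
#'   split; birth dates are uniform within each era).
#' @param sex_male_prob Probability a pair is male.
#' @param ga_mean,ga_sd Gestational age moments (weeks).
#' @param parity_mean,parity_sd Parity moments (live births, >= 1).
#' @param maternal_age_mean,maternal_age_sd Maternal age moments (years).
#' @param bottle_prob_case,bottle_prob_control Probability of the latent
#'   bottle-feeding exposure per group.
#' @param feeding_effect_per_day Effect of bottle-feeding on each affected
#'   metabolite per day of age at sampling, in units of the biological
#'   log-scale SD (negative lowers the metabolite).
#' @param affected_metabolites Names of the metabolites carrying the
#'   feeding effect and sharing the latent positive-correlation factor.
#' @param affected_factor_loading Loading of affected metabolites on a
#'   shared per-sample latent factor (induces their mutual positive
#'   correlation).
#' @param disease_effects Named numeric vector of direct case-vs-control
#'   effects in SD units (default none; used to inject known effects for
#'   recovery tests).
#' @param code_prob_bottle_case,code_prob_bottle_control Probability that
#'   a bottle-fed case/control receives the feeding-difficulty diagnosis
#'   code; non-bottle-fed newborns receive it with `code_prob_base`.
#' @param code_prob_base Baseline probability of the code.
#' @param code_day0_prob Probability a bottle-fed carrier's code is
#'   assigned on the day of birth (day 0) rather than later.
#' @param code_day0_prob_nonbottle Day-0 probability for carriers who are
#'   not bottle-fed (lower: immediate feeding difficulty marks the
#'   bottle-fed), so day-0 codes preferentially tag the latent exposure.
#' @param icd_code The diagnosis code string recorded in the sample sheet.
#' @param genotype_maf Minor-allele frequency of the simulated variant.
#' @param genotype_beta_precursor Per-allele effect (SD units) on the
#'   precursor metabolite.
#' @param genotype_snp,genotype_precursor Variant id (sample-sheet dosage
#'   column name) and the precursor metabolite it acts on.
#' @param plate_factor_sd Log-scale SD of the multiplicative per-plate
#'   batch factor `C_{m,p}` (0 disables batch effects).
#' @param blank_level_frac Paper-blank signal level as a fraction of the
#'   metabolite target value.
#' @param blank_noise_cv,qc_noise_cv Lognormal coefficient of variation of
#'   blank and QC well signals.
#' @param sample_log_sd Biological SD of log concentrations; all effect
#'   sizes above are expressed in units of this SD.
#' @param fail_lod_metabolites Metabolites designed to fail the
#'   limit-of-detection filter (their concentrations are pushed below the
#'   blank level).
#' @param fail_cv_metabolites Metabolites designed to fail the QC2
#'   coefficient-of-variation filter (their QC noise is `fail_cv_value`).
#' @param fail_cv_value QC2 CV used for designed CV failures.
#' @param seed Integer seed; every generator function seeds from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 267, n_plates = 8, wells_per_plate = 96,
                       blanks_per_plate = 3, qc2_reps_per_plate = 5,
                       policy_change_year = 2009,
                       age_sampling_pre = 6, age_sampling_post = 2,
                       birth_year_range = c(1997, 2014),
                       pre_policy_frac = 98 / 267,
                       sex_male_prob = 0.873,
                       ga_mean = 39.9, ga_sd = 1.5,
                       parity_mean = 1.7, parity_sd = 0.9,
                       maternal_age_mean = 30, maternal_age_sd = 5,
                       bottle_prob_case = 0.5, bottle_prob_control = 0.2,
                       feeding_effect_per_day = -0.4,
                       affected_metabolites = .DEFAULT_AFFECTED,
                       affected_factor_loading = 0.5,
                       disease_effects = numeric(0),
                       code_prob_bottle_case = 0.126,
                       code_prob_bottle_control = 0.067,
                       code_prob_base = 0.002,
                       code_day0_prob = 0.5,
                       code_day0_prob_nonbottle = 0.15,
                       icd_code = "P92.5",
                       genotype_maf = 0.3,
                       genotype_beta_precursor = 0.35,
                       genotype_snp = "rs174547",
                       genotype_precursor = "PC(38:3)",
                       plate_factor_sd = 0.15,
                       blank_level_frac = 0.02,
                       blank_noise_cv = 0.2, qc_noise_cv = 0.05,
                       sample_log_sd = 0.35,
                       fail_lod_metabolites = character(0),
                       fail_cv_metabolites = character(0),
                       fail_cv_value = 0.4,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(sex_male_prob, bottle_prob_case, bottle_prob_control,
             code_prob_bottle_case, code_prob_bottle_control,
             code_prob_base, code_day0_prob, code_day0_prob_nonbottle,
             genotype_maf, pre_policy_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(n_pairs >= 1, n_plates >= 1, wells_per_plate >= 12,
            blanks_per_plate >= 1, qc2_reps_per_plate >= 1,
            plate_factor_sd >= 0, sample_log_sd > 0,
            length(birth_year_range) == 2,
            birth_year_range[1] <= birth_year_range[2])
  non_sample <- blanks_per_plate + qc2_reps_per_plate + 2L # + QC1 + QC3
  capacity <- n_plates * (wells_per_plate - non_sample)
  if (2L * n_pairs > capacity) {
    stop("infeasible layout: ", 2L * n_pairs, " samples exceed the ",
         capacity, " sample wells available on ", n_plates, " plates")
  }
  if (abs(affected_factor_loading) > 1) {
    stop("affected_factor_loading must lie in [-1, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a matched case-control cohort
#'
#' Draws `n_pairs` case-control pairs matched on sex and exact day of
#' birth. Per-pair: sex and birth date; per-newborn: gestational age,
#' parity, maternal age, age at dried-blood-spot sampling (era median plus
#' small integer jitter), a latent bottle-feeding exposure, an optional
#' feeding-difficulty diagnosis code (more likely for bottle-fed newborns,
#' assigned on day 0 or later), and an additive genotype dosage drawn
#' independently of disease status.
#'
#' @param config A [sim_config()].
#' @return List with `samples` (the sample sheet: one row per newborn,
#'   columns `sample_id`, `pair_id`, `case`, `sex`, `birth_date`,
#'   `year_of_birth`, `gestational_age`, `parity`, `maternal_age`,
#'   `cesarean`, `age_days`, `icd_code`, `code_day` and one dosage column
#'   named after the variant) and `truth` (latent per-sample
#'   bottle-feeding status and the configured effect sizes).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  pair_id <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_male_prob, "M", "F")
  # era first (published stratum proportions), then uniform within era
  cut_year <- max(min(config$policy_change_year,
                      config$birth_year_range[2] + 1L),
                  config$birth_year_range[1])
  d0 <- as.Date(sprintf("%d-01-01", config$birth_year_range[1]))
  dcut <- as.Date(sprintf("%d-01-01", cut_year))
  d1 <- as.Date(sprintf("%d-12-31", config$birth_year_range[2]))
  pre_days <- as.integer(dcut - d0)          # days strictly before cut
  post_days <- as.integer(d1 - dcut) + 1L
  era_pre <- stats::runif(n) < config$pre_policy_frac
  if (pre_days <= 0L) era_pre[] <- FALSE
  if (post_days <= 0L) era_pre[] <- TRUE
  off <- ifelse(era_pre,
                sample.int(max(pre_days, 1L), n, replace = TRUE) - 1L,
                pre_days + sample.int(max(post_days, 1L), n,
                                      replace = TRUE) - 1L)
  birth_date <- d0 + off
  yob <- as.integer(format(birth_date, "%Y"))

  # per-sample draws; rows alternate case, control within pair
  ns <- 2L * n
  case <- rep(c(1L, 0L), n)
  idx_pair <- rep(seq_len(n), each = 2L)
  ga <- round(pmin(43, pmax(30, stats::rnorm(ns, config$ga_mean,
                                             config$ga_sd))), 1)
  parity <- pmax(1L, as.integer(round(stats::rnorm(ns, config$parity_mean,
                                                   config$parity_sd))))
  mat_age <- round(pmin(50, pmax(16, stats::rnorm(ns, config$maternal_age_mean,
                                                  config$maternal_age_sd))), 1)
  cesarean <- as.integer(stats::runif(ns) <
                           ifelse(case == 1L, 0.213, 0.169))
  pre <- yob[idx_pair] < config$policy_change_year
  jitter <- ifelse(pre,
                   sample(c(-1L, 0L, 1L, 2L), ns, replace = TRUE,
                          prob = c(0.2, 0.4, 0.25, 0.15)),
                   sample(c(0L, 1L), ns, replace = TRUE, prob = c(0.7, 0.3)))
  age_days <- ifelse(pre, config$age_sampling_pre,
                     config$age_sampling_post) + jitter
  age_days <- pmax(1L, as.integer(age_days))

  bottle_p <- ifelse(case == 1L, config$bottle_prob_case,
                     config$bottle_prob_control)
  bottle <- as.integer(stats::runif(ns) < bottle_p)
  code_p <- ifelse(bottle == 1L,
                   ifelse(case == 1L, config$code_prob_bottle_case,
                          config$code_prob_bottle_control),
                   config$code_prob_base)
  has_code <- stats::runif(ns) < code_p
  day0_p <- ifelse(bottle == 1L, config$code_day0_prob,
                   config$code_day0_prob_nonbottle)
  code_day <- ifelse(has_code,
                     ifelse(stats::runif(ns) < day0_p, 0L,
                            sample(1:20, ns, replace = TRUE)),
                     NA_integer_)
  dosage <- stats::rbinom(ns, 2L, config$genotype_maf)

  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(ns)),
    pair_id = pair_id[idx_pair],
    case = case,
    sex = sex[idx_pair],
    birth_date = birth_date[idx_pair],
    year_of_birth = yob[idx_pair],
    gestational_age = ga,
    parity = parity,
    maternal_age = mat_age,
    cesarean = cesarean,
    age_days = age_days,
    icd_code = ifelse(has_code, config$icd_code, NA_character_),
    code_day = code_day,
    stringsAsFactors = FALSE
  )
  samples[[config$genotype_snp]] <- dosage

  truth <- list(
    bottle = stats::setNames(bottle, samples$sample_id),
    feeding_effect_per_day = config$feeding_effect_per_day,
    affected_metabolites = config$affected_metabolites,
    disease_effects = config$disease_effects,
    genotype_snp = config$genotype_snp,
    genotype_precursor = config$genotype_precursor,
    genotype_beta_precursor = config$genotype_beta_precursor
  )
  list(samples = samples, truth = truth)
}

#' Simulate true sample concentrations
#'
#' Draws the biological concentration matrix without any plate layout or
#' batch effects: `log C = log(base_m) + sample_log_sd * z`, where `z`
#' collects the shared latent factor (affected metabolites), the feeding
#' effect (per day of age at sampling, bottle-fed newborns only), genotype
#' and disease terms, plus unit-variance idiosyncratic noise. Uses the
#' current RNG state (callers seed; [simulate_plates()] seeds from the
#' config).
#'
#' @param samples Sample sheet from [simulate_cohort()].
#' @param panel A [panel_definition()].
#' @param config A [sim_config()].
#' @param bottle Optional 0/1 vector of latent bottle-feeding status per
#'   sample (defaults to all zero).
#' @return Numeric matrix (samples x metabolites) of concentrations in
#'   micromolar.
#' @export
simulate_concentrations <- function(samples, panel, config,
                                    bottle = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  ns <- nrow(samples)
  mets <- panel$name
  tv <- stats::setNames(panel$target_value_uM, mets)
  if (is.null(bottle)) bottle <- rep(0L, ns)
  lam <- config$affected_factor_loading
  u <- stats::rnorm(ns)
  dosage <- samples[[config$genotype_snp]]
  if (is.null(dosage)) dosage <- rep(0L, ns)

  Z <- matrix(stats::rnorm(ns * length(mets)), ns, length(mets),
              dimnames = list(samples$sample_id, mets))
  affected <- intersect(config$affected_metabolites, mets)
  if (length(affected)) {
    Z[, affected] <- lam * u + sqrt(1 - lam^2) * Z[, affected]
    Z[, affected] <- Z[, affected] + config$feeding_effect_per_day *
      samples$age_days * bottle
  }
  if (config$genotype_precursor %in% mets) {
    Z[, config$genotype_precursor] <- Z[, config$genotype_precursor] +
      config$genotype_beta_precursor * dosage
  }
  de <- config$disease_effects
  for (m in intersect(names(de), mets)) {
    Z[, m] <- Z[, m] + de[[m]] * samples$case
  }
  base <- tv[mets]
  if (length(config$fail_lod_metabolites)) {
    shrink <- intersect(config$fail_lod_metabolites, mets)
    # centre designed LOD failures below the blank level so most sample
    # wells fall at or under the per-plate LOD
    base[shrink] <- base[shrink] * config$blank_level_frac * 0.3
  }
  conc <- sweep(exp(config$sample_log_sd * Z), 2, base, `*`)
  conc
}

#' Simulate raw plate measurements for a cohort
#'
#' Lays the cohort out on `n_plates` 96-well plates (a matched case and
#' control always share a plate), draws a multiplicative batch factor
#' `C_{m,p}` per metabolite and plate, and emits a long-format raw
#' measurement table with paper-blank, QC1/QC2/QC3 and sample wells. Blank
#' wells sit at `blank_level_frac * TV_m`, QC2 wells at `TV_m * C_{m,p}`
#' times lognormal noise with CV `qc_noise_cv` (or `fail_cv_value` for
#' designed CV failures), and sample wells at the true concentration times
#' `C_{m,p}`.
#'
#' @param samples Sample sheet from [simulate_cohort()].
#' @param panel A [panel_definition()].
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cohort()] (supplies the latent
#'   bottle-feeding status; omit for an all-zero exposure).
#' @return List with `plates` (long-format data frame: `plate`, `well`,
#'   `sample_id`, `role`, `metabolite`, `raw_uM`), `concentrations` (true
#'   sample concentration matrix) and `truth` (adds the `C_{m,p}` matrix,
#'   the plate assignment and the designed-failure lists with their
#'   intended reasons).
#' @export
simulate_plates <- function(samples, panel, config = sim_config(),
                            truth = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "panel_definition"))
  set.seed(config$seed + 1L)
  mets <- panel$name
  tv <- stats::setNames(panel$target_value_uM, mets)
  n_m <- length(mets)
  bottle <- if (!is.null(truth)) truth$bottle[samples$sample_id] else NULL
  conc <- simulate_concentrations(samples, panel, config, bottle = bottle)

  # plate assignment: pairs in order, same plate for both members
  non_sample <- config$blanks_per_plate + config$qc2_reps_per_plate + 2L
  per_plate <- config$wells_per_plate - non_sample
  pair_ids <- unique(samples$pair_id)
  pairs_per_plate <- per_plate %/% 2L
  plate_of_pair <- stats::setNames(
    ((seq_along(pair_ids) - 1L) %/% pairs_per_plate) + 1L, pair_ids)
  if (max(plate_of_pair) > config$n_plates) {
    stop("infeasible layout: pairs do not fit on ", config$n_plates,
         " plates")
  }
  plate_of_sample <- plate_of_pair[samples$pair_id]

  C <- matrix(exp(stats::rnorm(n_m * config$n_plates, 0,
                               config$plate_factor_sd)),
              n_m, config$n_plates, dimnames = list(mets, NULL))
  qc_cv <- rep(config$qc_noise_cv, n_m)
  names(qc_cv) <- mets
  qc_cv[intersect(config$fail_cv_metabolites, mets)] <- config$fail_cv_value
  sdlog_qc <- sqrt(log(1 + qc_cv^2))
  sdlog_blank <- sqrt(log(1 + config$blank_noise_cv^2))

  blocks <- vector("list", config$n_plates)
  for (p in seq_len(config$n_plates)) {
    pl <- sprintf("PL%02d", p)
    nb <- config$blanks_per_plate
    nq2 <- config$qc2_reps_per_plate
    smp <- samples$sample_id[plate_of_sample == p]
    roles <- c(rep("blank", nb), "QC1", rep("QC2", nq2), "QC3",
               rep("sample", length(smp)))
    ids <- c(sprintf("%s_BLANK%d", pl, seq_len(nb)), sprintf("%s_QC1", pl),
             sprintf("%s_QC2_%d", pl, seq_len(nq2)), sprintf("%s_QC3", pl),
             smp)
    wells <- seq_along(roles)
    Cp <- C[, p]
    raw <- matrix(NA_real_, length(roles), n_m)
    bi <- which(roles == "blank")
    raw[bi, ] <- rep(config$blank_level_frac * tv, each = length(bi)) *
      exp(stats::rnorm(length(bi) * n_m, -sdlog_blank^2 / 2, sdlog_blank))
    for (lev in c("QC1", "QC2", "QC3")) {
      li <- which(roles == lev)
      scale <- c(QC1 = 0.25, QC2 = 1, QC3 = 4)[[lev]]
      noise <- exp(stats::rnorm(length(li) * n_m,
                                rep(-sdlog_qc^2 / 2, each = length(li)),
                                rep(sdlog_qc, each = length(li))))
      raw[li, ] <- rep(scale * tv * Cp, each = length(li)) * noise
    }
    si <- which(roles == "sample")
    raw[si, ] <- conc[smp, , drop = FALSE] *
      rep(Cp, each = length(si))
    blocks[[p]] <- data.frame(
      plate = pl,
      well = rep(wells, n_m),
      sample_id = rep(ids, n_m),
      role = rep(roles, n_m),
      metabolite = rep(mets, each = length(roles)),
      raw_uM = as.vector(raw),
      stringsAsFactors = FALSE
    )
  }
  plates <- do.call(rbind, blocks)
  rownames(plates) <- NULL
  colnames(C) <- sprintf("PL%02d", seq_len(config$n_plates))

  truth2 <- c(truth, list(
    plate_factors = C,
    plate_of_sample = stats::setNames(sprintf("PL%02d", plate_of_sample),
                                      samples$sample_id),
    designed_failures = rbind(
      if (length(config$fail_lod_metabolites))
        data.frame(metabolite = config$fail_lod_metabolites,
                   reason = "lod", stringsAsFactors = FALSE),
      if (length(config$fail_cv_metabolites))
        data.frame(metabolite = config$fail_cv_metabolites,
                   reason = "cv", stringsAsFactors = FALSE))
  ))
  list(plates = plates, concentrations = conc, truth = truth2)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [simulate_cohort()] then [simulate_plates()].
#'
#' @param config A [sim_config()].
#' @param panel A [panel_definition()]; defaults to [bundled_panel()].
#' @return List with `samples`, `panel`, `plates`, `concentrations`,
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config(), panel = bundled_panel()) {
  coh <- simulate_cohort(config)
  pl <- simulate_plates(coh$samples, panel, config, truth = coh$truth)
  list(samples = coh$samples, panel = panel, plates = pl$plates,
       concentrations = pl$concentrations, truth = pl$truth)
}

#' Write a synthetic study to the pipeline's input files
#'
#' Writes `plates.csv`, `samples.tsv`, `panel.tsv` and a `truth.json`
#' ground-truth sidecar into `dir`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plate_table(study$plates, file.path(dir, "plates.csv"))
  write_sample_sheet(study$samples, file.path(dir, "samples.tsv"))
  write_panel(study$panel, file.path(dir, "panel.tsv"))
  truth <- study$truth
  truth$plate_factors <- as.data.frame(truth$plate_factors)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
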