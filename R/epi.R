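# Diagnosis-code co-occurrence and SNP-metabolite models.

#' A 2x2 case-control exposure table
#'
#' @param a Cases with the code/exposure.
#' @param b Controls with the code.
#' @param c_ Cases without the code.
#' @param d Controls without the code.
#' @return List of class `"two_by_two"` with the counts and margins.
#' @export
two_by_two <- function(a, b, c_, d) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("cell counts must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c_, d = d,
                 n_cases = a + c_, n_controls = b + d),
            class = "two_by_two")
}

#' Tabulate diagnosis-code carriage in cases vs controls
#'
#' @param samples Sample sheet with `case` and `icd_code`.
#' @param code Diagnosis code string (default `"P92.5"`, neonatal
#'   difficulty in feeding at breast).
#' @return A [two_by_two()].
#' @export
make_code_table <- function(samples, code = "P92.5") {
  has <- !is.na(samples$icd_code) & samples$icd_code == code
  two_by_two(sum(has & samples$case == 1L),
             sum(has & samples$case == 0L),
             sum(!has & samples$case == 1L),
             sum(!has & samples$case == 0L))
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided exact test for a 2x2 table: the p-value sums the
#' noncentral-hypergeometric point probabilities (at odds ratio 1) not
#' exceeding that of the observed table; the odds-ratio estimate is the
#' conditional maximum-likelihood estimate given the margins, and the
#' confidence interval is the exact central interval obtained by
#' inverting one-sided conditional tests at `(1 - conf) / 2` per side
#' (the convention of `stats::fisher.test()`, which performs the
#' computation).
#'
#' @param table A [two_by_two()].
#' @param conf Confidence level (default 0.95).
#' @return List of class `"exact_test"`: `or_cmle`, `ci_low`, `ci_high`,
#'   `p`, `conf`, `table`, and `unbounded` (`TRUE` when a zero cell makes
#'   a CI endpoint 0 or infinite).
#' @export
fisher_exact <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  m <- matrix(c(table$a, table$c, table$b, table$d), 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  ft <- stats::fisher.test(m, conf.level = conf)
  ci <- ft$conf.int
  structure(list(or_cmle = unname(ft$estimate),
                 ci_low = ci[1], ci_high = ci[2],
                 p = ft$p.value, conf = conf, table = table,
                 unbounded = ci[1] == 0 || !is.finite(ci[2])),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  t <- x$table
  cat(sprintf("2x2 table: %d/%d cases vs %d/%d controls with code\n",
              t$a, t$n_cases, t$b, t$n_controls))
  cat(sprintf("Conditional-MLE OR %.2f, %.0f%% exact CI %.2f-%.2f, P = %.3g\n",
              x$or_cmle, 100 * x$conf, x$ci_low, x$ci_high, x$p))
  if (x$unbounded) cat("  (zero cell: CI endpoint unbounded)\n")
  invisible(x)
}

#' Diagnosis-timing linear model
#'
#' Among newborns carrying the diagnosis code, regresses a transformed
#' metabolite on an indicator of the code having been assigned on the day
#' of birth (day 0) vs later, adjusted for sex (factor), year of birth
#' (continuous), parity, gestational age (weeks) and case status, by
#' ordinary least squares. Reports the indicator's coefficient with its
#' two-sided t-test.
#'
#' @param y Transformed metabolite values aligned with `samples` rows.
#' @param samples Sample sheet with `icd_code` and `code_day`.
#' @param code Diagnosis code restricting the analysis set.
#' @return List of class `"timing_model"`: `beta`, `se`, `p`, `n_day0`,
#'   `n_later`, `fit`.
#' @export
code_timing_model <- function(y, samples, code = "P92.5") {
  sel <- !is.na(samples$icd_code) & samples$icd_code == code &
    !is.na(samples$code_day)
  d <- samples[sel, , drop = FALSE]
  d$y <- y[sel]
  d$day0 <- as.integer(d$code_day == 0L)
  d <- d[stats::complete.cases(
    d[, c("y", "day0", "sex", "year_of_birth", "parity",
          "gestational_age", "case")]), , drop = FALSE]
  if (sum(d$day0 == 1L) < 2L || sum(d$day0 == 0L) < 2L) {
    stop("need at least 2 code carriers per timing level (day 0 vs later)")
  }
  d$sex <- factor(d$sex)
  covars <- c("day0",
              if (nlevels(droplevels(d$sex)) > 1L) "sex",
              "year_of_birth", "parity", "gestational_age", "case")
  fit <- stats::lm(stats::reformulate(covars, response = "y"), data = d)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop("collinear term(s) in timing model: ",
         paste(bad, collapse = ", "))
  }
  cs <- summary(fit)$coefficients
  structure(list(beta = cs["day0", "Estimate"],
                 se = cs["day0", "Std. Error"],
                 p = cs["day0", "Pr(>|t|)"],
                 n_day0 = sum(d$day0 == 1L), n_later = sum(d$day0 == 0L),
                 fit = fit),
            class = "timing_model")
}

#' @export
print.timing_model <- function(x, ...) {
  cat(sprintf(
    "Code-timing model (day 0: n=%d, later: n=%d): beta = %.3f, SE = %.3f, P = %.3g\n",
    x$n_day0, x$n_later, x$beta, x$se, x$p))
  invisible(x)
}

#' Element-wise metabolite ratio
#'
#' Computed on the normalized concentration scale (before any
#' transformation); elements with a non-positive or missing denominator
#' are flagged missing. Downstream models receive the
#' inverse-normal-transformed ratio, which is invariant to any common
#' per-sample scaling of the two metabolites.
#'
#' @param numerator,denominator Numeric vectors of equal length.
#' @return Numeric vector of ratios with `NA` where undefined.
#' @export
metabolite_ratio <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  bad <- is.na(denominator) | denominator <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad), " element(s) with non-positive denominator set to NA")
  }
  out <- numerator / denominator
  out[bad] <- NA_real_
  out
}

#' SNP-trait association by additive-dosage linear model
#'
#' Ordinary least squares of a transformed trait (metabolite or
#' metabolite ratio) on allele dosage (0/1/2), adjusted for case status,
#' sex (factor), year of birth (factor, sparse levels merged), parity and
#' gestational age. Supports era-stratified runs.
#'
#' @param dosage Integer vector of allele dosages aligned with `samples`.
#' @param trait Transformed trait vector aligned with `samples`.
#' @param samples Sample sheet.
#' @param snp Variant label stored in the result.
#' @param trait_name Trait label stored in the result.
#' @param stratum `"all"` (default), `"pre_policy"` or `"post_policy"`.
#' @param split_year Policy-change year for stratification (default 2009).
#' @return List of class `"snp_assoc"`: `snp`, `trait`, `beta`, `se`,
#'   `p`, `stratum`, `n`, `dosage_coding`, `fit`.
#' @export
snp_trait_assoc <- function(dosage, trait, samples, snp = "snp",
                            trait_name = "trait",
                            stratum = c("all", "pre_policy", "post_policy"),
                            split_year = 2009) {
  stratum <- match.arg(stratum)
  stopifnot(length(dosage) == nrow(samples),
            length(trait) == nrow(samples))
  sel <- switch(stratum,
                all = rep(TRUE, nrow(samples)),
                pre_policy = samples$year_of_birth < split_year,
                post_policy = samples$year_of_birth >= split_year)
  d <- samples[sel, , drop = FALSE]
  d$dosage <- dosage[sel]
  d$y <- trait[sel]
  d <- d[stats::complete.cases(
    d[, c("y", "dosage", "case", "sex", "year_of_birth", "parity",
          "gestational_age")]), , drop = FALSE]
  if (nrow(d) < 10L) stop("too few complete observations in stratum ",
                          stratum)
  if (length(unique(d$dosage)) < 2L) {
    stop("monomorphic dosage in stratum ", stratum)
  }
  d$sex <- factor(d$sex)
  grp <- if (!is.null(d$pair_id)) d$pair_id else d$sample_id
  d$yob <- merge_sparse_years(d$year_of_birth, grp)
  covars <- c("dosage", "case",
              if (nlevels(droplevels(d$sex)) > 1L) "sex",
              if (nlevels(droplevels(d$yob)) > 1L) "yob",
              "parity", "gestational_age")
  # prune covariates that are constant in this stratum
  covars <- covars[vapply(covars, function(v) {
    x <- d[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1L else diff(range(x)) > 0
  }, logical(1))]
  fit <- stats::lm(stats::reformulate(covars, response = "y"), data = d)
  cs <- summary(fit)$coefficients
  structure(list(snp = snp, trait = trait_name,
                 beta = cs["dosage", "Estimate"],
                 se = cs["dosage", "Std. Error"],
                 p = cs["dosage", "Pr(>|t|)"],
                 stratum = stratum, n = nrow(d),
                 dosage_coding = "additive, counts of effect allele (0/1/2)",
                 fit = fit),
            class = "snp_assoc")
}

#' @export
print.snp_assoc <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s, n=%d]: beta = %.4f, SE = %.4f, P = %.3g\n",
              x$trait, x$snp, x$stratum, x$n, x$beta, x$se, x$p))
  invisible(x)
}

#' SNP sweep across all metabolites with Bonferroni correction
#'
#' Runs [snp_trait_assoc()] for one variant against every column of a
#' normalized metabolite matrix (each inverse-normal transformed first)
#' and flags associations at the Bonferroni threshold
#' `alpha / n_metabolites`.
#'
#' @param dosage Allele dosages aligned with `samples`.
#' @param mat Samples x metabolites normalized concentration matrix.
#' @param samples Sample sheet.
#' @param snp Variant label.
#' @param alpha Family-wise level (default 0.05).
#' @param ... Passed to [snp_trait_assoc()] (e.g. `stratum`).
#' @return Data frame with one row per metabolite (`snp`, `trait`,
#'   `beta`, `se`, `p`, `stratum`, `n`, `significant_bonferroni`), sorted
#'   by p; attribute `threshold`.
#' @export
snp_metabolome_scan <- function(dosage, mat, samples, snp = "snp",
                                alpha = 0.05, ...) {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(samples))
  rows <- lapply(colnames(mat), function(m) {
    y <- inverse_normal_transform(mat[, m])
    r <- snp_trait_assoc(dosage, y, samples, snp = snp, trait_name = m, ...)
    data.frame(snp = r$snp, trait = r$trait, beta = r$beta, se = r$se,
               p = r$p, stratum = r$stratum, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- alpha / ncol(mat)
  out$significant_bonferroni <- out$p < thr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
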