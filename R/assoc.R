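# Metabolome-wide matched-pair association: rank-based inverse normal
# transformation, pair-level random-intercept mixed models (lme4), era
# stratification, Bonferroni bookkeeping, pairwise Pearson correlations.

#' Rank-based inverse normal transformation
#'
#' Maps the value at rank `r` (average ranks for ties) of `n` non-missing
#' observations to the standard-normal quantile of `(r - 0.5) / n`
#' (default offset), or `(r - 3/8) / (n + 1/4)` for the Blom offset. The
#' output is monotone in the input and invariant to any strictly monotone
#' transformation of it.
#'
#' @param x Numeric vector with at least two finite values; `NA`s are
#'   propagated. A constant vector is an error (the transform is
#'   undefined).
#' @param offset `"half"` (default) or `"blom"`.
#' @return Numeric vector of normal scores, same length as `x`.
#' @export
inverse_normal_transform <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L) stop("need at least two non-missing values")
  if (!all(is.finite(v))) stop("non-finite values in input")
  if (diff(range(v)) == 0) {
    stop("all values identical: inverse normal transform undefined")
  }
  r <- rank(v, ties.method = "average")
  n <- length(v)
  p <- if (offset == "half") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm(p)
  out
}

# Merge year-of-birth factor levels represented by fewer than min_pairs
# pairs into the nearest (by calendar distance) better-supported year, so
# small cohorts do not produce singular fixed-effect designs.
merge_sparse_years <- function(year, pair_id, min_pairs = 2L) {
  lev <- sort(unique(year))
  repeat {
    counts <- vapply(lev, function(y) {
      length(unique(pair_id[year == y]))
    }, integer(1))
    small <- which(counts < min_pairs)
    if (!length(small) || length(lev) == 1L) break
    i <- small[which.min(counts[small])]
    others <- setdiff(seq_along(lev), i)
    j <- others[which.min(abs(lev[others] - lev[i]))]
    year[year == lev[i]] <- lev[j]
    lev <- sort(unique(year))
  }
  factor(year)
}

# Assemble the per-metabolite model frame: complete pairs only, sparse
# year levels merged, covariate columns that are constant (or collinear
# after factor expansion) pruned. `covariates` names columns of `samples`.
.build_model_frame <- function(y, samples,
                               covariates = c("sex", "year_of_birth",
                                              "parity", "gestational_age"),
                               extra = character(0)) {
  covariates <- union(covariates, extra)
  miss <- setdiff(c("pair_id", "case", covariates), names(samples))
  if (length(miss)) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  d <- samples[, c("sample_id", "pair_id", "case", covariates),
               drop = FALSE]
  d$y <- y
  ok <- stats::complete.cases(d)
  bad_pairs <- unique(d$pair_id[!ok])
  d <- d[!d$pair_id %in% bad_pairs, , drop = FALSE]
  tab <- table(d$pair_id, d$case)
  if (nrow(tab) == 0L) stop("no complete case-control pairs left")
  if (any(tab != 1L) || ncol(tab) != 2L) {
    stop("pairs must contain exactly one case and one control each")
  }
  if ("year_of_birth" %in% covariates) {
    d$year_of_birth <- merge_sparse_years(d$year_of_birth, d$pair_id)
  }
  if ("sex" %in% covariates) d$sex <- factor(d$sex)
  if ("cesarean" %in% covariates) d$cesarean <- factor(d$cesarean)
  d
}

# Drop covariate terms whose model-matrix columns are constant or linearly
# dependent, keeping `case`. Returns the surviving covariate names.
.prune_covariates <- function(d, covariates) {
  keep <- character(0)
  for (v in covariates) {
    x <- d[[v]]
    if (is.factor(x) && nlevels(droplevels(x)) < 2L) next
    if (is.numeric(x) && diff(range(x)) == 0) next
    keep <- c(keep, v)
  }
  if (!length(keep)) return(keep)
  X <- stats::model.matrix(
    stats::reformulate(c("case", keep)), data = d)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped_cols <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    # map aliased columns back to terms and drop those terms
    assign <- attr(X, "assign")
    terms_lab <- c("(Intercept)", "case", keep)[assign + 1L]
    bad_terms <- unique(terms_lab[colnames(X) %in% dropped_cols])
    if ("case" %in% bad_terms) {
      stop("case status is collinear with the covariates; cannot fit")
    }
    keep <- setdiff(keep, bad_terms)
  }
  keep
}

#' Fit the matched-pair mixed model for one metabolite
#'
#' Restricted-maximum-likelihood fit of
#' `y ~ case + covariates + (1 | pair)` with `lme4::lmer()`: a linear
#' mixed model with a random intercept per matched case-control pair.
#' Incomplete pairs (missing outcome or covariate) are dropped pairwise;
#' year-of-birth levels carried by a single pair are merged into the
#' nearest year; covariate columns that are constant or collinear in the
#' fixed-effect design are pruned before fitting (an error is raised only
#' if the case-status column itself is confounded). The reported p-value
#' is a Wald test on the case coefficient using the normal reference
#' (default) or, with `use_t = TRUE`, a Satterthwaite t-test via
#' \pkg{lmerTest}.
#'
#' @param y Numeric outcome vector aligned with `samples` rows (typically
#'   an inverse-normal-transformed metabolite).
#' @param samples Sample sheet (needs `sample_id`, `pair_id`, `case` and
#'   the covariate columns).
#' @param covariates Character vector of fixed-effect covariate column
#'   names; the default matches the study model (sex and year of birth as
#'   factors, parity, gestational age in weeks).
#' @param use_t Use a Satterthwaite t reference for the p-value (requires
#'   \pkg{lmerTest}).
#' @return List of class `"pair_lmm"`: `beta`, `se`, `p` for the case
#'   coefficient, `n_pairs`, `covariates_used`, `fit` (the `merMod`).
#' @export
fit_pair_lmm <- function(y, samples,
                         covariates = c("sex", "year_of_birth", "parity",
                                        "gestational_age"),
                         use_t = FALSE) {
  d <- .build_model_frame(y, samples, covariates)
  used <- .prune_covariates(d, intersect(covariates, names(d)))
  fit <- .fit_lmm(d, used, use_t = use_t)
  res <- .case_stats(fit, use_t = use_t)
  structure(list(beta = res[["beta"]], se = res[["se"]], p = res[["p"]],
                 n_pairs = length(unique(d$pair_id)),
                 covariates_used = used, fit = fit),
            class = "pair_lmm")
}

.fit_lmm <- function(d, used, use_t = FALSE) {
  rhs <- paste(c("case", used, "(1 | pair_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  if (use_t) {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("use_t = TRUE requires the lmerTest package")
    }
    lmerTest::lmer(fml, data = d, REML = TRUE, control = ctrl)
  } else {
    lme4::lmer(fml, data = d, REML = TRUE, control = ctrl)
  }
}

.case_stats <- function(fit, use_t = FALSE) {
  if (use_t) {
    co <- stats::coef(summary(fit))
    c(beta = co["case", "Estimate"], se = co["case", "Std. Error"],
      p = co["case", "Pr(>|t|)"])
  } else {
    beta <- lme4::fixef(fit)[["case"]]
    V <- as.matrix(stats::vcov(fit))
    se <- sqrt(V["case", "case"])
    z <- beta / se
    c(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
  }
}

#' @export
print.pair_lmm <- function(x, ...) {
  cat(sprintf(
    "Matched-pair mixed model (%d pairs): beta = %.4f, SE = %.4f, P = %.3g\n",
    x$n_pairs, x$beta, x$se, x$p))
  if (length(x$covariates_used)) {
    cat("  fixed-effect covariates:",
        paste(x$covariates_used, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Metabolome-wide matched-pair association scan
#'
#' Transforms each metabolite column to normal scores (unless
#' `transform = FALSE`) and fits the matched-pair mixed model of
#' [fit_pair_lmm()] to each. All metabolites share one fixed-effect design,
#' so after the first full fit the remaining metabolites are refit on the
#' same model structure (`lme4::refit()`), which is exact and much faster.
#' The Bonferroni significance threshold is `alpha` divided by the number
#' of metabolites actually tested.
#'
#' @param mat Numeric matrix, samples x metabolites (rows aligned with
#'   `samples`), normalized concentrations.
#' @param samples Sample sheet.
#' @param alpha Family-wise significance level (default 0.05).
#' @param covariates Fixed-effect covariates, as in [fit_pair_lmm()].
#' @param transform Apply [inverse_normal_transform()] per metabolite
#'   (default `TRUE`).
#' @param offset Transform offset, see [inverse_normal_transform()].
#' @param use_t Satterthwaite t p-values instead of Wald normal.
#' @param stratum Label stored in the result rows (default `"all"`).
#' @return Data frame of class `"assoc_scan"`, one row per metabolite:
#'   `metabolite`, `beta`, `se`, `p`, `stratum`, `n_pairs`,
#'   `significant_bonferroni`; sorted by p. Attributes `alpha`,
#'   `n_tested`, `threshold`.
#' @export
metabolome_scan <- function(mat, samples, alpha = 0.05,
                            covariates = c("sex", "year_of_birth",
                                           "parity", "gestational_age"),
                            transform = TRUE,
                            offset = c("half", "blom"),
                            use_t = FALSE, stratum = "all") {
  offset <- match.arg(offset)
  stopifnot(is.matrix(mat), nrow(mat) == nrow(samples))
  mets <- colnames(mat)
  if (is.null(mets)) stop("matrix must have metabolite column names")
  n_m <- length(mets)

  rows <- vector("list", n_m)
  base_fit <- NULL
  base_ids <- NULL
  used <- NULL
  for (j in seq_len(n_m)) {
    y <- mat[, j]
    if (transform) y <- inverse_normal_transform(y, offset = offset)
    if (is.null(base_fit)) {
      d <- .build_model_frame(y, samples, covariates)
      used <- .prune_covariates(d, intersect(covariates, names(d)))
      base_fit <- .fit_lmm(d, used, use_t = FALSE)
      base_ids <- d$sample_id
      fit <- base_fit
      np <- length(unique(d$pair_id))
    } else if (!anyNA(y)) {
      # refit() does not honour the stored singular-fit check setting
      fit <- suppressMessages(
        lme4::refit(base_fit, newresp = y[match(base_ids,
                                                samples$sample_id)]))
      np <- length(base_ids) / 2L
    } else {
      # missingness pattern may differ: full fit for this metabolite
      d <- .build_model_frame(y, samples, covariates)
      u2 <- .prune_covariates(d, intersect(covariates, names(d)))
      fit <- .fit_lmm(d, u2, use_t = FALSE)
      np <- length(unique(d$pair_id))
    }
    st <- .case_stats(fit, use_t = FALSE)
    if (use_t) {
      # refit path keeps lme4 objects; recompute with Satterthwaite df
      st <- .case_stats(.fit_lmm(
        .build_model_frame(y, samples, covariates), used, use_t = TRUE),
        use_t = TRUE)
    }
    rows[[j]] <- data.frame(metabolite = mets[j], beta = st[["beta"]],
                            se = st[["se"]], p = st[["p"]],
                            stratum = stratum, n_pairs = np,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  thr <- alpha / n_m
  out$significant_bonferroni <- out$p < thr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_m
  attr(out, "threshold") <- thr
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' @export
print.assoc_scan <- function(x, n = 10L, ...) {
  cat(sprintf(
    "Association scan: %d metabolites, Bonferroni threshold %.3g (alpha %.2f)\n",
    attr(x, "n_tested"), attr(x, "threshold"), attr(x, "alpha")))
  cat(sprintf("  significant: %d\n", sum(x$significant_bonferroni)))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Era-stratified association scans
#'
#' Splits the matched pairs by year of birth at `split_year` (the
#' screening-policy change that shortened the age at sampling) and runs
#' [metabolome_scan()] within each stratum. By default each stratum is
#' re-transformed to normal scores on its own samples
#' (`retransform = TRUE`); the alternative reuses the values passed in.
#' Empty strata are reported and skipped.
#'
#' @param mat Samples x metabolites matrix of normalized concentrations.
#' @param samples Sample sheet with `year_of_birth`.
#' @param split_year First year of the late (post-policy) stratum
#'   (default 2009).
#' @param retransform Re-apply the inverse normal transform within each
#'   stratum (default) rather than reusing global transforms.
#' @param ... Passed to [metabolome_scan()].
#' @return An `"assoc_scan"` data frame with strata `"pre_policy"`
#'   (year of birth < `split_year`) and `"post_policy"`, plus attribute
#'   `n_pairs_stratum`.
#' @export
stratified_scan <- function(mat, samples, split_year = 2009,
                            retransform = TRUE, ...) {
  stopifnot(nrow(mat) == nrow(samples))
  if (!retransform) {
    # one global transform, reused across strata
    mat <- apply(mat, 2, inverse_normal_transform)
  }
  pre <- samples$year_of_birth < split_year
  pieces <- list()
  np <- c(pre_policy = 0L, post_policy = 0L)
  for (lab in c("pre_policy", "post_policy")) {
    sel <- if (lab == "pre_policy") pre else !pre
    if (!any(sel)) {
      message("stratum ", lab, " is empty; skipped")
      next
    }
    sc <- metabolome_scan(mat[sel, , drop = FALSE],
                          samples[sel, , drop = FALSE],
                          transform = retransform, stratum = lab, ...)
    np[[lab]] <- max(sc$n_pairs)
    pieces[[lab]] <- sc
  }
  if (!length(pieces)) stop("both strata are empty")
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  rownames(out) <- NULL
  attr(out, "alpha") <- attr(pieces[[1]], "alpha")
  attr(out, "n_tested") <- attr(pieces[[1]], "n_tested")
  attr(out, "threshold") <- attr(pieces[[1]], "threshold")
  attr(out, "n_pairs_stratum") <- np
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Pairwise Pearson correlations with t-tests
#'
#' Pearson product-moment correlation on pairwise-complete observations
#' for every pair of columns, with the two-sided t-test
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Cells with fewer than 3 complete observations or zero variance are
#' `NA`.
#'
#' @param mat Numeric matrix, samples x metabolites (e.g. the transformed
#'   values of the significant hits).
#' @return List of class `"cor_result"` with symmetric matrices `r`
#'   (unit diagonal), `p` (`NA` diagonal) and `n` (complete observation
#'   counts).
#' @export
pairwise_correlation <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1L)
  obs <- !is.na(mat)
  n <- crossprod(obs)
  suppressWarnings(r <- stats::cor(mat, use = "pairwise.complete.obs"))
  r[n < 3L] <- NA_real_
  tt <- r * sqrt(pmax(n - 2L, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2L, 1L))
  p[n < 3L | !is.finite(tt)] <- NA_real_
  diag(r) <- 1
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat("Pairwise Pearson correlations (", ncol(x$r), " variables)\n",
      sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Diagnostic plot of an association scan
#'
#' Plots -log10 p per metabolite in panel order with the Bonferroni
#' threshold as a dashed line; effect direction by color.
#'
#' @param x An `"assoc_scan"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.assoc_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cols <- ifelse(x$beta < 0, "steelblue", "firebrick")
  graphics::plot(seq_len(nrow(x)), -log10(x$p), col = cols, pch = 19,
                 xlab = "metabolite (by p-value rank)",
                 ylab = expression(-log[10](P)), ...)
  graphics::abline(h = -log10(thr), lty = 2)
  invisible(x)
}
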