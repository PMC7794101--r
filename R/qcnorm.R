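# Plate-level data cleaning: per-plate LOD from paper blanks, LOD-based
# metabolite exclusion, QC2/target-value plate normalization, CV filtering.

.check_plate_table <- function(plates) {
  needed <- c("plate", "well", "sample_id", "role", "metabolite", "raw_uM")
  miss <- setdiff(needed, names(plates))
  if (length(miss)) {
    stop("plate table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(plates$role),
                 c("sample", "blank", "QC1", "QC2", "QC3"))
  if (length(bad)) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  invisible(plates)
}

#' Per-plate limit of detection from paper blanks
#'
#' The limit of detection `LOD_{m,p}` of metabolite `m` on plate `p` is
#' the median raw (non-normalized) signal of the paper-blank wells of that
#' plate; LODs are computed separately for each plate. Even blank counts
#' use the usual midpoint median.
#'
#' @param plates Long-format plate table (columns `plate`, `well`,
#'   `sample_id`, `role`, `metabolite`, `raw_uM`).
#' @return Numeric matrix, metabolites x plates.
#' @export
compute_lod <- function(plates) {
  .check_plate_table(plates)
  bl <- plates[plates$role == "blank", , drop = FALSE]
  if (nrow(bl) == 0L) stop("no blank wells in plate table")
  mets <- unique(plates$metabolite)
  pls <- unique(plates$plate)
  lod <- matrix(NA_real_, length(mets), length(pls),
                dimnames = list(mets, pls))
  agg <- stats::aggregate(raw_uM ~ metabolite + plate, data = bl,
                          FUN = stats::median)
  lod[cbind(agg$metabolite, agg$plate)] <- agg$raw_uM
  if (anyNA(lod)) {
    i <- which(is.na(lod), arr.ind = TRUE)[1, ]
    stop("metabolite '", mets[i[1]], "' has no blank wells on plate ",
         pls[i[2]])
  }
  lod
}

#' Limit-of-detection metabolite filter
#'
#' For each metabolite, computes the fraction of sample measurements at or
#' below the plate-specific LOD, separately within cases and within
#' controls. Under the default `rule = "either"` a metabolite is kept when
#' at least one of the two groups has at least `1 - max_frac` of its
#' measurements above LOD; `rule = "both"` requires it of both groups.
#'
#' @param plates Plate table.
#' @param samples Sample sheet with `sample_id` and `case` (1 = case).
#' @param lod LOD matrix from [compute_lod()].
#' @param max_frac Maximum tolerated fraction of measurements at or below
#'   LOD (default 0.20).
#' @param rule `"either"` (default) or `"both"`; see above.
#' @return Data frame with `metabolite`, `frac_case`, `frac_control`,
#'   `keep`.
#' @export
lod_filter <- function(plates, samples, lod, max_frac = 0.20,
                       rule = c("either", "both")) {
  rule <- match.arg(rule)
  .check_plate_table(plates)
  sm <- plates[plates$role == "sample", , drop = FALSE]
  case_of <- stats::setNames(samples$case, samples$sample_id)
  unknown <- setdiff(unique(sm$sample_id), names(case_of))
  if (length(unknown)) {
    stop("sample well(s) not in sample sheet: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  below <- sm$raw_uM <= lod[cbind(sm$metabolite, sm$plate)]
  grp <- case_of[sm$sample_id]
  frac <- function(g) {
    tapply(below[grp == g], sm$metabolite[grp == g], mean)
  }
  mets <- rownames(lod)
  fc <- frac(1L)[mets]
  f0 <- frac(0L)[mets]
  keep <- if (rule == "either") {
    (fc <= max_frac) | (f0 <= max_frac)
  } else {
    (fc <= max_frac) & (f0 <= max_frac)
  }
  data.frame(metabolite = mets, frac_case = unname(fc),
             frac_control = unname(f0), keep = unname(keep),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plate correction factors from QC2 reference wells
#'
#' For each metabolite `m` and plate `p`, `A_{m,p}` is the median raw
#' signal of the replicated QC2 wells, using only wells strictly above the
#' plate's LOD; the correction factor is `C_{m,p} = A_{m,p} / TV_m` with
#' `TV_m` the metabolite's target value from the panel definition. A
#' metabolite with no QC2 well above LOD on some plate gets `NA` there and
#' is reported as unusable on that plate.
#'
#' @param plates Plate table.
#' @param panel A [panel_definition()] supplying `TV_m`.
#' @param lod LOD matrix from [compute_lod()].
#' @return List with matrices `qc2_median` (`A`), `correction` (`C`), and
#'   `unusable` (data frame of metabolite/plate combinations with no
#'   usable QC2 well).
#' @export
plate_correction <- function(plates, panel, lod) {
  .check_plate_table(plates)
  stopifnot(inherits(panel, "panel_definition"))
  qc <- plates[plates$role == "QC2", , drop = FALSE]
  if (nrow(qc) == 0L) stop("no QC2 wells in plate table")
  mets <- rownames(lod)
  pls <- colnames(lod)
  A <- matrix(NA_real_, length(mets), length(pls),
              dimnames = list(mets, pls))
  above <- qc$raw_uM > lod[cbind(qc$metabolite, qc$plate)]
  qa <- qc[above, , drop = FALSE]
  if (nrow(qa)) {
    agg <- stats::aggregate(raw_uM ~ metabolite + plate, data = qa,
                            FUN = stats::median)
    A[cbind(agg$metabolite, agg$plate)] <- agg$raw_uM
  }
  tv <- stats::setNames(panel$target_value_uM, panel$name)
  if (any(!mets %in% names(tv))) {
    stop("metabolite(s) missing from panel: ",
         paste(utils::head(setdiff(mets, names(tv)), 5), collapse = ", "))
  }
  C <- A / tv[mets]
  un <- which(is.na(A), arr.ind = TRUE)
  unusable <- data.frame(metabolite = mets[un[, 1]], plate = pls[un[, 2]],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(qc2_median = A, correction = C, unusable = unusable)
}

#' Normalize raw plate values by the plate correction factor
#'
#' `Norm_{m,p} = Raw_{m,p} / C_{m,p}` for every well (all roles). After
#' normalization the median of the above-LOD QC2 wells of each plate
#' equals `TV_m` exactly, by construction.
#'
#' @param plates Plate table.
#' @param correction Correction matrix `C` from [plate_correction()]
#'   (rows restricted to the metabolites to normalize).
#' @return The plate table restricted to metabolites in `correction`,
#'   with `raw_uM` replaced by a `norm_uM` column (raw retained).
#' @export
normalize_plates <- function(plates, correction) {
  .check_plate_table(plates)
  keep <- plates$metabolite %in% rownames(correction)
  out <- plates[keep, , drop = FALSE]
  C <- correction[cbind(out$metabolite, out$plate)]
  if (anyNA(C) || any(C <= 0)) {
    stop("correction factor missing or non-positive for some ",
         "(metabolite, plate); drop those metabolites first")
  }
  out$norm_uM <- out$raw_uM / C
  rownames(out) <- NULL
  out
}

#' Coefficient-of-variation metabolite filter
#'
#' Pools the normalized QC2 replicate wells of all plates (e.g. 5
#' replicates x 8 plates = 40 observations) and computes
#' `CV_m = sd/mean` with the n-1 sample standard deviation. Metabolites
#' with `CV_m` above `cv_max`, or with non-positive mean, are dropped.
#'
#' @param norm Normalized plate table from [normalize_plates()].
#' @param cv_max CV threshold (default 0.25).
#' @return Data frame with `metabolite`, `cv`, `keep`.
#' @export
cv_filter <- function(norm, cv_max = 0.25) {
  qc <- norm[norm$role == "QC2", , drop = FALSE]
  if (nrow(qc) == 0L) stop("no QC2 wells in normalized table")
  mn <- tapply(qc$norm_uM, qc$metabolite, mean)
  sd_ <- tapply(qc$norm_uM, qc$metabolite, stats::sd)
  cv <- ifelse(mn > 0, sd_ / mn, Inf)
  data.frame(metabolite = names(mn), cv = unname(cv),
             keep = unname(cv <= cv_max & mn > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full plate-level QC and normalization
#'
#' Applies, in order: per-plate LOD from blanks ([compute_lod()]), the
#' LOD-fraction metabolite filter ([lod_filter()]), QC2/target-value plate
#' correction ([plate_correction()]; metabolites with an unusable plate
#' are dropped entirely), normalization ([normalize_plates()]) and the
#' QC2 CV filter ([cv_filter()]). The stage order matters and is pinned by
#' regression tests: LOD verdicts are made on non-normalized values and CV
#' verdicts on normalized values of the survivors.
#'
#' @param plates Plate table.
#' @param samples Sample sheet.
#' @param panel A [panel_definition()].
#' @param lod_frac Maximum fraction of sample measurements at or below LOD
#'   (default 0.20).
#' @param cv_max Maximum QC2 CV (default 0.25).
#' @param lod_rule `"either"` (default) or `"both"`, see [lod_filter()].
#' @return List of class `"qc_result"`: `matrix` (samples x kept
#'   metabolites, normalized concentrations in micromolar, rows in sample
#'   sheet order) and `report` (class `"qc_report"`: `lod`, `qc2_median`,
#'   `correction`, `cv`, `verdicts` with one row per panel metabolite and
#'   verdict `kept` / `dropped_lod` / `dropped_qc2` / `dropped_cv`, plus
#'   the thresholds used).
#' @export
run_qc <- function(plates, samples, panel, lod_frac = 0.20, cv_max = 0.25,
                   lod_rule = c("either", "both")) {
  lod_rule <- match.arg(lod_rule)
  .check_plate_table(plates)
  stopifnot(inherits(panel, "panel_definition"))
  mets <- unique(plates$metabolite)
  extra <- setdiff(mets, panel$name)
  if (length(extra)) {
    stop("plate table contains metabolite(s) absent from the panel: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }

  lod <- compute_lod(plates)
  lf <- lod_filter(plates, samples, lod, max_frac = lod_frac,
                   rule = lod_rule)
  verdict <- stats::setNames(rep("kept", length(mets)), mets)
  detail <- stats::setNames(rep(NA_character_, length(mets)), mets)
  drop1 <- lf$metabolite[!lf$keep]
  verdict[drop1] <- "dropped_lod"
  detail[drop1] <- sprintf(
    "frac<=LOD cases %.3f, controls %.3f (max %.2f, rule %s)",
    lf$frac_case[!lf$keep], lf$frac_control[!lf$keep], lod_frac, lod_rule)

  kept1 <- setdiff(mets, drop1)
  pc <- plate_correction(plates, panel, lod)
  drop2 <- intersect(kept1, unique(pc$unusable$metabolite))
  verdict[drop2] <- "dropped_qc2"
  detail[drop2] <- "no QC2 well above LOD on some plate"

  kept2 <- setdiff(kept1, drop2)
  norm <- normalize_plates(plates,
                           pc$correction[kept2, , drop = FALSE])
  cvf <- cv_filter(norm, cv_max = cv_max)
  cv <- stats::setNames(cvf$cv, cvf$metabolite)
  drop3 <- cvf$metabolite[!cvf$keep]
  verdict[drop3] <- "dropped_cv"
  detail[drop3] <- sprintf("QC2 CV %.3f > %.2f", cv[drop3], cv_max)

  kept <- setdiff(kept2, drop3)
  sm <- norm[norm$role == "sample" & norm$metabolite %in% kept, ,
             drop = FALSE]
  mat <- matrix(NA_real_, nrow(samples), length(kept),
                dimnames = list(samples$sample_id, kept))
  mat[cbind(sm$sample_id, sm$metabolite)] <- sm$norm_uM

  report <- structure(list(
    lod = lod, qc2_median = pc$qc2_median, correction = pc$correction,
    cv = cv,
    lod_fractions = lf,
    verdicts = data.frame(metabolite = mets, verdict = unname(verdict),
                          detail = unname(detail),
                          stringsAsFactors = FALSE),
    thresholds = list(lod_frac = lod_frac, cv_max = cv_max,
                      lod_rule = lod_rule),
    n_input = length(mets), n_kept = length(kept)
  ), class = "qc_report")
  structure(list(matrix = mat, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  tab <- table(factor(x$verdicts$verdict,
                      levels = c("kept", "dropped_lod", "dropped_qc2",
                                 "dropped_cv")))
  cat("Plate QC report\n")
  cat(sprintf("  metabolites in: %d\n", x$n_input))
  cat(sprintf("  dropped (>%.0f%% of samples <= LOD, rule '%s'): %d\n",
              100 * x$thresholds$lod_frac, x$thresholds$lod_rule,
              tab[["dropped_lod"]]))
  cat(sprintf("  dropped (no usable QC2 on some plate): %d\n",
              tab[["dropped_qc2"]]))
  cat(sprintf("  dropped (QC2 CV > %.0f%%): %d\n",
              100 * x$thresholds$cv_max, tab[["dropped_cv"]]))
  cat(sprintf("  kept: %d\n", tab[["kept"]]))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  cat(sprintf("  normalized matrix: %d samples x %d metabolites\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
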