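# End-to-end pipeline: file formats, run configuration, the composed run,
# and fixture generation.

#' Read / write the long-format plate measurement CSV
#'
#' Columns: `plate`, `well`, `sample_id`, `role`
#' (sample/blank/QC1/QC2/QC3), `metabolite`, `raw_uM`.
#'
#' @param path File path.
#' @return `read_plate_table()` returns the validated data frame.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_plate_table(df)
  key <- paste(df$plate, df$well, df$metabolite)
  if (anyDuplicated(key)) {
    stop("duplicate (plate, well, metabolite) rows in ", path)
  }
  df
}

#' @rdname read_plate_table
#' @param plates Plate table data frame.
#' @export
write_plate_table <- function(plates, path) {
  .check_plate_table(plates)
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the sample sheet TSV
#'
#' One row per newborn: `sample_id`, `pair_id`, `case` (1 = case),
#' `sex`, covariates, `age_days`, optional `icd_code`/`code_day`, and
#' optional SNP dosage columns named by variant id.
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns the validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  needed <- c("sample_id", "pair_id", "case")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a normalized concentration matrix TSV
#'
#' Wide TSV: first column `sample_id`, remaining columns metabolites,
#' values in micromolar.
#'
#' @param path File path.
#' @return `read_matrix()` returns a numeric matrix with sample-id row
#'   names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix
#' @param mat Numeric matrix with sample-id row names.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles input paths, QC and testing thresholds, model flags and the
#' seed. Round-trips through a flat `key = value` text file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param plates,samples,panel Paths to the three input files.
#' @param out_dir Output directory for the run.
#' @param lod_frac,cv_max QC thresholds (see [run_qc()]).
#' @param lod_rule `"either"` or `"both"` (see [lod_filter()]).
#' @param alpha Family-wise significance level.
#' @param split_year Policy-change year for stratified scans.
#' @param cesarean Add cesarean section (factor) to the fixed effects
#'   (sensitivity model).
#' @param transform_offset `"half"` or `"blom"` normal-score offset.
#' @param retransform_strata Re-transform within each stratum (default)
#'   or reuse global normal scores.
#' @param code Diagnosis code for the co-occurrence test.
#' @param snp Variant id (sample-sheet dosage column) for the genetic
#'   models, or `NA` to skip.
#' @param ratio Character vector of two metabolite names,
#'   numerator/denominator of the genetic ratio trait, or `NULL`.
#' @param seed Integer seed for any randomness in a run.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(plates, samples, panel, out_dir = "run",
                       lod_frac = 0.20, cv_max = 0.25,
                       lod_rule = "either",
                       alpha = 0.05, split_year = 2009,
                       cesarean = FALSE,
                       transform_offset = "half",
                       retransform_strata = TRUE,
                       code = "P92.5", snp = "rs174547",
                       ratio = c("PC(38:4)", "PC(38:3)"),
                       seed = 1L) {
  stopifnot(lod_frac >= 0, lod_frac <= 1, cv_max >= 0,
            alpha > 0, alpha <= 1)
  lod_rule <- match.arg(lod_rule, c("either", "both"))
  transform_offset <- match.arg(transform_offset, c("half", "blom"))
  cfg <- list(plates = plates, samples = samples, panel = panel,
              out_dir = out_dir, lod_frac = lod_frac, cv_max = cv_max,
              lod_rule = lod_rule, alpha = alpha, split_year = split_year,
              cesarean = isTRUE(cesarean),
              transform_offset = transform_offset,
              retransform_strata = isTRUE(retransform_strata),
              code = code, snp = snp,
              ratio = ratio, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @param path Config file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- config
  flat$ratio <- paste(config$ratio, collapse = "|")
  lines <- vapply(names(flat), function(k) {
    paste0(k, " = ", as.character(flat[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec(
    "^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  cfg <- stats::setNames(as.list(vals), keys)
  ratio <- if (!is.null(cfg$ratio) && nzchar(cfg$ratio)) {
    strsplit(cfg$ratio, "|", fixed = TRUE)[[1]]
  } else NULL
  run_config(
    plates = cfg$plates, samples = cfg$samples, panel = cfg$panel,
    out_dir = cfg$out_dir,
    lod_frac = as.numeric(cfg$lod_frac), cv_max = as.numeric(cfg$cv_max),
    lod_rule = cfg$lod_rule, alpha = as.numeric(cfg$alpha),
    split_year = as.integer(cfg$split_year),
    cesarean = as.logical(cfg$cesarean),
    transform_offset = cfg$transform_offset,
    retransform_strata = as.logical(cfg$retransform_strata),
    code = cfg$code,
    snp = if (identical(cfg$snp, "NA")) NA_character_ else cfg$snp,
    ratio = ratio,
    seed = as.integer(cfg$seed))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Composes the stages on the three input files: plate QC and
#' normalization ([run_qc()]), the metabolome-wide matched-pair scan
#' ([metabolome_scan()]) plus era-stratified scans ([stratified_scan()]),
#' pairwise correlations of the Bonferroni-significant hits, the
#' diagnosis-code exact test ([fisher_exact()]) with the code-timing
#' model when timing data exist, and the SNP-trait models when a dosage
#' column is present. Writes `normalized_matrix.tsv`, `qc_report.json`,
#' `qc_summary.txt`, `assoc_results.tsv`, `epi_results.txt`,
#' `snp_results.tsv` and `run_log.txt` into the output directory.
#' Identical config and inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`qc`, `scan`,
#'   `stratified`, `correlations`, `code_test`, `timing`, `snp`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  for (f in c("plates", "samples", "panel")) {
    if (!file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- .stage("panel", read_panel(config$panel))
  plates <- .stage("plates", read_plate_table(config$plates))
  samples <- .stage("samples", read_sample_sheet(config$samples))

  qc <- .stage("qc", run_qc(plates, samples, panel,
                            lod_frac = config$lod_frac,
                            cv_max = config$cv_max,
                            lod_rule = config$lod_rule))
  covars <- c("sex", "year_of_birth", "parity", "gestational_age",
              if (config$cesarean) "cesarean")
  scan <- .stage("assoc", metabolome_scan(
    qc$matrix, samples, alpha = config$alpha, covariates = covars,
    offset = config$transform_offset))
  strat <- .stage("assoc_stratified", stratified_scan(
    qc$matrix, samples, split_year = config$split_year,
    retransform = config$retransform_strata, alpha = config$alpha,
    covariates = covars, offset = config$transform_offset))

  hits <- scan$metabolite[scan$significant_bonferroni]
  cors <- NULL
  if (length(hits) >= 2L) {
    tm <- apply(qc$matrix[, hits, drop = FALSE], 2,
                inverse_normal_transform)
    cors <- .stage("correlations", pairwise_correlation(tm))
  }

  code_test <- NULL
  timing <- NULL
  if (!is.null(samples$icd_code) &&
      any(samples$icd_code == config$code, na.rm = TRUE)) {
    tab <- make_code_table(samples, config$code)
    if (min(tab$a + tab$b, tab$c + tab$d) > 0) {
      code_test <- .stage("epi", fisher_exact(tab))
    }
    top <- scan$metabolite[1]
    carriers <- !is.na(samples$icd_code) & samples$icd_code == config$code &
      !is.na(samples$code_day)
    lv <- table(samples$code_day[carriers] == 0)
    if (length(lv) == 2L && all(lv >= 2L) && top %in% colnames(qc$matrix)) {
      y <- inverse_normal_transform(qc$matrix[, top])
      timing <- .stage("epi_timing",
                       code_timing_model(y, samples, config$code))
      timing$trait <- top
    }
  }

  snp_res <- NULL
  if (!is.na(config$snp) && config$snp %in% names(samples)) {
    dosage <- samples[[config$snp]]
    rows <- list()
    if (!is.null(config$ratio) &&
        all(config$ratio %in% colnames(qc$matrix))) {
      rt <- metabolite_ratio(qc$matrix[, config$ratio[1]],
                             qc$matrix[, config$ratio[2]])
      lab <- paste0(config$ratio[1], "/", config$ratio[2])
      for (s in c("all", "pre_policy", "post_policy")) {
        r <- .stage("genetics", snp_trait_assoc(
          dosage, inverse_normal_transform(rt), samples,
          snp = config$snp, trait_name = lab, stratum = s,
          split_year = config$split_year))
        rows[[paste(lab, s)]] <- data.frame(
          snp = r$snp, trait = r$trait, beta = r$beta, se = r$se,
          p = r$p, stratum = r$stratum, n = r$n, stringsAsFactors = FALSE)
      }
    }
    sweep_res <- .stage("genetics", snp_metabolome_scan(
      dosage, qc$matrix, samples, snp = config$snp,
      alpha = config$alpha))
    snp_res <- rbind(do.call(rbind, rows),
                     cbind(sweep_res[, c("snp", "trait", "beta", "se",
                                         "p", "stratum", "n")]))
    rownames(snp_res) <- NULL
  }

  # outputs
  od <- config$out_dir
  write_matrix(qc$matrix, file.path(od, "normalized_matrix.tsv"))
  rep <- qc$report
  jsonlite::write_json(
    list(thresholds = rep$thresholds,
         n_input = rep$n_input, n_kept = rep$n_kept,
         verdicts = rep$verdicts,
         cv = as.list(rep$cv),
         lod = as.data.frame(rep$lod),
         correction = as.data.frame(rep$correction)),
    file.path(od, "qc_report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::capture.output(print(rep), file = file.path(od, "qc_summary.txt"))
  res_all <- rbind(as.data.frame(scan), as.data.frame(strat))
  utils::write.table(res_all, file.path(od, "assoc_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(snp_res)) {
    utils::write.table(snp_res, file.path(od, "snp_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  epi_lines <- c(
    if (!is.null(code_test)) utils::capture.output(print(code_test)),
    if (!is.null(timing)) utils::capture.output(print(timing)))
  if (length(epi_lines)) {
    writeLines(epi_lines, file.path(od, "epi_results.txt"))
  }

  drop_tab <- table(factor(rep$verdicts$verdict,
                           levels = c("kept", "dropped_lod", "dropped_qc2",
                                      "dropped_cv")))
  log_lines <- c(
    paste0("dbsmetab version: ",
           as.character(utils::packageVersion("dbsmetab"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("lod_frac: ", config$lod_frac, " (rule ", config$lod_rule, ")"),
    paste0("cv_max: ", config$cv_max),
    paste0("alpha: ", config$alpha),
    paste0("split_year: ", config$split_year),
    paste0("metabolites in: ", rep$n_input),
    paste0("dropped at LOD stage: ", drop_tab[["dropped_lod"]]),
    paste0("dropped at QC2-correction stage: ", drop_tab[["dropped_qc2"]]),
    paste0("dropped at CV stage: ", drop_tab[["dropped_cv"]]),
    paste0("metabolites kept: ", rep$n_kept),
    paste0("bonferroni threshold: ", config$alpha, "/", rep$n_kept,
           " = ", format(config$alpha / rep$n_kept, digits = 6)),
    paste0("significant metabolites: ", length(hits)))
  writeLines(log_lines, file.path(od, "run_log.txt"))

  invisible(list(qc = qc, scan = scan, stratified = strat,
                 correlations = cors, code_test = code_test,
                 timing = timing, snp = snp_res, out_dir = od))
}

#' Generate on-disk synthetic fixtures
#'
#' Writes a complete synthetic study (plate CSV, sample TSV, panel TSV,
#' ground-truth JSON) at one of two sizes: `"tiny"` (20 pairs, 2 plates;
#' fast enough for unit tests) or `"study_scale"` (267 pairs, 8 plates,
#' the emulated study size). Both sizes share the bundled panel
#' definition.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param size `"tiny"` or `"study_scale"`.
#' @param panel Panel definition shared by both sizes (default
#'   [bundled_panel()]).
#' @param ... Overrides passed to [sim_config()].
#' @return The [sim_config()] used, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, size = c("tiny", "study_scale"),
                          panel = bundled_panel(), ...) {
  size <- match.arg(size)
  args <- if (size == "tiny") {
    list(n_pairs = 20, n_plates = 2, seed = seed)
  } else {
    list(n_pairs = 267, n_plates = 8, seed = seed)
  }
  cfg <- do.call(sim_config, utils::modifyList(args, list(...)))
  study <- simulate_study(cfg, panel = panel)
  write_study(study, dir)
  invisible(cfg)
}
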