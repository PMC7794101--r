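test_that("per-plate LOD is the blank median, with midpoint convention", {
  tab <- rbind(
    plate_rows("PL01", c("blank", "blank", "blank"), c(1.0, 9.0, 2.0)),
    plate_rows("PL02", c("blank", "blank", "blank"), c(0, 0, 0)),
    plate_rows("PL03", c("blank", "blank"), c(1.0, 3.0)))
  lod <- compute_lod(tab)
  expect_equal(lod["PC(38:4)", "PL01"], 2.0)
  expect_equal(lod["PC(38:4)", "PL02"], 0)
  expect_equal(lod["PC(38:4)", "PL03"], 2.0)  # even count: midpoint
})

test_that("a metabolite missing from a plate's blanks is an error", {
  tab <- rbind(
    plate_rows("PL01", c("blank", "sample"), c(1, 5), met = "PC(38:4)"),
    plate_rows("PL01", "sample", 5, met = "AC(2:0)",
               sample_ids = "S01"))
  expect_error(compute_lod(tab), "AC\\(2:0\\).*PL01")
  expect_error(compute_lod(plate_rows("PL01", "sample", 5)), "no blank")
})

test_that("LOD filter keeps a metabolite when one group is 80% above LOD", {
  # LOD = 1; 3/10 case values at/below, 1/10 control values below
  vals_case <- c(rep(0.5, 3), rep(5, 7))
  vals_ctrl <- c(0.5, rep(5, 9))
  tab <- rbind(
    plate_rows("PL01", rep("blank", 3), c(1, 1, 1)),
    plate_rows("PL01", rep("sample", 20), c(vals_case, vals_ctrl),
               sample_ids = sprintf("S%02d", 1:20)))
  samples <- craft_samples(sprintf("S%02d", 1:10), sprintf("S%02d", 11:20))
  lod <- compute_lod(tab)

  lf <- lod_filter(tab, samples, lod)
  expect_equal(lf$frac_case, 0.3)
  expect_equal(lf$frac_control, 0.1)
  expect_true(lf$keep)  # control group passes the 80% rule
  # strict-AND option: both groups must pass
  expect_false(lod_filter(tab, samples, lod, rule = "both")$keep)

  # 30% at/below in both groups: dropped under either rule
  vals_bad <- c(rep(1, 3), rep(5, 7))  # "<=" is non-strict
  tab2 <- rbind(
    plate_rows("PL01", rep("blank", 3), c(1, 1, 1)),
    plate_rows("PL01", rep("sample", 20), c(vals_bad, vals_bad),
               sample_ids = sprintf("S%02d", 1:20)))
  expect_false(lod_filter(tab2, samples, lod)$keep)

  # everything above LOD: kept with zero fractions
  tab3 <- rbind(
    plate_rows("PL01", rep("blank", 3), c(1, 1, 1)),
    plate_rows("PL01", rep("sample", 20), rep(5, 20),
               sample_ids = sprintf("S%02d", 1:20)))
  lf3 <- lod_filter(tab3, samples, lod)
  expect_equal(c(lf3$frac_case, lf3$frac_control), c(0, 0))
  expect_true(lf3$keep)
})

test_that("plate correction is the above-LOD QC2 median over the target", {
  pan <- mono_panel(tv = 10)
  base <- plate_rows("PL01", c(rep("blank", 3), rep("QC2", 5)),
                     c(0.4, 0.5, 0.6, 10, 10, 10, 10, 10))
  lod <- compute_lod(base)
  expect_equal(lod["PC(38:4)", "PL01"], 0.5)
  pc <- plate_correction(base, pan, lod)
  expect_equal(pc$correction["PC(38:4)", "PL01"], 1.0)

  tab2 <- plate_rows("PL01", c(rep("blank", 3), rep("QC2", 5)),
                     c(0.4, 0.5, 0.6, 18, 20, 22, 19, 21))
  pc2 <- plate_correction(tab2, pan, compute_lod(tab2))
  expect_equal(pc2$qc2_median["PC(38:4)", "PL01"], 20)
  expect_equal(pc2$correction["PC(38:4)", "PL01"], 2.0)

  # sub-LOD QC2 cell excluded from the median
  tab3 <- plate_rows("PL01", c(rep("blank", 3), rep("QC2", 5)),
                     c(0.4, 0.5, 0.6, 0.1, 20, 20, 20, 20))
  pc3 <- plate_correction(tab3, pan, compute_lod(tab3))
  expect_equal(pc3$qc2_median["PC(38:4)", "PL01"], 20)

  # no QC2 above LOD: flagged unusable
  tab4 <- plate_rows("PL01", c(rep("blank", 3), rep("QC2", 5)),
                     c(5, 5, 5, rep(0.1, 5)))
  pc4 <- plate_correction(tab4, pan, compute_lod(tab4))
  expect_true(is.na(pc4$correction["PC(38:4)", "PL01"]))
  expect_equal(pc4$unusable$metabolite, "PC(38:4)")
})

test_that("normalization divides by C and pins QC2 medians at TV", {
  tab <- plate_rows("PL01",
                    c(rep("blank", 3), rep("QC2", 5), rep("sample", 2)),
                    c(0.4, 0.5, 0.6, 18, 20, 22, 19, 21, 30, 12),
                    sample_ids = c(rep(NA, 8), "S01", "S02"))
  pan <- mono_panel(tv = 10)
  lod <- compute_lod(tab)
  pc <- plate_correction(tab, pan, lod)
  norm <- normalize_plates(tab, pc$correction)
  expect_equal(norm$norm_uM[which(norm$sample_id == "S01")], 15)  # 30 / 2
  # above-LOD QC2 median of normalized values == TV exactly
  qn <- norm[norm$role == "QC2" & norm$raw_uM > 0.5, ]
  expect_identical(median(qn$norm_uM), 10)
  # C = 1 leaves values unchanged
  C1 <- pc$correction
  C1[] <- 1
  expect_equal(normalize_plates(tab, C1)$norm_uM, tab$raw_uM)
  # non-positive correction is an error
  C0 <- pc$correction
  C0[] <- 0
  expect_error(normalize_plates(tab, C0), "non-positive")
})

test_that("CV filter uses the n-1 sample SD over pooled QC2 wells", {
  mk <- function(vals) {
    t <- plate_rows("PL01", rep("QC2", length(vals)), vals)
    t$norm_uM <- t$raw_uM
    t
  }
  cf <- cv_filter(mk(c(8, 12)))
  expect_equal(cf$cv, sd(c(8, 12)) / 10)       # 2.828.. / 10 ~ 28.3%
  expect_false(cf$keep)                        # > 25%
  expect_true(cv_filter(mk(c(8, 12)), cv_max = 1.0)$keep)
  cf0 <- cv_filter(mk(rep(7, 6)))
  expect_equal(cf0$cv, 0)
  expect_true(cf0$keep)
})

test_that("run_qc drops exactly the designed failures", {
  cfg <- sim_config(n_pairs = 16, n_plates = 2,
                    fail_lod_metabolites = c("PC(30:0)", "CE(14:0)"),
                    fail_cv_metabolites = "Valine",
                    fail_cv_value = 0.8, seed = 31)
  st <- simulate_study(cfg, panel = small_panel())
  qc <- run_qc(st$plates, st$samples, st$panel)
  v <- with(qc$report$verdicts, setNames(verdict, metabolite))
  expect_equal(unname(v[c("PC(30:0)", "CE(14:0)")]),
               rep("dropped_lod", 2))
  expect_equal(unname(v[["Valine"]]), "dropped_cv")
  expect_equal(sum(v == "kept"), panel_total(st$panel) - 3L)
  expect_equal(ncol(qc$matrix), panel_total(st$panel) - 3L)
  # verdicts partition the panel
  expect_setequal(qc$report$verdicts$metabolite,
                  unique(st$plates$metabolite))
})

test_that("the LOD stage takes precedence over the CV stage", {
  # one metabolite that fails both filters must be recorded as an LOD
  # failure: swapping the stage order would mislabel it as a CV failure
  cfg <- sim_config(n_pairs = 16, n_plates = 2,
                    fail_lod_metabolites = "PC(30:0)",
                    fail_cv_metabolites = "PC(30:0)",
                    fail_cv_value = 0.8, seed = 32)
  st <- simulate_study(cfg, panel = small_panel())
  qc <- run_qc(st$plates, st$samples, st$panel)
  v <- qc$report$verdicts
  expect_equal(v$verdict[v$metabolite == "PC(30:0)"], "dropped_lod")
})

test_that("normalization is idempotent", {
  cfg <- sim_config(n_pairs = 8, n_plates = 2, seed = 33)
  st <- simulate_study(cfg, panel = small_panel())
  lod <- compute_lod(st$plates)
  pc <- plate_correction(st$plates, st$panel, lod)
  norm <- normalize_plates(st$plates, pc$correction)
  # treat normalized values as a fresh raw table and recompute C
  tab2 <- norm
  tab2$raw_uM <- tab2$norm_uM
  tab2$norm_uM <- NULL
  pc2 <- plate_correction(tab2, st$panel, compute_lod(tab2))
  expect_equal(max(abs(pc2$correction - 1)), 0, tolerance = 1e-12)
  norm2 <- normalize_plates(tab2, pc2$correction)
  expect_equal(norm2$norm_uM, norm$norm_uM, tolerance = 1e-12)
})

test_that("rescaling one plate leaves the normalized matrix unchanged", {
  cfg <- sim_config(n_pairs = 16, n_plates = 2, seed = 34)
  st <- simulate_study(cfg, panel = small_panel())
  qc1 <- run_qc(st$plates, st$samples, st$panel)
  scaled <- st$plates
  sel <- scaled$plate == "PL01"
  scaled$raw_uM[sel] <- scaled$raw_uM[sel] * 3.7
  qc2 <- run_qc(scaled, st$samples, st$panel)
  expect_equal(qc2$matrix, qc1$matrix, tolerance = 1e-12)
  expect_equal(qc2$report$verdicts, qc1$report$verdicts)
})
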