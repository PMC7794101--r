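# Shared fixture builders: everything is generated in code at test time.

# Minimal panel with the study's seven hit metabolites plus a few nulls.
small_panel <- function(extra = c("PC(30:0)", "PC(32:1)", "LPC(14:0)",
                                  "Valine", "CE(14:0)")) {
  p <- bundled_panel()
  panel_definition(p[p$name %in% c(sim_config()$affected_metabolites,
                                   extra), ])
}

# One-metabolite panel with a chosen target value.
mono_panel <- function(name = "PC(38:4)", tv = 10) {
  e <- parse_metabolite_name(name)
  panel_definition(data.frame(
    name = name, class = e$class, carbons = e$carbons,
    double_bonds = e$double_bonds, modifier = e$modifier,
    target_value_uM = tv, stringsAsFactors = FALSE))
}

# Hand-crafted long-format plate rows for one metabolite.
plate_rows <- function(plate, roles, values, met = "PC(38:4)",
                       sample_ids = NULL) {
  n <- length(roles)
  if (is.null(sample_ids)) {
    sample_ids <- ifelse(roles == "sample", sprintf("S%02d", seq_len(n)),
                         paste0(plate, "_", roles, "_", seq_len(n)))
  }
  data.frame(plate = plate, well = seq_len(n), sample_id = sample_ids,
             role = roles, metabolite = met, raw_uM = values,
             stringsAsFactors = FALSE)
}

# Sample sheet for crafted plate tables: first half cases, second controls.
craft_samples <- function(ids_case, ids_control) {
  n <- length(ids_case)
  stopifnot(length(ids_control) == n)
  data.frame(
    sample_id = c(ids_case, ids_control),
    pair_id = rep(sprintf("P%02d", seq_len(n)), 2),
    case = rep(c(1L, 0L), each = n),
    sex = "M", year_of_birth = 2010L, parity = 1L,
    gestational_age = 40, age_days = 2L,
    stringsAsFactors = FALSE)
}

# Balanced matched-pair outcome data for mixed-model oracle checks:
# y = pair intercept + delta * case + residual.
paired_data <- function(n_pairs, delta = 0, pair_sd = 2, resid_sd = 1) {
  b <- rnorm(n_pairs, 0, pair_sd)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(2 * n_pairs)),
    pair_id = rep(sprintf("P%03d", seq_len(n_pairs)), each = 2),
    case = rep(c(1L, 0L), n_pairs),
    y = rep(b, each = 2) + delta * rep(c(1L, 0L), n_pairs) +
      rnorm(2 * n_pairs, 0, resid_sd),
    stringsAsFactors = FALSE)
}

# Brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum central-hypergeometric point probabilities <= observed.
brute_fisher_p <- function(a, b, c_, d) {
  row1 <- a + b
  col1 <- a + c_
  N <- a + b + c_ + d
  lo <- max(0L, row1 + col1 - N)
  hi <- min(row1, col1)
  x <- lo:hi
  pr <- dhyper(x, col1, N - col1, row1)
  sum(pr[pr <= dhyper(a, col1, N - col1, row1) * (1 + 1e-7)])
}

# Noncentral hypergeometric tail probabilities at odds ratio psi, for the
# exact-CI inversion check.
nchg_tail <- function(a, b, c_, d, psi, upper = TRUE) {
  row1 <- a + b
  col1 <- a + c_
  N <- a + b + c_ + d
  lo <- max(0L, row1 + col1 - N)
  hi <- min(row1, col1)
  x <- lo:hi
  lw <- dhyper(x, col1, N - col1, row1, log = TRUE) + x * log(psi)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (upper) sum(w[x >= a]) else sum(w[x <= a])
}
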