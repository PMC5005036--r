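# Shared fixture builders and independent oracles, all generated in code.

make_qm <- function(values, ..., proteins = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- proteins %||% sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- samples %||% sprintf("S%d", seq_len(ncol(values)))
  quant_matrix(values, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent two-line riBAQ oracle: straight summation per sample
ribaq_oracle <- function(values, contaminant) {
  v <- values[!contaminant, , drop = FALSE]
  sweep(v, 2, colSums(v, na.rm = TRUE), "/")
}

# closed-form OLS slope oracle via lm() on detected points
ols_slope_oracle <- function(x, y) {
  ok <- is.finite(y)
  unname(stats::coef(stats::lm(y[ok] ~ x[ok]))[2])
}

# brute-force specific-binder filter: literal set comprehension over the
# detection matrix
filter_oracle <- function(qm, design, min_specific = 4, max_control = 0) {
  det <- is.finite(qm$values) & qm$values > 0
  spec <- design$ip$run[design$ip$condition == "specific"]
  ctrl <- design$ip$run[design$ip$condition == "control"]
  ids <- rownames(qm$values)
  ids[vapply(ids, function(p) {
    sum(det[p, spec]) >= min_specific && sum(det[p, ctrl]) <= max_control
  }, logical(1))]
}

# adjusted Rand index, computed from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small seeded totals matrix for IP simulations
make_totals <- function(n = 100, n_runs = 2, seed = 99) {
  set.seed(seed)
  v <- matrix(10^rnorm(n * n_runs, 6, 1), n, n_runs,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              paste0("T", seq_len(n_runs))))
  quant_matrix(v)
}

default_partners <- function() {
  data.frame(protein_id = c("P002", "P003", "P004", "P005", "P006"),
             capture_efficiency = c(1, 0.5, 0.2, 0.1, 0.05),
             stringsAsFactors = FALSE)
}

one_peptide_prm <- function(rt = 20, frags = c(y4 = 0.5, y6 = 0.3, y7 = 0.2),
                            amplitude = 2e5, ...) {
  prm_sim_config(peptides = list(list(sequence = "TESTPEPK", true_rt = rt,
                                      fragments = frags,
                                      amplitude = amplitude)), ...)
}
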