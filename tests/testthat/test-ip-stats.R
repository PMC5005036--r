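ip_design <- function(n_spec = 6, n_ctrl = 6, n_tot = 2) {
  study_design(ip_conditions = data.frame(
    run = c(sprintf("IP%d", seq_len(n_spec)),
            sprintf("CTRL%d", seq_len(n_ctrl)),
            sprintf("T%d", seq_len(n_tot))),
    condition = rep(c("specific", "control", "total"),
                    c(n_spec, n_ctrl, n_tot))))
}

test_that("specific-binder filter applies the 4-of-6 / control-absent rule", {
  d <- ip_design()
  v <- matrix(NA_real_, 3, 14,
              dimnames = list(c("all6", "only3", "inctrl"),
                              d$ip$run))
  v["all6", sprintf("IP%d", 1:6)] <- 1
  v["only3", sprintf("IP%d", 1:3)] <- 1
  v["inctrl", sprintf("IP%d", 1:6)] <- 1
  v["inctrl", "CTRL2"] <- 1
  qm <- quant_matrix(v, scale = "ribaq")
  expect_identical(filter_specific(qm, d), "all6")
  expect_identical(filter_specific(qm, d, max_control = 1),
                   c("all6", "inctrl"))
  expect_error(filter_specific(qm, d, min_specific = 7), "exceeds")
})

test_that("filter matches the brute-force oracle on simulated experiments", {
  totals <- make_totals(n = 60)
  for (seed in c(7, 20, 33)) {
    cfg <- ip_sim_config(bait_id = "P001",
                         true_partners = default_partners(), seed = seed)
    sim <- simulate_ip(cfg, totals)
    rib <- compute_ribaq(sim$quant)
    expect_setequal(filter_specific(rib, sim$design),
                    filter_oracle(rib, sim$design))
  }
})

test_that("enrichment ratio reproduces forced and bait-like cases", {
  d <- ip_design(n_spec = 2, n_ctrl = 0, n_tot = 2)
  v <- rbind(flat = c(0.01, 0.01, 0.01, 0.01),
             bait = c(2e-2, 2e-2, 2e-6, 2e-6),
             lost = c(NA, NA, 1e-4, 1e-4))
  colnames(v) <- c("IP1", "IP2", "T1", "T2")
  qm <- quant_matrix(v, scale = "ribaq")
  er <- enrichment_ratio(qm, d)
  expect_equal(er$enrichment_ratio[er$protein_id == "flat"], 1)
  # a bait-like ~10^4-fold enrichment
  expect_equal(er$enrichment_ratio[er$protein_id == "bait"], 1e4)
  expect_equal(er$log10_enrichment[er$protein_id == "bait"], 4)
  expect_equal(er$category[er$protein_id == "lost"], "total_only")
  expect_true(is.na(er$enrichment_ratio[er$protein_id == "lost"]))
})

test_that("enrichment ratio equals the mean-ratio oracle on random data", {
  set.seed(13)
  d <- ip_design(n_spec = 4, n_ctrl = 2, n_tot = 3)
  v <- matrix(rlnorm(25 * 9, -8, 1), 25, 9,
              dimnames = list(sprintf("P%02d", 1:25), d$ip$run))
  v[sample(length(v), 40)] <- NA
  qm <- quant_matrix(v, scale = "ribaq")
  er <- enrichment_ratio(qm, d)
  for (i in seq_len(nrow(er))) {
    if (er$category[i] != "both") next
    p <- er$protein_id[i]
    expect_equal(er$enrichment_ratio[i],
                 mean(v[p, sprintf("IP%d", 1:4)], na.rm = TRUE) /
                   mean(v[p, sprintf("T%d", 1:3)], na.rm = TRUE))
  }
})

test_that("eluate-only proteins get a censored lower-bound ratio", {
  d <- ip_design(n_spec = 2, n_ctrl = 0, n_tot = 2)
  v <- rbind(ghost = c(1e-3, 1e-3, NA, NA),
             anchor = c(1e-4, 1e-4, 2e-6, 4e-6))
  colnames(v) <- c("IP1", "IP2", "T1", "T2")
  er <- enrichment_ratio(quant_matrix(v, scale = "ribaq"), d)
  g <- er[er$protein_id == "ghost", ]
  expect_equal(g$category, "eluate_only")
  expect_true(g$censored)
  expect_equal(g$enrichment_ratio, 1e-3 / 2e-6)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand application of the step-up rule
  p <- c(0.005, 0.04, 0.2, 0.9)
  expect_equal(bh_fdr(p), c(0.02, 0.08, 0.2666666666666667, 0.9))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("BH adjustment is monotone, dominates raw p and is permutation-invariant", {
  set.seed(61)
  for (rep in 1:10) {
    p <- runif(50)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm]), adj[perm])
  }
})

test_that("stoichiometry implements both prey-to-bait formulas", {
  d <- ip_design(n_spec = 2, n_ctrl = 0, n_tot = 2)
  v <- rbind(bait = c(0.2, 0.2, 0.0002, 0.0002),
             partner = c(0.002, 0.002, 0.0004, 0.0004),
             peer = c(0.2, 0.2, 0.001, 0.001),
             noref = c(0.01, 0.01, NA, NA))
  colnames(v) <- c("IP1", "IP2", "T1", "T2")
  st <- stoichiometry(quant_matrix(v, scale = "ribaq"), d, "bait")
  get <- function(p, col) st[st$protein_id == p, col]
  expect_equal(get("bait", "unadjusted"), 1)
  expect_equal(get("bait", "adjusted"), 1)
  # (0.002/0.2) = 0.01; adjusted: 0.01 * 0.0002/0.0004 = 0.005
  expect_equal(get("partner", "unadjusted"), 0.01)
  expect_equal(get("partner", "adjusted"), 0.005)
  # eluate riBAQ equal to the bait's -> unadjusted 1
  expect_equal(get("peer", "unadjusted"), 1)
  # absent from totals -> adjusted undefined
  expect_true(is.na(get("noref", "adjusted")))
  expect_error(stoichiometry(quant_matrix(v, scale = "ribaq"), d, "nope"),
               "not detected")
})
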