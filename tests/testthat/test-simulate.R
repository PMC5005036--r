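test_that("the purification generator is deterministic and validates its config", {
  cf <- purification_sim_config(n_proteins = 80, seed = 5)
  s1 <- simulate_purification(cf)
  s2 <- simulate_purification(cf)
  expect_identical(s1$quant$values, s2$quant$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$evidence$intensity, s2$evidence$intensity)
  s3 <- simulate_purification(purification_sim_config(n_proteins = 80,
                                                      seed = 6))
  expect_false(identical(s1$quant$values, s3$quant$values))
  expect_error(purification_sim_config(frac_membrane = 1.2), "proportions")
  expect_error(purification_sim_config(n_proteins = 0))
})

test_that("noise-free generation recovers assigned slopes exactly", {
  cf <- purification_sim_config(n_proteins = 60, slope_sd = 0,
                                noise_sigma = 0, dropout_steepness = 0,
                                n_isoform_groups = 0, seed = 2)
  sim <- simulate_purification(cf)
  rib <- compute_ribaq(sim$quant)
  # slopes are fit on raw riBAQ profiles; riBAQ shifts every protein's
  # log-profile by the same per-fraction constant, so compare classes
  sl <- enrichment_slope(rib, sim$design)
  tr <- merge(sl, sim$truth$proteins, by = "protein_id")
  mem <- tr$class == "membrane"
  expect_true(all(abs(tr$slope[mem] - tr$slope[!mem] [1] -
                        cf$slope_membrane) < 1e-8))
  # on the raw iBAQ scale recovery is exact per protein
  sl_raw <- enrichment_slope(sim$quant, sim$design)
  tr_raw <- merge(sl_raw, sim$truth$proteins, by = "protein_id")
  expect_equal(tr_raw$slope, tr_raw$true_slope, tolerance = 1e-8)
})

test_that("an empty membrane class yields only near-zero slopes", {
  cf <- purification_sim_config(n_proteins = 50, frac_membrane = 0,
                                slope_sd = 0, noise_sigma = 0,
                                dropout_steepness = 0,
                                n_isoform_groups = 0, seed = 3)
  sim <- simulate_purification(cf)
  expect_false(any(sim$truth$proteins$class == "membrane"))
  expect_true(all(abs(sim$truth$proteins$true_slope) < 1e-12))
})

test_that("default generation lets slope fitting rank proteins correctly", {
  sim <- simulate_purification(purification_sim_config(seed = 1))
  rib <- compute_ribaq(sim$quant)
  sl <- enrichment_slope(rib, sim$design)
  tr <- merge(sl, sim$truth$proteins, by = "protein_id")
  expect_gt(cor(tr$slope, tr$true_slope, method = "spearman"), 0.8)
  # median membrane-vs-background separation recovers the configured slope
  sep <- median(tr$slope[tr$class == "membrane"]) -
    median(tr$slope[tr$class == "background"])
  expect_lt(abs(sep - 0.4) / 0.4, 0.15)
})

test_that("detection dropout is monotone in abundance", {
  sim <- simulate_purification(purification_sim_config(
    n_proteins = 2000, noise_sigma = 0, n_isoform_groups = 0, seed = 9))
  det <- is.finite(sim$quant$values)
  tr <- sim$truth$proteins
  # membrane proteins gain abundance along the fractions, so their
  # per-fraction detection rate must be non-decreasing (up to sampling)
  mem <- tr$class == "membrane"
  rates <- colMeans(det[mem, ])
  expect_true(all(diff(rates) >= -0.02))
  # and across proteins, higher baseline abundance => higher detection
  base <- rowMeans(log10(sim$quant$values), na.rm = TRUE)
  seen <- is.finite(base)
  med <- stats::median(base[seen])
  expect_gt(mean(rowMeans(det)[seen & base >= med]),
            mean(rowMeans(det)[seen & base < med]))
})

test_that("isoform groups conserve intensity and carry unique peptides", {
  sim <- simulate_purification(purification_sim_config(
    n_proteins = 40, n_isoform_groups = 4, dropout_steepness = 0, seed = 8))
  member <- sim$truth$member_ibaq
  groups <- unique(sim$truth$proteins$parent_group)
  groups <- groups[!is.na(groups)]
  for (g in groups) {
    members <- sim$truth$proteins$protein_id[
      sim$truth$proteins$parent_group %in% g]
    expect_equal(unname(sim$quant$values[g, ]),
                 unname(colSums(member[members, ])), tolerance = 1e-12)
    # every member has at least one unique peptide
    meta <- sim$evidence$meta
    expect_true(all(members %in% meta$unique_to[meta$parent_group == g]))
  }
  # apportionment recovers the true member split
  g <- groups[1]
  members <- sim$truth$proteins$protein_id[
    sim$truth$proteins$parent_group %in% g]
  ev_rows <- sim$evidence$meta$parent_group == g
  ev <- peptide_evidence(sim$evidence$meta[ev_rows, ],
                         sim$evidence$intensity[ev_rows, , drop = FALSE])
  grp_vals <- sim$quant$values[g, ]
  shares <- apportion_isoforms(grp_vals, ev)
  expect_equal(shares[members, ], member[members, ], tolerance = 1e-9)
})

test_that("the IP generator honors its limiting cases", {
  totals <- make_totals(n = 50)
  # no nonspecific binding -> empty control runs
  cfg <- ip_sim_config(bait_id = "P001", true_partners = default_partners(),
                       nonspecific_rate = 0, seed = 2)
  sim <- simulate_ip(cfg, totals)
  ctrl <- grep("^CTRL", colnames(sim$quant$values))
  expect_true(all(is.na(sim$quant$values[, ctrl])))

  # full capture without noise: partner eluate/total equals bait's
  cfg1 <- ip_sim_config(bait_id = "P001",
                        true_partners = data.frame(protein_id = "P002",
                                                   capture_efficiency = 1),
                        eluate_noise_sigma = 0, nonspecific_rate = 0,
                        partner_detect_prob = 1, seed = 3)
  sim1 <- simulate_ip(cfg1, totals)
  v <- sim1$quant$values
  avail <- rowMeans(totals$values)
  r_bait <- mean(v["P001", paste0("IP", 1:6)]) / avail["P001"]
  r_part <- mean(v["P002", paste0("IP", 1:6)]) / avail["P002"]
  expect_equal(unname(r_part), unname(r_bait), tolerance = 1e-12)

  expect_error(simulate_ip(
    ip_sim_config(bait_id = "NOPE", true_partners = default_partners()),
    totals), "NOPE")
})

test_that("planted partners pass the detection filter and outrank background", {
  totals <- make_totals(n = 100)
  cfg <- ip_sim_config(bait_id = "P001", true_partners = default_partners(),
                       seed = 7)
  sim <- simulate_ip(cfg, totals)
  rib <- compute_ribaq(sim$quant)
  keep <- filter_specific(rib, sim$design)
  planted <- c("P001", default_partners()$protein_id)
  expect_true(all(planted %in% keep))
  # >= 95% of non-partners fail the filter
  others <- setdiff(rownames(rib$values), planted)
  expect_lt(mean(others %in% keep), 0.05)

  # with modest noise all partners outrank all background by ratio
  cfg2 <- ip_sim_config(bait_id = "P001", true_partners = default_partners(),
                        eluate_noise_sigma = 0.1, seed = 11)
  sim2 <- simulate_ip(cfg2, totals)
  er <- enrichment_ratio(compute_ribaq(sim2$quant), sim2$design)
  er <- er[er$category == "both", ]
  pr <- er$enrichment_ratio[er$protein_id %in% planted]
  bg <- er$enrichment_ratio[!er$protein_id %in% planted]
  expect_gt(min(pr), max(bg))
})

test_that("the PRM generator produces Gaussian peaks with known areas", {
  # noise-free single fragment: integral matches the closed form within 1%
  cfg <- prm_sim_config(peptides = list(list(
    sequence = "ONE", true_rt = 12, fragments = c(y1 = 1),
    amplitude = 5e4)), noise_floor = 0, seed = 1)
  sim <- simulate_prm(cfg)
  tr <- sim$traces
  area <- integrate_peak(data.frame(time_min = tr$time_min,
                                    intensity = tr$intensity),
                         c(12 - 1.5, 12 + 1.5))
  expect_equal(area, 5e4 * 0.1 * sqrt(2 * pi), tolerance = 0.01)

  # summed-trace apex lands within one sampling interval of the true RT
  cfg3 <- one_peptide_prm(rt = 20, noise_floor = 100, seed = 3)
  s3 <- simulate_prm(cfg3)
  s <- sum_traces(s3$traces)
  expect_lt(abs(s$time_min[which.max(s$intensity)] - 20),
            cfg3$sampling_interval + 1e-12)

  # determinism and validation
  expect_identical(simulate_prm(cfg3)$traces, simulate_prm(cfg3)$traces)
  expect_error(prm_sim_config(peptides = list()), "empty")
  expect_error(prm_sim_config(peptides = list(list(
    sequence = "BAD", true_rt = 5, fragments = c(y1 = 0.7)))), "sum to 1")
})
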