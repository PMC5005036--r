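gauss_trace <- function(rt, sigma, amp, grid, fragment = "y1",
                        run = "r1", peptide = "PEP") {
  data.frame(run = run, peptide = peptide, fragment = fragment,
             time_min = grid,
             intensity = amp * exp(-(grid - rt)^2 / (2 * sigma^2)),
             stringsAsFactors = FALSE)
}

test_that("trace summation is pointwise and handles unequal grids", {
  grid <- seq(0, 10, by = 0.05)
  a <- gauss_trace(5, 0.2, 100, grid, "y1")
  expect_equal(sum_traces(a)$intensity, a$intensity)
  two <- rbind(a, within(a, fragment <- "y2"))
  expect_equal(sum_traces(two)$intensity, 2 * a$intensity)

  set.seed(3)
  b <- gauss_trace(5.1, 0.3, 50, grid, "y2")
  c3 <- gauss_trace(4.9, 0.25, 80, grid, "y3")
  s <- sum_traces(rbind(a, b, c3))
  expect_equal(s$intensity, a$intensity + b$intensity + c3$intensity,
               tolerance = 1e-9)
  # coarser second grid: interpolated contribution at shared points
  coarse <- gauss_trace(5, 0.2, 10, seq(0, 10, by = 0.1), "y4")
  s2 <- sum_traces(rbind(a, coarse))
  expect_equal(nrow(s2), length(grid))
})

test_that("trapezoidal integration recovers closed forms", {
  grid <- seq(0, 10, by = 0.002)
  rect <- data.frame(time_min = grid,
                     intensity = ifelse(grid >= 2 & grid <= 5, 7, 0))
  expect_equal(integrate_peak(rect, c(2, 5)), 21, tolerance = 0.005 * 21)
  zero <- data.frame(time_min = grid, intensity = 0)
  expect_equal(integrate_peak(zero, c(1, 9)), 0)
  g <- gauss_trace(5, 0.3, 1000, grid)
  expect_equal(integrate_peak(g, c(5 - 1.2, 5 + 1.2)),
               1000 * 0.3 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(integrate_peak(g, c(6, 4)), "increasing")
  expect_error(integrate_peak(g, c(-1, 5)), "span")
})

test_that("integration is linear on a shared grid", {
  grid <- seq(0, 4, by = 0.01)
  a <- gauss_trace(2, 0.2, 100, grid)
  b <- gauss_trace(2.3, 0.15, 60, grid)
  combo <- data.frame(time_min = grid,
                      intensity = 3 * a$intensity + 0.5 * b$intensity)
  expect_equal(integrate_peak(combo, c(1, 3.5)),
               3 * integrate_peak(a, c(1, 3.5)) +
                 0.5 * integrate_peak(b, c(1, 3.5)),
               tolerance = 1e-12)
})

test_that("peak qualification enforces the three acceptance criteria", {
  # two fragments only, MS2 matched -> rejected on criterion 1
  cfg2 <- one_peptide_prm(rt = 10, frags = c(y4 = 0.6, y5 = 0.4), seed = 5)
  s2 <- simulate_prm(cfg2)
  pc <- qualify_peak(s2$traces, s2$ms2)
  expect_false(pc$accepted)
  expect_equal(pc$area, 0)
  expect_match(paste(pc$rejection_reasons, collapse = " "), "co-eluting")

  # three fragments, dense points, matched MS2 inside -> accepted
  cfg3 <- one_peptide_prm(seed = 3)
  s3 <- simulate_prm(cfg3)
  pc3 <- qualify_peak(s3$traces, s3$ms2)
  expect_true(pc3$accepted)
  expect_gt(pc3$n_points, 2)
  expect_length(pc3$rejection_reasons, 0)

  # no MS2 match anywhere and no reference -> rejected, area zero-filled
  cfg0 <- one_peptide_prm(seed = 4, ms2_event_prob_at_apex = 0)
  s0 <- simulate_prm(cfg0)
  pc0 <- qualify_peak(s0$traces, NULL)
  expect_false(pc0$accepted)
  expect_equal(pc0$area, 0)
  expect_gte(length(pc0$rejection_reasons), 1)
})

test_that("the retention-time fallback is a strict 2-minute boundary", {
  cfg <- one_peptide_prm(rt = 20, frags = c(y4 = 0.4, y5 = 0.3, y6 = 0.3),
                         ms2_event_prob_at_apex = 0, seed = 4)
  s <- simulate_prm(cfg)
  frags <- c("y4", "y5", "y6")
  acc <- function(offset)
    qualify_peak(s$traces, NULL, reference_rt = 20 + offset,
                 reference_fragments = frags)$accepted
  expect_true(acc(1.5))
  expect_true(acc(1.999))
  expect_false(acc(2.001))
  expect_false(acc(2.5))
  # fallback also requires the fragment set to match
  wrong <- qualify_peak(s$traces, NULL, reference_rt = 20,
                        reference_fragments = c("y4", "y5", "y9"))
  expect_false(wrong$accepted)
  subset_ok <- qualify_peak(s$traces, NULL, reference_rt = 20,
                            reference_fragments = c("y4", "y5", "y6", "y9"),
                            fragment_match = "subset")
  expect_true(subset_ok$accepted)
})

test_that("experiment normalization averages per-peptide factors", {
  expect_equal(unname(experiment_normalization(
    matrix(5, 3, 4))), rep(1, 4))
  expect_equal(unname(experiment_normalization(
    matrix(c(2, 4, 6), 1, 3))), c(0.5, 1, 1.5))
  expect_equal(unname(experiment_normalization(
    rbind(c(2, 4, 6), c(30, 30, 30)))), c(0.75, 1, 1.25))
  # complete matrices: factors average to exactly 1
  set.seed(71)
  for (rep in 1:5) {
    b <- matrix(rlnorm(4 * 5), 4, 5)
    expect_equal(mean(experiment_normalization(b)), 1, tolerance = 1e-12)
  }
  b <- matrix(c(1, NA, NA, NA), 2, 2,
              dimnames = list(NULL, c("e1", "e2")))
  expect_error(experiment_normalization(b), "e2")
})

test_that("IP/total averages conditions and tests specific vs control", {
  res <- ip_over_total(specific = c(5, 5, 5, 5), control = c(1, 1.5, 1, 1.2),
                       total = c(5, 5))
  expect_equal(res$ip_over_total, 1)
  res2 <- ip_over_total(specific = c(10, 10, 10, 10),
                        control = c(0, 0, 0, 1e-9), total = c(5, 5))
  expect_equal(res2$ip_over_total, 2)
  expect_equal(res2$control_over_total, 0, tolerance = 1e-9)
  expect_lt(res2$p_value, 0.001)
  expect_error(ip_over_total(1, c(1, 2), c(1)), "replicates")
})

test_that("the specific-vs-control p-value is calibrated under the null", {
  set.seed(81)
  p <- replicate(200, {
    ip_over_total(rnorm(5, 10), rnorm(5, 10), total = c(10, 10))$p_value
  })
  # binomial(200, 0.05) 99.9% upper bound
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p < 0.5), 0.3)
})
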