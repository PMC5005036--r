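#' Sum fragment-ion chromatograms for one peptide in one run
#'
#' PRM quantitation integrates the *summed* fragment-ion signal: each
#' monitored daughter ion's extracted chromatogram is summed pointwise
#' and the summed trace is integrated. Traces on different time grids
#' are linearly interpolated onto the densest grid first (outside a
#' fragment's own span it contributes 0).
#'
#' @param traces data.frame with columns `fragment`, `time_min`,
#'   `intensity` (one peptide, one run; extra columns ignored).
#' @return data.frame with columns `time_min`, `intensity`.
#' @export
sum_traces <- function(traces) {
  stopifnot(is.data.frame(traces),
            all(c("fragment", "time_min", "intensity") %in% names(traces)))
  if (nrow(traces) == 0) stop("no traces supplied", call. = FALSE)
  frags <- split(traces[, c("time_min", "intensity")], traces$fragment)
  grids <- lapply(frags, function(f) sort(f$time_min))
  # densest grid: the fragment with the most points
  grid <- grids[[which.max(vapply(grids, length, integer(1)))]]
  same <- all(vapply(grids, function(g)
    length(g) == length(grid) && all(g == grid), logical(1)))
  total <- numeric(length(grid))
  for (f in frags) {
    o <- order(f$time_min)
    t_f <- f$time_min[o]; y_f <- f$intensity[o]
    if (same) total <- total + y_f
    else total <- total + stats::approx(t_f, y_f, xout = grid,
                                        yleft = 0, yright = 0,
                                        rule = 1, ties = "ordered")$y |>
        (\(y) ifelse(is.na(y), 0, y))()
  }
  data.frame(time_min = grid, intensity = total)
}

#' Trapezoidal integration of a chromatogram segment
#'
#' Integrates a trace between boundaries with a zero baseline
#' (area units: intensity x minutes). Boundary times are included by
#' linear interpolation when they fall between samples.
#'
#' @param trace data.frame with columns `time_min`, `intensity`.
#' @param boundaries numeric length-2 vector `(start, end)` in minutes.
#' @return the peak area.
#' @export
integrate_peak <- function(trace, boundaries) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "intensity") %in% names(trace)))
  if (length(boundaries) != 2 || boundaries[2] <= boundaries[1])
    stop("`boundaries` must be an increasing (start, end) pair",
         call. = FALSE)
  o <- order(trace$time_min)
  t <- trace$time_min[o]; y <- trace$intensity[o]
  if (boundaries[1] < t[1] || boundaries[2] > t[length(t)])
    stop("boundaries outside the trace span", call. = FALSE)
  inside <- t > boundaries[1] & t < boundaries[2]
  yb <- stats::approx(t, y, xout = boundaries, ties = "ordered")$y
  tt <- c(boundaries[1], t[inside], boundaries[2])
  yy <- c(yb[1], y[inside], yb[2])
  pracma::trapz(tt, yy)
}

# Locate the candidate peak on a summed trace: smooth with a fixed-width
# moving mean, take the apex as the maximum (near reference_rt when
# given), and extend boundaries to where the smoothed trace drops below
# max(noise_floor, floor_frac * apex).
locate_peak <- function(summed, reference_rt = NULL, rt_window = 2,
                        smooth_points = 3, noise_floor = 0,
                        floor_frac = 0.01) {
  t <- summed$time_min; y <- summed$intensity
  ys <- if (smooth_points > 1) {
    k <- rep(1 / smooth_points, smooth_points)
    as.numeric(stats::filter(y, k, sides = 2))
  } else y
  ys[is.na(ys)] <- y[is.na(ys)]
  cand <- seq_along(t)
  if (!is.null(reference_rt))
    cand <- which(abs(t - reference_rt) <= rt_window)
  if (!length(cand)) cand <- seq_along(t)
  apex <- cand[which.max(ys[cand])]
  thresh <- max(noise_floor, floor_frac * ys[apex])
  lo <- apex
  while (lo > 1 && ys[lo - 1] >= thresh) lo <- lo - 1
  hi <- apex
  while (hi < length(t) && ys[hi + 1] >= thresh) hi <- hi + 1
  list(apex_idx = apex, rt_apex = t[apex],
       boundaries = c(t[lo], t[hi]), idx = lo:hi,
       smoothed = ys, threshold = thresh)
}

#' Rule-based PRM peak qualification and integration
#'
#' Applies the acceptance rules for a targeted chromatographic peak:
#' 1. three or more co-eluting fragment ions contribute to the peak
#'    signal (a fragment co-elutes when its own apex lies within one
#'    peak half-width of the summed-trace apex and it rises above the
#'    noise floor inside the boundaries);
#' 2. at least two data points were collected across the peak;
#' 3. one or more MS2 spectra acquired inside the peak were matched to
#'    the peptide.
#' When criterion 3 fails, a fallback accepts the peak iff a reference
#' retention time from an identified peak of the same peptide in
#' another run is available, the apex is within `rt_tolerance` minutes
#' of it, and the set of above-noise fragment labels matches the
#' reference fragment set. A peak failing qualification has area
#' exactly 0 (the zero-fill rule).
#'
#' @param traces data.frame of fragment chromatograms for one
#'   peptide/run (`fragment`, `time_min`, `intensity`).
#' @param ms2 data.frame of MS2 identification events for this
#'   peptide/run with columns `time_min`, `matched`; may be empty.
#' @param reference_rt retention time (minutes) of an identified peak
#'   for this peptide from another run, or `NULL`.
#' @param reference_fragments character vector of fragment labels of
#'   the reference peak, or `NULL`.
#' @param rt_tolerance fallback retention-time tolerance in minutes
#'   (default 2.0).
#' @param noise_floor intensity below which signal is considered noise.
#' @param smooth_points width (points) of the moving-mean smoother used
#'   for peak localization.
#' @param floor_frac boundaries extend to where the smoothed summed
#'   trace falls below `max(noise_floor, floor_frac * apex)`. The
#'   default 0.01 truncates under 0.3% of a Gaussian peak's area.
#' @param fragment_match `"equal"` (default) requires set equality of
#'   above-noise fragment labels with `reference_fragments`;
#'   `"subset"` accepts a subset.
#' @return a `peak_call` list: `boundaries`, `area`, `accepted`,
#'   `rejection_reasons`, `rt_apex`, `n_coeluting`, `n_points`,
#'   `fragments`.
#' @export
qualify_peak <- function(traces, ms2 = NULL, reference_rt = NULL,
                         reference_fragments = NULL, rt_tolerance = 2,
                         noise_floor = 0, smooth_points = 3,
                         floor_frac = 0.01,
                         fragment_match = c("equal", "subset")) {
  fragment_match <- match.arg(fragment_match)
  summed <- sum_traces(traces)
  # localization searches twice the acceptance tolerance so a peak just
  # outside the fallback window is still found, then rejected by the rule
  pk <- locate_peak(summed, reference_rt = reference_rt,
                    rt_window = 2 * rt_tolerance,
                    smooth_points = smooth_points,
                    noise_floor = noise_floor, floor_frac = floor_frac)
  in_peak <- traces$time_min >= pk$boundaries[1] &
    traces$time_min <= pk$boundaries[2]
  width <- max(pk$boundaries[2] - pk$rt_apex, pk$rt_apex - pk$boundaries[1])

  # criterion 1: co-eluting fragments
  frag_split <- split(traces[in_peak, , drop = FALSE],
                      traces$fragment[in_peak])
  coelut <- vapply(frag_split, function(f) {
    if (!nrow(f)) return(FALSE)
    above <- f$intensity > noise_floor
    if (!any(above)) return(FALSE)
    apex_f <- f$time_min[which.max(f$intensity)]
    abs(apex_f - pk$rt_apex) <= max(width, .Machine$double.eps)
  }, logical(1))
  frag_set <- sort(names(coelut)[coelut])
  n_coelut <- length(frag_set)

  # criterion 2: points across the peak
  n_points <- length(pk$idx)

  # criterion 3: matched MS2 event inside the peak
  ms2_ok <- FALSE
  if (!is.null(ms2) && nrow(ms2)) {
    ms2_ok <- any(ms2$matched &
                  ms2$time_min >= pk$boundaries[1] &
                  ms2$time_min <= pk$boundaries[2])
  }

  reasons <- character(0)
  if (n_coelut < 3)
    reasons <- c(reasons, "fewer than 3 co-eluting fragment ions")
  if (n_points < 2)
    reasons <- c(reasons, "fewer than 2 data points across the peak")
  if (!ms2_ok) {
    # retention-time fallback for unidentified peaks
    fallback <- FALSE
    if (!is.null(reference_rt)) {
      rt_ok <- abs(pk$rt_apex - reference_rt) <= rt_tolerance
      frag_ok <- if (is.null(reference_fragments)) FALSE
        else if (fragment_match == "equal")
          setequal(frag_set, reference_fragments)
        else all(frag_set %in% reference_fragments)
      fallback <- rt_ok && frag_ok
      if (!rt_ok)
        reasons <- c(reasons, sprintf(
          "no matched MS2 and apex %.3f min from reference (> %g min)",
          abs(pk$rt_apex - reference_rt), rt_tolerance))
      else if (!frag_ok)
        reasons <- c(reasons,
                     "no matched MS2 and fragment set differs from reference")
    } else {
      reasons <- c(reasons, "no matched MS2 spectrum within the peak")
    }
    ms2_ok <- fallback
  }

  accepted <- n_coelut >= 3 && n_points >= 2 && ms2_ok
  area <- if (accepted) integrate_peak(summed, pk$boundaries) else 0
  structure(list(boundaries = pk$boundaries, area = area,
                 accepted = accepted,
                 rejection_reasons = if (accepted) character(0) else reasons,
                 rt_apex = pk$rt_apex, n_coeluting = n_coelut,
                 n_points = n_points, fragments = frag_set),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("peak_call: %s, apex %.2f min, area %.4g\n",
              if (x$accepted) "accepted" else "REJECTED",
              x$rt_apex, x$area))
  if (length(x$rejection_reasons))
    cat("  reasons: ", paste(x$rejection_reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Bait-based experiment normalization factors
#'
#' Corrects run-to-run loading/response differences using the bait's
#' own peptides: for each bait peptide, its area in an experiment is
#' divided by that peptide's mean area over all experiments; the
#' per-peptide factors are then averaged across bait peptides to give
#' one normalization factor per experiment. Downstream areas are
#' divided by the factor of their experiment.
#'
#' @param bait_areas numeric matrix, bait peptides x experiments
#'   (`NA` = peptide not measured in that experiment).
#' @return named numeric vector of factors, one per experiment.
#' @export
experiment_normalization <- function(bait_areas) {
  stopifnot(is.matrix(bait_areas), ncol(bait_areas) >= 1)
  pep_mean <- rowMeans(bait_areas, na.rm = TRUE)
  rel <- bait_areas / pep_mean
  factors <- colMeans(rel, na.rm = TRUE)
  if (any(!is.finite(factors)))
    stop("experiment(s) with no bait peptide value: ",
         paste(colnames(bait_areas)[!is.finite(factors)], collapse = ", "),
         call. = FALSE)
  factors
}

#' IP/total summary for one peptide
#'
#' Averages normalized peak areas per condition and reports the ratio
#' of the mean specific-eluate area to the mean starting-material
#' (total) area, the analogous control ratio, and a two-tailed
#' two-sample t-test (Welch by default) comparing specific vs control
#' areas with a 95% confidence interval.
#'
#' @param specific numeric vector of normalized areas in bait-antibody
#'   eluate replicates (>= 2).
#' @param control numeric vector of normalized areas in control-IgG
#'   eluate replicates (>= 2).
#' @param total numeric vector of normalized areas in starting-material
#'   runs (>= 1).
#' @param var_equal pass `TRUE` for the pooled-variance Student test.
#' @return list with `mean_specific`, `mean_control`, `mean_total`,
#'   `ip_over_total`, `control_over_total`, `p_value`, `conf_int`.
#' @export
ip_over_total <- function(specific, control, total, var_equal = FALSE) {
  if (length(specific) < 2 || length(control) < 2)
    stop("need >= 2 replicates in both specific and control conditions",
         call. = FALSE)
  if (length(total) < 1) stop("no total-condition areas", call. = FALSE)
  mt <- mean(total)
  if (mt <= 0) stop("mean total area must be positive", call. = FALSE)
  tt <- tryCatch(stats::t.test(specific, control, var.equal = var_equal,
                               conf.level = 0.95),
                 error = function(e) NULL)
  list(mean_specific = mean(specific),
       mean_control = mean(control),
       mean_total = mt,
       ip_over_total = mean(specific) / mt,
       control_over_total = mean(control) / mt,
       p_value = if (is.null(tt)) NA_real_ else unname(tt$p.value),
       conf_int = if (is.null(tt)) c(NA_real_, NA_real_)
                  else unname(tt$conf.int))
}
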