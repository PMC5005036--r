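#' Detection-based specific-binder filter
#'
#' The binary control-subtraction rule for candidate interactors: keep
#' proteins detected in at least `min_specific` of the bait-antibody
#' (specific) eluate runs and in at most `max_control` control-IgG
#' eluate runs. The defaults encode "detected in at least four of six
#' specific runs and absent from all controls".
#'
#' @param m a [quant_matrix()] of riBAQ values over IP runs.
#' @param design a [study_design()] with `ip_conditions` set.
#' @param min_specific minimum specific-run detections (default 4).
#' @param max_control maximum allowed control-run detections (default 0).
#' @return character vector of passing protein ids.
#' @export
filter_specific <- function(m, design, min_specific = 4, max_control = 0) {
  stopifnot(inherits(m, "quant_matrix"), inherits(design, "study_design"))
  spec_runs <- ip_runs(design, "specific")
  ctrl_runs <- ip_runs(design, "control")
  if (min_specific > length(spec_runs))
    stop("`min_specific` (", min_specific, ") exceeds the number of ",
         "specific runs (", length(spec_runs), ")", call. = FALSE)
  det <- is_detected(m)
  n_spec <- rowSums(det[, intersect(spec_runs, colnames(det)),
                        drop = FALSE])
  n_ctrl <- rowSums(det[, intersect(ctrl_runs, colnames(det)),
                        drop = FALSE])
  rownames(det)[n_spec >= min_specific & n_ctrl <= max_control]
}

#' Immunoaffinity enrichment ratio
#'
#' Per protein, the ratio of its mean riBAQ across bait-antibody eluate
#' runs to its mean riBAQ across starting-material (total) runs; means
#' are taken over detected runs only. Proteins seen on only one side
#' are segregated into `eluate_only` / `total_only` categories rather
#' than placed on the ratio continuum; `eluate_only` proteins receive a
#' censored lower-bound ratio against the smallest detected total riBAQ
#' (`censored = TRUE`).
#'
#' @param m a [quant_matrix()] of riBAQ values over IP runs.
#' @param design a [study_design()] with `ip_conditions` set.
#' @param zero_impute treat non-detected runs as zero when averaging
#'   (default `FALSE`, i.e. average over detected runs only).
#' @return data.frame with columns `protein_id`,
#'   `n_specific_detections`, `n_control_detections`,
#'   `n_total_detections`, `mean_eluate`, `mean_total`,
#'   `enrichment_ratio`, `log10_enrichment`, `category`
#'   (`both`/`eluate_only`/`total_only`), `censored`. Proteins absent
#'   from both sides are excluded.
#' @export
enrichment_ratio <- function(m, design, zero_impute = FALSE) {
  stopifnot(inherits(m, "quant_matrix"), inherits(design, "study_design"))
  spec_runs <- intersect(ip_runs(design, "specific"), colnames(m$values))
  tot_runs <- intersect(ip_runs(design, "total"), colnames(m$values))
  ctrl_runs <- intersect(ip_runs(design, "control"), colnames(m$values))
  if (!length(spec_runs) || !length(tot_runs))
    stop("design must map at least one specific and one total run ",
         "present in the matrix", call. = FALSE)
  det <- is_detected(m)
  v <- m$values

  cond_mean <- function(runs) {
    vv <- v[, runs, drop = FALSE]
    if (zero_impute) {
      vv[!det[, runs, drop = FALSE]] <- 0
      rowMeans(vv)
    } else {
      n <- rowSums(det[, runs, drop = FALSE])
      s <- rowSums(vv, na.rm = TRUE)
      ifelse(n > 0, s / n, NA_real_)
    }
  }
  mean_el <- cond_mean(spec_runs)
  mean_tot <- cond_mean(tot_runs)
  n_spec <- rowSums(det[, spec_runs, drop = FALSE])
  n_tot <- rowSums(det[, tot_runs, drop = FALSE])
  n_ctrl <- if (length(ctrl_runs))
    rowSums(det[, ctrl_runs, drop = FALSE]) else rep(0L, nrow(v))

  in_el <- n_spec > 0
  in_tot <- n_tot > 0
  keep <- in_el | in_tot
  category <- ifelse(in_el & in_tot, "both",
                     ifelse(in_el, "eluate_only", "total_only"))
  min_total <- suppressWarnings(min(v[, tot_runs, drop = FALSE],
                                    na.rm = TRUE))
  ratio <- rep(NA_real_, nrow(v))
  ratio[in_el & in_tot] <- (mean_el / mean_tot)[in_el & in_tot]
  censored <- in_el & !in_tot
  if (any(censored) && is.finite(min_total))
    ratio[censored] <- mean_el[censored] / min_total

  out <- data.frame(protein_id = rownames(v),
                    n_specific_detections = as.integer(n_spec),
                    n_control_detections = as.integer(n_ctrl),
                    n_total_detections = as.integer(n_tot),
                    mean_eluate = mean_el,
                    mean_total = mean_tot,
                    enrichment_ratio = ratio,
                    log10_enrichment = log10(ratio),
                    category = category,
                    censored = censored,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[keep, , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of p-values (wrapper around
#' [stats::p.adjust()] with input validation); order-preserving, with
#' adjusted values never below raw ones.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p))
    stop("`p` must be numeric", call. = FALSE)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Bait-relative stoichiometry
#'
#' For each protein, its abundance in the bait-antibody eluate relative
#' to the bait, on a mol/mol scale via riBAQ. The unadjusted value is
#' (eluate riBAQ of protein) / (eluate riBAQ of bait); the adjusted
#' value rescales by (total riBAQ of bait) / (total riBAQ of protein)
#' to correct for how much of each protein was available in the
#' starting extract. Run-mean riBAQ over detected runs is used on both
#' sides. The bait's own stoichiometry is 1 under both definitions;
#' proteins absent from the totals get `NA` adjusted values.
#'
#' @param m a [quant_matrix()] of riBAQ values over IP runs.
#' @param design a [study_design()] with `ip_conditions` set.
#' @param bait protein id of the bait; must be detected in both the
#'   specific eluates and the totals.
#' @return data.frame with columns `protein_id`, `unadjusted`,
#'   `adjusted`, sorted by decreasing unadjusted stoichiometry.
#' @export
stoichiometry <- function(m, design, bait) {
  er <- enrichment_ratio(m, design)
  if (!bait %in% er$protein_id)
    stop("bait `", bait, "` not detected in the experiment", call. = FALSE)
  b <- er[er$protein_id == bait, ]
  if (!is.finite(b$mean_eluate) || !is.finite(b$mean_total))
    stop("bait `", bait, "` must be detected in both eluate and total runs",
         call. = FALSE)
  el <- er[is.finite(er$mean_eluate), , drop = FALSE]
  unadj <- el$mean_eluate / b$mean_eluate
  adj <- unadj * b$mean_total / el$mean_total
  out <- data.frame(protein_id = el$protein_id,
                    unadjusted = unadj, adjusted = adj,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$unadjusted, out$protein_id), , drop = FALSE]
}
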